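# Sequence/conformation context windows, two-sample positional enrichment,
# and three-shell microenvironment residue propensities.

PAD_SYMBOL <- "·" # middle dot: padding beyond chain ends / undefined

#' Extract a symbol window around a site
#'
#' The track is the ordered per-residue symbol series of one chain (amino
#' acids, secondary structure types, or structural alphabet states).
#' Offsets run from `-k` to `+k` in sequence order; positions outside the
#' chain, and `NA` symbols (for example undefined alphabet states at chain
#' ends), yield the padding symbol.
#'
#' @param track Tibble with columns `res_number` and `symbol`, ordered or
#'   orderable by `res_number`, for a single chain.
#' @param res_number Residue number of the central site.
#' @param k Half-width of the window.
#' @param require_center Optional symbol the center must carry (e.g. `"K"`
#'   for the amino-acid track); a mismatch is an error.
#' @return Tibble `offset`, `symbol` with `2k + 1` rows.
#' @export
extract_context <- function(track, res_number, k, require_center = NULL) {
  track <- arrange(as_tibble(track), .data$res_number)
  pos <- match(res_number, track$res_number)
  if (is.na(pos)) abort(paste0("site residue ", res_number, " not on the track"))
  if (!is.null(require_center) &&
      !identical(track$symbol[pos], require_center)) {
    abort(sprintf("central residue %s is '%s', expected '%s'",
                  res_number, track$symbol[pos], require_center))
  }
  idx <- pos + seq(-k, k)
  sym <- ifelse(idx >= 1 & idx <= nrow(track), track$symbol[pmax(idx, 1)],
                NA_character_)
  sym[is.na(sym)] <- PAD_SYMBOL
  tibble(offset = seq(-k, k), symbol = sym)
}

#' Context windows for a table of sites
#'
#' Vectorised equivalent of applying [extract_context()] to every site.
#'
#' @param tracks Tibble `chain_id`, `res_number`, `symbol` covering all
#'   chains of interest.
#' @param sites Tibble with `chain_id`, `res_number` (and any extra columns,
#'   carried through as window identifiers).
#' @param k Half-width.
#' @param require_center See [extract_context()].
#' @return Tibble `site_id`, `chain_id`, `res_number`, `offset`, `symbol`
#'   (long form, `2k + 1` rows per site).
#' @export
context_windows <- function(tracks, sites, k, require_center = NULL) {
  tracks <- as_tibble(tracks)
  by_chain <- split(tracks, tracks$chain_id)
  sites <- mutate(as_tibble(sites),
                  site_id = paste0(.data$chain_id, ":", .data$res_number))
  offs <- seq(-k, k)
  map(split(sites, sites$chain_id), function(s) {
    tr <- by_chain[[s$chain_id[1]]]
    if (is.null(tr)) abort(paste0("no track for chain ", s$chain_id[1]))
    tr <- arrange(tr, .data$res_number)
    pos <- match(s$res_number, tr$res_number)
    if (anyNA(pos)) {
      abort(paste0("site residue(s) not on the track: ",
                   paste(s$res_number[is.na(pos)], collapse = ", ")))
    }
    if (!is.null(require_center)) {
      bad <- tr$symbol[pos] != require_center
      if (any(bad, na.rm = TRUE) || anyNA(tr$symbol[pos])) {
        abort(sprintf("central residue(s) %s are not '%s'",
                      paste(s$res_number[bad | is.na(tr$symbol[pos])],
                            collapse = ", "), require_center))
      }
    }
    idx <- outer(pos, offs, "+") # n_sites x (2k+1)
    valid <- idx >= 1 & idx <= nrow(tr)
    sym <- matrix(PAD_SYMBOL, nrow(idx), ncol(idx))
    sym[valid] <- tr$symbol[idx[valid]]
    sym[is.na(sym)] <- PAD_SYMBOL
    tibble(site_id = rep(s$site_id, each = length(offs)),
           chain_id = rep(s$chain_id, each = length(offs)),
           res_number = rep(s$res_number, each = length(offs)),
           offset = rep(offs, nrow(s)),
           symbol = as.vector(t(sym)))
  }) |> list_rbind()
}

#' Two-sample positional enrichment table
#'
#' For every (offset, symbol) pair, compares the symbol frequency between
#' the positive and negative window sets with a two-sided Fisher's exact
#' test on the 2x2 count table. `direction` is `enriched`/`depleted` by the
#' sign of `freq_pos - freq_neg` when `p < alpha`, else `none`. Padding
#' symbols take part in the denominators, so per-offset frequencies sum
#' to 1.
#'
#' @param pos_windows,neg_windows Long window tables ([context_windows()])
#'   with identical `k`.
#' @param alpha Significance level for calling a direction.
#' @return Tibble `offset`, `symbol`, `freq_pos`, `freq_neg`, `p_value`,
#'   `direction`.
#' @export
two_sample_enrichment <- function(pos_windows, neg_windows, alpha = 0.05) {
  if (nrow(pos_windows) == 0 || nrow(neg_windows) == 0) {
    abort("both window sets must be non-empty")
  }
  if (!setequal(unique(pos_windows$offset), unique(neg_windows$offset))) {
    abort("window sets have different offsets (different k?)")
  }
  n_pos <- length(unique(pos_windows$site_id))
  n_neg <- length(unique(neg_windows$site_id))
  cnt <- function(w) count(w, .data$offset, .data$symbol, name = "count")
  tab <- dplyr::full_join(cnt(pos_windows), cnt(neg_windows),
                          by = c("offset", "symbol"),
                          suffix = c("_pos", "_neg")) |>
    mutate(across(c("count_pos", "count_neg"), ~ifelse(is.na(.x), 0L, .x)))
  tab |>
    mutate(
      freq_pos = .data$count_pos / n_pos,
      freq_neg = .data$count_neg / n_neg,
      p_value = map2_dbl(.data$count_pos, .data$count_neg, function(a, b) {
        fisher_exact_2x2(matrix(c(a, n_pos - a, b, n_neg - b), 2))
      }),
      direction = ifelse(
        .data$p_value < alpha,
        ifelse(.data$freq_pos > .data$freq_neg, "enriched", "depleted"),
        "none"
      )
    ) |>
    select("offset", "symbol", "freq_pos", "freq_neg", "p_value", "direction") |>
    arrange(.data$offset, .data$symbol)
}

#' Three-shell microenvironment residue propensities
#'
#' For each site, residues are binned into concentric shells by the C-beta
#' distance (C-alpha for glycine) from the central lysine; shells are
#' half-open intervals `(lo, hi]`, by default 0-7.5, 7.5-11.5 and
#' 11.5-15.5 Angstrom. The propensity of an amino acid in a shell is its
#' frequency in the shell divided by its frequency in the whole structure;
#' the central residue is excluded from both. Amino acids absent from the
#' structure (and all amino acids of an empty shell) have propensity 0.
#'
#' @param model A [structure_model()].
#' @param sites Tibble with `chain_id`, `res_number` rows (central lysines).
#' @param shells Increasing numeric vector of shell boundaries.
#' @return Tibble `site_id`, `shell`, `aa`, `propensity`, `n_shell`.
#' @export
shell_propensities <- function(model, sites, shells = c(0, 7.5, 11.5, 15.5)) {
  if (is.unsorted(shells, strictly = TRUE)) {
    abort("shell boundaries must be strictly increasing")
  }
  cb <- cbeta_atoms(model, warn = FALSE)
  xyz <- cbind(cb$x, cb$y, cb$z)
  key <- paste0(cb$chain_id, ":", cb$res_number)
  aas <- names(rsa_reference())
  n_shells <- length(shells) - 1
  sites <- as_tibble(sites)
  ci <- match(paste0(sites$chain_id, ":", sites$res_number), key)
  if (anyNA(ci)) {
    abort(paste0("site(s) without CB/CA atom: ",
                 paste(sites$chain_id[is.na(ci)], sites$res_number[is.na(ci)],
                       collapse = ", ")))
  }
  onehot <- outer(cb$aa, aas, "==") * 1 # n_res x 20
  d <- cross_dist(xyz[ci, , drop = FALSE], xyz)
  d[cbind(seq_along(ci), ci)] <- Inf # exclude the central residue
  bg_cnt <- matrix(colSums(onehot), length(ci), length(aas), byrow = TRUE) -
    onehot[ci, , drop = FALSE]
  bg_freq <- bg_cnt / rowSums(bg_cnt)
  site_ids <- paste0(sites$chain_id, ":", sites$res_number)
  map(seq_len(n_shells), function(s) {
    cnt <- ((d > shells[s]) * (d <= shells[s + 1])) %*% onehot
    n_in <- rowSums(cnt)
    prop <- ifelse(bg_freq > 0 & n_in > 0,
                   (cnt / pmax(n_in, 1)) / bg_freq, 0)
    tibble(site_id = rep(site_ids, each = length(aas)), shell = s,
           aa = rep(aas, length(ci)),
           count = as.integer(t(cnt)),
           propensity = as.vector(t(prop)),
           n_shell = rep(as.integer(n_in), each = length(aas)))
  }) |> list_rbind()
}
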