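# Local conformation: kappa/alpha virtual angles along the C-alpha trace,
# 22-state structural alphabet assignment, and DSSP secondary structure.

virtual_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Dihedral of four points, in degrees, signed so that a right-handed
# alpha-helical C-alpha trace gives about +50.
virtual_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(cr * b2) / vnorm(b2), sum(n1 * n2)) * 180 / pi
}

#' Kappa/alpha virtual angles of a C-alpha trace
#'
#' `kappa(i)` is the virtual bond angle at `Ca(i)` formed with `Ca(i-1)` and
#' `Ca(i+1)`, in `[0, 180]` degrees; `alpha(i)` is the virtual dihedral of
#' `Ca(i-1), Ca(i), Ca(i+1), Ca(i+2)`, in `(-180, 180]`. Both are `NA` where
#' the needed neighbours are missing (chain ends) or separated by a chain
#' break (consecutive C-alpha distance above `chain_break_cutoff`).
#'
#' @param model A [structure_model()], or a tibble of C-alpha positions with
#'   columns `chain_id`, `res_number`, `x`, `y`, `z`.
#' @param chain_break_cutoff Chain-break distance in Angstrom.
#' @return Tibble `chain_id`, `res_number`, `kappa`, `alpha`.
#' @export
compute_kappa_alpha <- function(model, chain_break_cutoff = 4.5) {
  ca <- if ("atom_name" %in% names(model)) {
    model |> filter(!.data$het, .data$atom_name == "CA")
  } else {
    model
  }
  ca <- arrange(as_tibble(ca), .data$chain_id, .data$res_number)
  per_chain <- function(d) {
    n <- nrow(d)
    xyz <- cbind(d$x, d$y, d$z)
    ok_step <- if (n > 1) {
      sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2)) <=
        chain_break_cutoff
    } else logical(0)
    kappa <- rep(NA_real_, n); alpha <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i >= 2 && i <= n - 1 && ok_step[i - 1] && ok_step[i]) {
        kappa[i] <- virtual_angle(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ])
        if (i <= n - 2 && ok_step[i + 1]) {
          alpha[i] <- virtual_dihedral(xyz[i - 1, ], xyz[i, ],
                                       xyz[i + 1, ], xyz[i + 2, ])
        }
      }
    }
    tibble(chain_id = d$chain_id, res_number = d$res_number,
           kappa = kappa, alpha = alpha)
  }
  split(ca, ca$chain_id) |> map(per_chain) |> list_rbind()
}

#' The packaged structural-alphabet map
#'
#' Loads the centroid table of the 22-letter kappa/alpha alphabet together
#' with the seven-group conformational classification (helix, helix-like,
#' strand, strand-like, highly/moderately curved coil, flat coil). State `Y`
#' carries a `merge_into = "A"` entry and is relabelled after assignment.
#'
#' @param path Optional replacement table (TSV with columns `state`,
#'   `kappa`, `alpha`, `group`, `merge_into`).
#' @return Tibble of centroids.
#' @export
sa_alphabet <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sa_centroids.tsv",
                                package = "ubistruct", mustWork = TRUE)
  map <- as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                                     stringsAsFactors = FALSE, fill = TRUE))
  map$merge_into[is.na(map$merge_into) | map$merge_into == ""] <- NA_character_
  stopifnot(!anyDuplicated(map$state))
  map
}

#' Assign structural-alphabet states from kappa/alpha angles
#'
#' Nearest-centroid assignment under the angular distance
#' `sqrt(dkappa^2 + dalpha^2)` with `dalpha` wrapped to `(-180, 180]`.
#' Ties break to the lexicographically smallest state letter; merged states
#' (`Y`) are relabelled to their parent (`A`) after assignment. Undefined
#' angles yield an `NA` state.
#'
#' @param angles Tibble with `kappa` and `alpha` columns
#'   ([compute_kappa_alpha()]).
#' @param map Centroid table ([sa_alphabet()]).
#' @return `angles` with added `sa_state` and `sa_group` columns.
#' @export
assign_structural_alphabet <- function(angles, map = sa_alphabet()) {
  ord <- order(map$state) # lexicographic tie-break: scan in letter order
  st <- map$state[ord]; ck <- map$kappa[ord]; cal <- map$alpha[ord]
  grp <- setNames(map$group, map$state)
  mrg <- setNames(map$merge_into, map$state)
  assign1 <- function(k, a) {
    if (is.na(k) || is.na(a)) return(NA_character_)
    d <- sqrt((k - ck)^2 + wrap_angle(a - cal)^2)
    st[which.min(d)]
  }
  state <- map2(angles$kappa, angles$alpha, assign1) |> unlist()
  merged <- ifelse(!is.na(state) & !is.na(mrg[state]), mrg[state], state)
  angles$sa_state <- unname(merged)
  angles$sa_group <- unname(grp[angles$sa_state])
  angles
}

#' Group structural-alphabet states
#'
#' @param states Character vector of state letters.
#' @param map Centroid table ([sa_alphabet()]).
#' @return Character vector of conformational groups.
#' @export
group_alphabet_states <- function(states, map = sa_alphabet()) {
  grp <- setNames(map$group, map$state)
  unknown <- setdiff(states[!is.na(states)], map$state)
  if (length(unknown) > 0) {
    abort(paste0("unknown structural alphabet state(s): ",
                 paste(unknown, collapse = ", ")))
  }
  unname(grp[states])
}

#' Read DSSP secondary structure
#'
#' Parses classic DSSP output and maps the eight-type code per residue;
#' blank codes become `"L"` (loop/other coil). Chain-break marker rows are
#' skipped.
#'
#' @param dssp Path to a DSSP file or DSSP-format text.
#' @return Tibble `chain_id`, `res_number`, `aa`, `ss_type`.
#' @export
read_dssp <- function(dssp) {
  lines <- if (length(dssp) == 1 && grepl("\n", dssp)) {
    strsplit(dssp, "\n")[[1]]
  } else if (length(dssp) == 1 && file.exists(dssp)) {
    readLines(dssp, warn = FALSE)
  } else {
    as.character(dssp)
  }
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) abort("malformed DSSP input: residue header not found")
  body <- lines[seq(hdr[1] + 1, length(lines))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & aa != " "
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "L"
  bad <- !ss %in% c("H", "G", "I", "E", "B", "T", "S", "L")
  if (any(bad)) ss[bad] <- "L"
  tibble(
    chain_id = trimws(substr(body, 12, 12)),
    res_number = as.integer(trimws(substr(body, 6, 10))),
    aa = substr(body, 14, 14),
    ss_type = ss
  )
}

#' Match DSSP assignments onto a structure's residues
#'
#' @param model A [structure_model()].
#' @param dssp_tbl Output of [read_dssp()].
#' @return Tibble of the model's residues with an `ss_type` column. Errors
#'   listing the residues present in the structure but missing from the
#'   DSSP table (or vice versa).
#' @export
match_secondary_structure <- function(model, dssp_tbl) {
  res <- model_residues(model)
  joined <- left_join(select(res, "chain_id", "res_number", "aa"),
                      select(dssp_tbl, "chain_id", "res_number", "ss_type"),
                      by = c("chain_id", "res_number"))
  missing <- joined[is.na(joined$ss_type), ]
  extra <- anti_join(dssp_tbl, res, by = c("chain_id", "res_number"))
  if (nrow(missing) > 0 || nrow(extra) > 0) {
    abort(paste0(
      "DSSP/structure residue mismatch; structure-only: ",
      paste(missing$chain_id, missing$res_number, collapse = ", "),
      "; DSSP-only: ",
      paste(extra$chain_id, extra$res_number, collapse = ", ")
    ))
  }
  joined
}
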