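# The structure model: a tidy atom table that the whole pipeline consumes.

#' Construct a structure model
#'
#' A structure model is a tibble of heavy atoms with one row per atom and
#' columns `chain_id`, `res_number`, `aa` (one-letter code, `NA` for hetero
#' groups), `resid3` (three-letter / hetero code), `atom_name`, `element`,
#' `x`, `y`, `z` and `het` (logical, `TRUE` for hetero atoms such as
#' ligands). The tibble carries a `source_id` attribute.
#'
#' @param atoms Data frame with the columns above.
#' @param source_id Identifier of the originating structure.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms, source_id = "model") {
  atoms <- as_tibble(atoms)
  needed <- c("chain_id", "res_number", "aa", "resid3", "atom_name",
              "element", "x", "y", "z", "het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("structure model is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  atoms <- atoms[, c(needed, setdiff(names(atoms), needed))]
  atoms$res_number <- as.integer(atoms$res_number)
  dup <- atoms |>
    filter(!.data$het) |>
    distinct(.data$chain_id, .data$res_number, .data$atom_name) |>
    nrow()
  if (dup < sum(!atoms$het)) {
    abort("duplicate (residue, atom_name) pairs: alternate locations must be resolved")
  }
  atoms <- arrange(atoms, .data$het, .data$chain_id, .data$res_number)
  attr(atoms, "source_id") <- source_id
  class(atoms) <- c("structure_model", class(tibble()))
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  poly <- x[!x$het, ]
  cat(sprintf(
    "<structure_model '%s': %d atoms, %d residues, %d chain(s), %d hetero atoms>\n",
    attr(x, "source_id") %||% "model", nrow(poly),
    nrow(distinct(poly, .data$chain_id, .data$res_number)),
    length(unique(poly$chain_id)), sum(x$het)
  ))
  NextMethod()
}

# Subsetting a structure model keeps the class and source id.
#' @export
`[.structure_model` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y", "z") %in% names(out))) {
    attr(out, "source_id") <- attr(x, "source_id")
    class(out) <- class(x)
  }
  out
}

#' Per-residue summary of a structure model
#'
#' @param model A `structure_model`.
#' @param het Include hetero groups (default drops them).
#' @return Tibble with one row per residue: `chain_id`, `res_number`, `aa`,
#'   `resid3`, `n_atoms`.
#' @export
model_residues <- function(model, het = FALSE) {
  m <- if (het) model else model[!model$het, ]
  m |>
    group_by(.data$chain_id, .data$res_number, .data$aa, .data$resid3) |>
    summarise(n_atoms = n(), .groups = "drop") |>
    arrange(.data$chain_id, .data$res_number)
}

#' Chain sequences of a structure model
#'
#' @param model A `structure_model`.
#' @return Named character vector of one-letter sequences, one per chain.
#' @export
model_sequences <- function(model) {
  res <- model_residues(model)
  res$aa[is.na(res$aa)] <- "X"
  vapply(split(res, res$chain_id), function(d) paste(d$aa, collapse = ""), "")
}

# Coordinate matrix (n x 3) of a model or atom subset.
coords <- function(model) {
  cbind(model$x, model$y, model$z)
}

# One representative "side-chain" atom per residue: CB, or CA for glycine
# (and, with a warning, for residues missing CB).
cbeta_atoms <- function(model, warn = TRUE) {
  poly <- model[!model$het, ]
  res <- distinct(as_tibble(poly), .data$chain_id, .data$res_number, .data$aa)
  key <- paste0(res$chain_id, ":", res$res_number)
  atom_key <- paste0(poly$chain_id, ":", poly$res_number)
  cb_rows <- which(poly$atom_name == "CB")
  ca_rows <- which(poly$atom_name == "CA")
  icb <- cb_rows[match(key, atom_key[cb_rows])]
  ica <- ca_rows[match(key, atom_key[ca_rows])]
  bad <- is.na(icb) & is.na(ica)
  if (any(bad)) {
    abort(paste0("residues without CB or CA atom: ",
                 paste(res$chain_id[bad], res$res_number[bad], collapse = ", ")))
  }
  odd <- is.na(icb) & res$aa != "G"
  if (warn && any(odd)) {
    warn(paste0("falling back to CA for non-glycine residues missing CB: ",
                paste(res$chain_id[odd], res$res_number[odd], collapse = ", ")))
  }
  pick <- ifelse(is.na(icb), ica, icb)
  tibble(chain_id = res$chain_id, res_number = res$res_number, aa = res$aa,
         x = poly$x[pick], y = poly$y[pick], z = poly$z[pick])
}
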