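# Site labelling and dataset-level filtering.

SITE_LABELS <- c("Ub", "NonUb", "Ace", "unlabeled")

#' Attach site labels to the lysines of a structure
#'
#' Every lysine in the model receives exactly one label. Annotation rows are
#' matched by (chain, residue number); rows pointing at non-lysine residues
#' or at residues absent from the model are rejected into a skip report
#' (attribute `"skipped"`), not treated as fatal. Lysines without an
#' annotation default to `NonUb`, mirroring the convention that
#' unannotated lysines are treated as non-ubiquitination sites.
#'
#' @param model A [structure_model()].
#' @param annotations Data frame with columns `chain_id`, `res_number`,
#'   `label` (one of `Ub`, `NonUb`, `Ace`, `unlabeled`). May be empty.
#' @return Tibble `chain_id`, `res_number`, `aa`, `label` (one row per
#'   lysine), with attribute `"skipped"` holding the rejected rows and a
#'   `reason` column.
#' @export
annotate_sites <- function(model, annotations = NULL) {
  res <- model_residues(model)
  lys <- filter(res, .data$aa == "K")
  ann <- as_tibble(annotations %||%
                     tibble(chain_id = character(), res_number = integer(),
                            label = character()))
  if (nrow(ann) > 0) {
    bad_label <- !ann$label %in% SITE_LABELS
    if (any(bad_label)) {
      abort(paste0("unknown site labels: ",
                   paste(unique(ann$label[bad_label]), collapse = ", ")))
    }
    dup <- ann |> count(.data$chain_id, .data$res_number) |> filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0("residues annotated more than once: ",
                   paste(dup$chain_id, dup$res_number, collapse = ", ")))
    }
  }
  ann$res_number <- as.integer(ann$res_number)
  key <- function(d) paste(d$chain_id, d$res_number)
  in_model <- key(ann) %in% key(res)
  on_lys <- key(ann) %in% key(lys)
  skipped <- bind_rows(
    mutate(ann[!in_model, ], reason = "residue absent from structure"),
    mutate(ann[in_model & !on_lys, ], reason = "annotated residue is not lysine")
  )
  ok <- ann[on_lys, ]
  sites <- lys |>
    select("chain_id", "res_number", "aa") |>
    left_join(select(ok, "chain_id", "res_number", "label"),
              by = c("chain_id", "res_number")) |>
    mutate(label = ifelse(is.na(.data$label), "NonUb", .data$label))
  attr(sites, "skipped") <- skipped
  sites
}

#' Read and write site tables
#'
#' Tab-separated site tables with header
#' `chain_id res_number aa label`.
#'
#' @param path File path.
#' @param sites Site tibble as produced by [annotate_sites()].
#' @return `read_site_table()` returns a tibble; `write_site_table()`
#'   returns `path` invisibly.
#' @export
read_site_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              comment.char = "#")) |>
    mutate(res_number = as.integer(.data$res_number))
}

#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch identity between two amino-acid sequences under a
#' match/mismatch/gap scoring of +1/0/-1, reported as
#' matches / alignment length.
#'
#' @param a,b One-letter amino-acid sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  alphabet <- unique(strsplit(paste0(a, b, "X"), "")[[1]])
  m <- matrix(0, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- 1
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Filter a chain collection by redundancy, label coverage and resolution
#'
#' Greedy longest-first redundancy removal: chains are visited from longest
#' to shortest and a chain is dropped when its global-alignment identity to
#' an already retained chain exceeds `max_identity`. Chains lacking either a
#' `Ub` or a `NonUb` site, and chains flagged as low resolution, are removed
#' first. The operation is idempotent.
#'
#' @param collection Tibble with columns `chain` (identifier), `model`
#'   (list of [structure_model()]), `sites` (list of site tibbles) and
#'   optionally `resolution_ok` (logical).
#' @param max_identity Identity threshold above which a chain is redundant.
#' @return The filtered collection tibble.
#' @export
filter_dataset <- function(collection, max_identity = 0.5) {
  collection <- as_tibble(collection)
  if (nrow(collection) == 0) return(collection)
  if (!"resolution_ok" %in% names(collection)) collection$resolution_ok <- TRUE
  keep_labels <- map_lgl(collection$sites, function(s) {
    any(s$label == "Ub") && any(s$label == "NonUb")
  })
  collection <- collection[keep_labels & collection$resolution_ok, ]
  if (nrow(collection) == 0) return(collection)
  seqs <- map_chr(collection$model, function(m) {
    paste(model_sequences(m), collapse = "")
  })
  ord <- order(-nchar(seqs))
  retained <- integer()
  for (i in ord) {
    redundant <- any(map_lgl(retained, function(j) {
      seq_identity(seqs[i], seqs[j]) > max_identity
    }))
    if (!redundant) retained <- c(retained, i)
  }
  collection[sort(retained), ]
}
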