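# Positional naive Bayes likelihood scoring under stratified k-fold
# cross-validation. Used for the sequence-context, conformation-context and
# microenvironment-composition indicators.

# Stratified fold assignment: within each label, sites are shuffled
# (seeded) and dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < folds) {
        abort(sprintf("class '%s' has fewer sites (%d) than folds (%d)",
                      lv, length(idx), folds))
      }
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Positional naive Bayes likelihood scores
#'
#' Trains, per window position, class-conditional symbol probabilities with
#' Laplace pseudocount 1 over the symbol vocabulary observed in the input
#' (the padding symbol is an ordinary symbol), and scores each site as
#' `sum over positions of log P(symbol | Ub) - log P(symbol | NonUb)`.
#' Every site is scored by the model trained on the other folds
#' (stratified by label, seeded), so scores are out-of-fold throughout.
#'
#' @param windows Long window table ([context_windows()]) with columns
#'   `site_id`, `offset`, `symbol`.
#' @param labels Tibble `site_id`, `label` with labels `Ub` / `NonUb`.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return Tibble `site_id`, `label`, `fold`, `score`.
#' @export
nb_positional_likelihood <- function(windows, labels, folds = 5, seed = 1) {
  labels <- as_tibble(labels)
  if (!all(c("Ub", "NonUb") %in% labels$label)) {
    abort("labels must contain both Ub and NonUb sites")
  }
  site_ids <- labels$site_id
  wide <- windows |>
    select("site_id", "offset", "symbol") |>
    tidyr::pivot_wider(names_from = "offset", values_from = "symbol")
  wide <- wide[match(site_ids, wide$site_id), ]
  if (anyNA(wide$site_id)) abort("windows missing for some labelled sites")
  sym <- as.matrix(wide[, -1, drop = FALSE])
  vocab <- sort(unique(as.vector(sym)))
  v <- length(vocab)
  fold <- stratified_folds(labels$label, folds, seed)
  score <- numeric(length(site_ids))
  for (f in seq_len(folds)) {
    train <- fold != f
    if (length(unique(labels$label[train])) < 2) {
      abort("a class is absent from the training folds")
    }
    for (cls in c("Ub", "NonUb")) {
      in_cls <- train & labels$label == cls
      n_cls <- sum(in_cls)
      # per-position symbol log-probabilities with Laplace pseudocount 1
      logp <- apply(sym[in_cls, , drop = FALSE], 2, function(col) {
        cnt <- table(factor(col, levels = vocab))
        log((as.numeric(cnt) + 1) / (n_cls + v))
      }) # v x n_positions
      idx <- matrix(match(sym[fold == f, , drop = FALSE], vocab),
                    nrow = sum(fold == f))
      contrib <- matrix(logp[cbind(as.vector(idx),
                                   rep(seq_len(ncol(sym)), each = nrow(idx)))],
                        nrow = nrow(idx))
      delta <- rowSums(contrib)
      if (cls == "Ub") score[fold == f] <- score[fold == f] + delta
      else score[fold == f] <- score[fold == f] - delta
    }
  }
  tibble(site_id = site_ids, label = labels$label, fold = fold, score = score)
}

#' Naive Bayes likelihood scores from composition counts
#'
#' Bag-of-symbols variant of [nb_positional_likelihood()] for the
#' microenvironment shells: each site contributes a multiset of amino acids
#' (its shell occupants); class-conditional amino-acid probabilities are
#' estimated from summed training counts with Laplace pseudocount 1, and a
#' site's score is the mean per-occupant log-likelihood ratio (mean, so
#' shells of different occupancy stay comparable; empty shells score 0).
#'
#' @param composition Tibble `site_id`, `symbol`, `count`.
#' @param labels Tibble `site_id`, `label`.
#' @param folds,seed See [nb_positional_likelihood()].
#' @return Tibble `site_id`, `label`, `fold`, `score`.
#' @export
nb_composition_likelihood <- function(composition, labels, folds = 5, seed = 1) {
  labels <- as_tibble(labels)
  comp <- composition |>
    select("site_id", "symbol", "count") |>
    tidyr::pivot_wider(names_from = "symbol", values_from = "count",
                       values_fill = 0)
  comp <- comp[match(labels$site_id, comp$site_id), ]
  if (anyNA(comp$site_id)) abort("composition missing for some labelled sites")
  m <- as.matrix(comp[, -1, drop = FALSE])
  v <- ncol(m)
  fold <- stratified_folds(labels$label, folds, seed)
  score <- numeric(nrow(labels))
  for (f in seq_len(folds)) {
    train <- fold != f
    lr <- log((colSums(m[train & labels$label == "Ub", , drop = FALSE]) + 1) /
                (sum(m[train & labels$label == "Ub", ]) + v)) -
      log((colSums(m[train & labels$label == "NonUb", , drop = FALSE]) + 1) /
            (sum(m[train & labels$label == "NonUb", ]) + v))
    test <- fold == f
    tot <- rowSums(m[test, , drop = FALSE])
    s <- as.numeric(m[test, , drop = FALSE] %*% lr)
    score[test] <- ifelse(tot > 0, s / pmax(tot, 1), 0)
  }
  tibble(site_id = labels$site_id, label = labels$label, fold = fold,
         score = score)
}
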