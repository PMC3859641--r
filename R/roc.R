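# ROC/AUC, DeLong's paired test, and weighted indicator combination.

as_pos_logical <- function(labels, positive = "Ub") {
  if (is.logical(labels)) return(labels)
  labels == positive
}

#' ROC curve and AUC
#'
#' AUC by the midrank (Mann-Whitney) formula `U / (n_pos * n_neg)` with
#' ties counted 1/2; the curve is a threshold sweep from (0,0) to (1,1).
#' Higher scores must indicate the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive), or a vector compared against
#'   `positive`.
#' @param positive Positive-class label.
#' @return A `ubi_roc` object: list with `auc`, `curve` (tibble `fpr`,
#'   `tpr`, `threshold`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "Ub") {
  pos <- as_pos_logical(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  thr_groups <- !duplicated(scores[ord])
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last_of_group <- c(thr_groups[-1], TRUE)
  curve <- tibble(
    fpr = c(0, fp[last_of_group] / n_neg),
    tpr = c(0, tp[last_of_group] / n_pos),
    threshold = c(Inf, scores[ord][last_of_group])
  )
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "ubi_roc")
}

#' @export
print.ubi_roc <- function(x, ...) {
  cat(sprintf("<ROC: AUC = %.4f, %d positives / %d negatives>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname roc_auc
#' @param x A `ubi_roc` object.
#' @param ... Unused.
#' @method tidy ubi_roc
#' @export
tidy.ubi_roc <- function(x, ...) x$curve

#' @rdname roc_auc
#' @method glance ubi_roc
#' @export
glance.ubi_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

# DeLong structural components: for each positive, the fraction of
# negatives it outranks (ties 1/2), and vice versa.
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  rk <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (rk[seq_len(m)] - rx) / n            # per positive
  v01 <- 1 - (rk[m + seq_len(n)] - ry) / m    # per negative
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's paired test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same sites with
#' the same labels, using the paired structural-components covariance
#' estimator; two-sided p from the normal deviate. Zero variance with equal
#' AUCs (e.g. comparing a score vector with itself) gives `p = 1`.
#'
#' @param scores_a,scores_b Numeric score vectors over the same sites.
#' @param labels Site labels (see [roc_auc()]).
#' @param positive Positive-class label.
#' @return One-row tibble `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "Ub") {
  if (length(scores_a) != length(scores_b)) {
    abort("score vectors must cover the same sites")
  }
  pos <- as_pos_logical(labels, positive)
  ca <- delong_components(scores_a, pos)
  cb <- delong_components(scores_b, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  s <- s10 / m + s01 / n
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- ca$auc - cb$auc
  if (v <= 1e-15) {
    p <- if (abs(d) < 1e-12) 1 else 0
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = ca$auc, auc_b = cb$auc, z = z, p_value = p)
}

#' Fit combination weights by coarse grid search
#'
#' Scans a grid (step `grid_step`, range `[0, 1]`) over the indicator
#' weights and returns the weight vector maximising the AUC of the weighted
#' sum on the supplied (training) sites. Indicators are first linearly
#' scaled to `[0, 1]`. The all-zero corner is excluded; among equal-AUC
#' weightings the first in grid order wins (deterministic).
#'
#' @param indicators Tibble with `label` plus one numeric column per
#'   indicator.
#' @param indicator_cols Names of the indicator columns.
#' @param grid_step Grid step for each weight.
#' @param positive Positive-class label.
#' @return Named weight vector.
#' @export
fit_indicator_weights <- function(indicators,
                                  indicator_cols = setdiff(names(indicators),
                                                           c("site_id", "label", "fold")),
                                  grid_step = 0.25, positive = "Ub") {
  m <- as.matrix(indicators[, indicator_cols, drop = FALSE])
  m <- apply(m, 2, scale_unit_interval)
  pos <- as_pos_logical(indicators$label, positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  grid <- as.matrix(expand.grid(rep(list(seq(0, 1, grid_step)),
                                    length(indicator_cols))))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  # AUC is invariant under positive scaling of the weight vector: keep one
  # representative per direction
  norm <- round(grid / apply(grid, 1, max) * 720)
  grid <- grid[!duplicated(norm %*% 721^(seq_len(ncol(norm)) - 1)), ,
               drop = FALSE]
  best_auc <- -Inf; best <- grid[1, ]
  chunk <- 2000L
  for (start in seq(1, nrow(grid), chunk)) {
    g <- grid[start:min(start + chunk - 1, nrow(grid)), , drop = FALSE]
    s <- m %*% t(g)
    # radix-sort ranks; ties (rare for continuous sums) break by order,
    # which cannot change the argmax materially
    n <- nrow(s)
    aucs <- apply(s, 2, function(col) {
      r <- integer(n)
      r[sort.list(col, method = "radix")] <- seq_len(n)
      (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    })
    i <- which.max(aucs)
    if (aucs[i] > best_auc + 1e-12) {
      best_auc <- aucs[i]; best <- g[i, ]
    }
  }
  setNames(as.numeric(best), indicator_cols)
}

#' Combine indicators into a weighted-sum score
#'
#' Each indicator is linearly scaled to `[0, 1]` and the combined score is
#' the weighted sum. With `weights = NULL` the weights are chosen per
#' cross-validation fold by [fit_indicator_weights()] on the training folds
#' only, and each site's combined score comes from the weights fitted
#' without it. Sites with a missing indicator value are excluded with a
#' report (attribute `"excluded"`).
#'
#' @param indicators Tibble with `site_id`, `label` and one numeric column
#'   per indicator.
#' @param weights Named weight vector covering all indicators, or `NULL`.
#' @param folds,seed Cross-validation parameters (used when `weights` is
#'   `NULL`).
#' @param grid_step Grid step for the per-fold weight search.
#' @param positive Positive-class label.
#' @return Tibble `site_id`, `label`, `combined`, with attributes
#'   `"weights"` (per-fold weight matrix or the supplied vector) and
#'   `"excluded"` (site ids dropped for missing values).
#' @export
combine_indicators <- function(indicators, weights = NULL, folds = 5,
                               seed = 1, grid_step = 0.25, positive = "Ub") {
  indicators <- as_tibble(indicators)
  cols <- setdiff(names(indicators), c("site_id", "label", "fold"))
  if (length(cols) == 0) abort("no indicator columns found")
  if (!is.null(weights)) {
    missing_w <- setdiff(cols, names(weights))
    if (length(missing_w) > 0) {
      abort(paste0("weights missing for: ", paste(missing_w, collapse = ", ")))
    }
  }
  ok <- complete.cases(indicators[, cols])
  excluded <- indicators$site_id[!ok]
  ind <- indicators[ok, ]
  m <- apply(as.matrix(ind[, cols, drop = FALSE]), 2, scale_unit_interval)
  if (!is.null(weights)) {
    out <- tibble(site_id = ind$site_id, label = ind$label,
                  combined = as.numeric(m %*% weights[cols]))
    attr(out, "weights") <- weights[cols]
  } else {
    fold <- stratified_folds(ind$label, folds, seed)
    combined <- numeric(nrow(ind))
    wmat <- matrix(NA_real_, folds, length(cols),
                   dimnames = list(NULL, cols))
    for (f in seq_len(folds)) {
      w <- fit_indicator_weights(ind[fold != f, c("label", cols)],
                                 indicator_cols = cols,
                                 grid_step = grid_step, positive = positive)
      wmat[f, ] <- w
      combined[fold == f] <- as.numeric(m[fold == f, , drop = FALSE] %*% w)
    }
    out <- tibble(site_id = ind$site_id, label = ind$label,
                  combined = combined)
    attr(out, "weights") <- wmat
  }
  attr(out, "excluded") <- excluded
  out
}
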