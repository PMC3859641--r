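# Two-sample statistics: rank-sum test with effect size, Fisher's exact
# test, unit-interval scaling.

#' Rank-sum comparison with effect size
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with the effect size
#' r = Z / sqrt(n1 + n2). For small pooled samples (`n1 + n2 <=
#' exact_max`) the p-value comes from exact enumeration of the permutation
#' distribution of the rank sum (ties handled through midranks); larger
#' samples use the normal approximation with tie correction. The sign
#' convention is the rank-biserial one used for modified-site comparisons:
#' `r` is negative when the first sample is shifted higher.
#'
#' @param x,y Numeric samples (x first, e.g. the modified sites).
#' @param exact_max Largest pooled size for exact enumeration.
#' @return One-row tibble `p_value`, `effect_r`, `n1`, `n2`.
#' @export
wilcoxon_effect <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) abort("both samples need at least one value")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble(p_value = 1, effect_r = 0, n1 = n1, n2 = n2))
  }
  rk <- rank(pooled)
  w1 <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    # exact permutation distribution of the rank sum of sample 1
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(rk[combos], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w1 - mu) - 1e-9)
    z_abs <- if (p >= 1) 0 else -qnorm(p / 2)
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w1 - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    z_abs <- abs(z)
  }
  r <- z_abs / sqrt(n) * if (w1 > mu) -1 else if (w1 < mu) 1 else 0
  tibble(p_value = min(1, p), effect_r = r, n1 = n1, n2 = n2)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables as or less probable
#' than the observed one (the standard two-sided convention). Degenerate
#' margins give `p = 1`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("need a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Linear scaling to the unit interval
#'
#' `(v - min) / (max - min)`; invariant under affine transforms of the
#' input. A constant vector maps to all 0.5 with a warning.
#'
#' @param values Numeric vector.
#' @return Scaled vector in `[0, 1]`.
#' @export
scale_unit_interval <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) == 0) {
    warn("constant vector: scaling to 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / diff(rng)
}
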