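# Rank statistics, naive Bayes scoring, ROC/AUC, DeLong, combination.

test_that("rank-sum test handles the degenerate and tiny exact cases", {
  same <- wilcoxon_effect(c(1, 1, 1), c(1, 1))
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_r, 0)

  tiny <- wilcoxon_effect(c(1, 2), c(3, 4))
  expect_equal(tiny$p_value, 1 / 3) # 2 of 6 arrangements as extreme
  expect_gt(tiny$effect_r, 0)       # first sample shifted LOWER -> r > 0
  hi <- wilcoxon_effect(c(3, 4), c(1, 2))
  expect_lt(hi$effect_r, 0)         # first sample shifted higher -> negative
  expect_equal(abs(hi$effect_r), abs(tiny$effect_r))
})

test_that("exact p-values agree with base wilcox.test on tie-free samples", {
  set.seed(21)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    got <- wilcoxon_effect(x, y)$p_value
    want <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("exact enumeration and the oracle agree, ties included", {
  set.seed(8)
  for (rep in 1:12) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    vals <- sample(1:4, n1 + n2, replace = TRUE) # forces ties
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(wilcoxon_effect(x, y)$p_value, wilcoxon_p_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample approximation tracks the exact enumeration", {
  set.seed(31)
  diffs <- replicate(40, {
    x <- rnorm(10); y <- rnorm(10)
    exact <- wilcoxon_effect(x, y, exact_max = 20)$p_value
    approx <- wilcoxon_effect(x, y, exact_max = 0)$p_value
    abs(approx - exact) / max(exact, 1e-3)
  })
  expect_lt(stats::median(diffs), 0.10)
  expect_lt(mean(diffs > 0.25), 0.10)
})

test_that("the 2x2 exact test matches closed forms and symmetry", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(4)
  for (rep in 1:10) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)))
  }
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1) # zero margin
})

test_that("unit scaling is affine-invariant with a constant-vector warning", {
  expect_equal(scale_unit_interval(c(0, 5, 10)), c(0, 0.5, 1))
  v <- c(0, 0.3, 1)
  expect_equal(scale_unit_interval(v), v)
  expect_equal(scale_unit_interval(3 * v - 7), scale_unit_interval(v))
  expect_warning(out <- scale_unit_interval(c(2, 2, 2)), "constant")
  expect_equal(out, rep(0.5, 3))
})

nb_fixture <- function(n_per_class = 30, signal = TRUE, seed = 17) {
  set.seed(seed)
  sym_pos <- if (signal) "L" else sample(c("L", "E"), n_per_class, TRUE)
  sym_neg <- if (signal) "E" else sample(c("L", "E"), n_per_class, TRUE)
  mk <- function(cls, syms) {
    purrr::map(seq_len(n_per_class), function(i) {
      tibble::tibble(site_id = paste0(cls, i), offset = c(-1L, 0L, 1L),
                     symbol = c(rep(syms, length.out = n_per_class)[i], "K",
                                sample(c("A", "V"), 1)))
    }) |> purrr::list_rbind()
  }
  windows <- dplyr::bind_rows(mk("u", sym_pos), mk("n", sym_neg))
  labels <- tibble::tibble(
    site_id = c(paste0("u", seq_len(n_per_class)),
                paste0("n", seq_len(n_per_class))),
    label = rep(c("Ub", "NonUb"), each = n_per_class)
  )
  list(windows = windows, labels = labels)
}

test_that("positional NB separates signal and is seed-deterministic", {
  fx <- nb_fixture(signal = TRUE, n_per_class = 100)
  sc <- nb_positional_likelihood(fx$windows, fx$labels, folds = 5, seed = 2)
  expect_gt(min(sc$score[sc$label == "Ub"]), max(sc$score[sc$label == "NonUb"]))
  sc2 <- nb_positional_likelihood(fx$windows, fx$labels, folds = 5, seed = 2)
  expect_identical(sc, sc2)
  sc3 <- nb_positional_likelihood(fx$windows, fx$labels, folds = 5, seed = 3)
  expect_false(identical(sc$fold, sc3$fold))

  # uniform symbol usage: scores near zero
  fx0 <- nb_fixture(signal = FALSE)
  sc0 <- nb_positional_likelihood(fx0$windows, fx0$labels, folds = 5, seed = 2)
  expect_lt(max(abs(sc0$score)), 1)

  # training-set duplication leaves scores unchanged up to the Laplace
  # smoothing, which shrinks like 1/n; needs all-positive counts, so use a
  # mixed fixture rather than the all-or-nothing one
  set.seed(41)
  mixed <- nb_fixture(signal = FALSE, n_per_class = 100, seed = 41)
  scm <- nb_positional_likelihood(mixed$windows, mixed$labels, folds = 5,
                                  seed = 2)
  dup <- list(
    windows = dplyr::bind_rows(mixed$windows,
                               dplyr::mutate(mixed$windows,
                                             site_id = paste0(site_id, "d"))),
    labels = dplyr::bind_rows(mixed$labels,
                              dplyr::mutate(mixed$labels,
                                            site_id = paste0(site_id, "d")))
  )
  scd <- nb_positional_likelihood(dup$windows, dup$labels, folds = 5, seed = 2)
  # per-site scores carry fold-sampling noise, so compare class means
  for (cls in c("Ub", "NonUb")) {
    expect_lt(abs(mean(scm$score[scm$label == cls]) -
                    mean(scd$score[scd$label == cls])), 0.05)
  }

  expect_error(nb_positional_likelihood(fx$windows,
                                        dplyr::mutate(fx$labels,
                                                      label = "Ub"),
                                        folds = 5, seed = 1),
               "Ub")
})

test_that("AUC midrank formula matches the curve and known cases", {
  perfect <- roc_auc(c(5, 6, 1, 2), c("Ub", "Ub", "NonUb", "NonUb"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$curve$fpr[1], 0)
  expect_equal(utils::tail(perfect$curve$tpr, 1), 1)

  tied <- roc_auc(c(1, 0, 1, 0), c("Ub", "Ub", "NonUb", "NonUb"))
  expect_equal(tied$auc, 0.5)

  set.seed(9)
  for (rep in 1:20) {
    sc <- sample(rnorm(15), 30, replace = TRUE) # ties likely
    lab <- sample(c("Ub", "NonUb"), 30, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, trapezoid_auc(r), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("Ub", 3)), "class")
})

test_that("DeLong test agrees with pROC and respects rank invariance", {
  set.seed(13)
  lab <- rep(c("Ub", "NonUb"), c(40, 60))
  a <- rnorm(100) + (lab == "Ub") * 0.8
  b <- rnorm(100) + (lab == "Ub") * 0.3
  got <- delong_test(a, b, lab)
  ref <- pROC::roc.test(
    pROC::roc(lab, a, levels = c("NonUb", "Ub"), direction = "<", quiet = TRUE),
    pROC::roc(lab, b, levels = c("NonUb", "Ub"), direction = "<", quiet = TRUE),
    method = "delong"
  )
  expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(got$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)

  self <- delong_test(a, a, lab)
  expect_equal(self$p_value, 1)
  mono <- delong_test(exp(a), a, lab) # strictly monotone transform
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$p_value, 1)
})

test_that("a planted AUC gap is detected with high power", {
  set.seed(5)
  hits <- replicate(40, {
    lab <- rep(c("Ub", "NonUb"), c(250, 250))
    a <- rnorm(500) + (lab == "Ub") * 0.55 # AUC ~ 0.65
    b <- rnorm(500)                        # AUC ~ 0.5
    delong_test(a, b, lab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("weighted combination respects fixed weights and excludes NAs", {
  set.seed(2)
  n <- 80
  lab <- rep(c("Ub", "NonUb"), each = n / 2)
  ind <- tibble::tibble(
    site_id = paste0("s", 1:n), label = lab,
    a = rnorm(n) + (lab == "Ub"), b = rnorm(n)
  )
  one <- combine_indicators(ind[, c("site_id", "label", "a")],
                            weights = c(a = 1))
  expect_equal(one$combined, scale_unit_interval(ind$a))

  # duplicated indicator: same AUC as the single one, any positive weights
  dup <- tibble::tibble(site_id = ind$site_id, label = lab, a = ind$a,
                        b = ind$a)
  cc <- combine_indicators(dup, weights = c(a = 0.25, b = 0.75))
  expect_equal(roc_auc(cc$combined, cc$label)$auc,
               roc_auc(ind$a, lab)$auc)

  withna <- ind; withna$a[3] <- NA
  cn <- combine_indicators(withna, weights = c(a = 0.5, b = 0.5))
  expect_equal(attr(cn, "excluded"), "s3")
  expect_equal(nrow(cn), n - 1)
  expect_error(combine_indicators(ind, weights = c(a = 1)), "missing")
})

test_that("grid search down-weights a pure-noise indicator", {
  set.seed(77)
  wins <- replicate(10, {
    n <- 300
    lab <- rep(c("Ub", "NonUb"), c(100, 200))
    ind <- tibble::tibble(
      site_id = paste0("s", 1:n), label = lab,
      signal = rnorm(n) + (lab == "Ub") * 1.2,
      noise = rnorm(n)
    )
    w <- fit_indicator_weights(ind)
    w["noise"] <= w["signal"]
  })
  expect_gte(sum(wins), 9)
})
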