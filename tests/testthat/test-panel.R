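# Small planted dataset for selection/model tests: n samples, p features,
# the first n_marker features shifted between groups.
planted_xy <- function(n1 = 35, n2 = 19, p = 30, n_marker = 3, effect = 2,
                       seed = 1) {
  set.seed(seed)
  g <- two_groups(n1, n2)
  x <- matrix(stats::rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
  x[g == "PPG", seq_len(n_marker)] <-
    x[g == "PPG", seq_len(n_marker)] + effect
  list(x = x, g = g, markers = sprintf("F%02d", seq_len(n_marker)))
}

test_that("univariate AUC equals exhaustive pair counting, with direction", {
  set.seed(10)
  for (case in 1:100) {
    n <- sample(4:12, 1)
    n1 <- sample(2:(n - 2), 1)
    g <- factor(c(rep("PPG", n1), rep("GPG", n - n1)))
    v <- if (case %% 3 == 0) sample(1:4, n, replace = TRUE) else stats::rnorm(n)
    got <- univariate_auc(v, g)
    a <- auc_bruteforce(v, g)
    expect_equal(got$auc_raw, a, tolerance = 1e-12)
    expect_equal(got$auc, max(a, 1 - a), tolerance = 1e-12)
    expect_identical(got$direction,
                     if (a >= 0.5) "higher_in_PPG" else "higher_in_GPG")
  }
  sep <- univariate_auc(c(1, 2, 8, 9), factor(c("GPG", "GPG", "PPG", "PPG")))
  expect_equal(sep$auc, 1)
  expect_error(univariate_auc(1:4, factor(rep("PPG", 4))), "two classes")
})

test_that("rank AUC agrees with pROC on random score vectors", {
  set.seed(99)
  for (case in 1:10) {
    n <- sample(20:60, 1)
    g <- two_groups(ceiling(n / 2), floor(n / 2))
    s <- stats::rnorm(n)
    ours <- univariate_auc(s, g)$auc_raw
    ref <- as.numeric(pROC::auc(pROC::roc(g, s, levels = c("GPG", "PPG"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("empirical ROC trapezoid AUC equals the rank AUC", {
  set.seed(11)
  for (case in 1:20) {
    n <- sample(6:40, 1)
    g <- two_groups(ceiling(n / 2), floor(n / 2))
    s <- round(stats::runif(n), sample(c(1, 2, 8), 1))  # force some ties
    roc <- multivariate_roc(s, g)
    expect_equal(roc$auc, univariate_auc(s, g)$auc_raw, tolerance = 1e-12)
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(utils::tail(roc$fpr, 1), utils::tail(roc$tpr, 1)), c(1, 1))
  }
  g2 <- two_groups(3, 3)
  s2 <- c(0, 0, 0, 1, 1, 1)
  expect_equal(multivariate_roc(s2, g2)$auc, 1)
  expect_equal(multivariate_roc(1 - s2, g2)$auc, 0)   # before orientation
})

test_that("backward elimination finds planted markers and is deterministic", {
  d <- planted_xy()
  tab <- aucrf_select(d$x, d$g, ntree_rank = 500, cv_repeats = 3, seed = 42)
  expect_true(all(d$markers %in% tab$protein_id))
  expect_true(all(tab$protein_id %in% colnames(d$x)))
  expect_lte(nrow(tab), ncol(d$x))
  expect_true(all(tab$prob_select >= 0 & tab$prob_select <= 1))
  expect_identical(tab$selected, tab$importance > attr(tab, "threshold"))
  expect_true(all(d$markers %in% filter_by_importance(tab, 0.3)))
  path <- attr(tab, "path")
  expect_equal(path$size[1], ncol(d$x))

  tab2 <- aucrf_select(d$x, d$g, ntree_rank = 500, cv_repeats = 3, seed = 42)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("a duplicated marker splits its selection probability", {
  d <- planted_xy(p = 15, n_marker = 1, effect = 3, seed = 2)
  x_dup <- cbind(d$x, F_dup = d$x[, "F01"] + stats::rnorm(nrow(d$x), 0, 1e-6))
  single <- aucrf_select(d$x, d$g, ntree_rank = 500, cv_repeats = 5, seed = 3)
  dup <- aucrf_select(x_dup, d$g, ntree_rank = 500, cv_repeats = 5, seed = 3)
  p_single <- single$prob_select[single$protein_id == "F01"]
  p_pair <- dup$prob_select[dup$protein_id %in% c("F01", "F_dup")]
  expect_length(p_pair, 2)
  expect_true(all(p_pair <= p_single))
})

test_that("importance filter thresholds strictly and orders by importance", {
  tab <- dkd_panel_ranking()
  expect_identical(filter_by_importance(tab, 0.4), "CTSA")
  expect_identical(filter_by_importance(tab, 1), character(0))
  got <- filter_by_importance(tab, 0.3)
  expect_identical(got, c("CTSA", "SPARCL1", "GM2A", "MUC1", "ACP2"))
})

test_that("panel models separate separable data and are reproducible", {
  d <- planted_xy(p = 5, n_marker = 5, effect = 6, seed = 4)
  for (kind in c("rf", "svm")) {
    m <- train_panel_model(d$x, d$g, kind, cv_repeats = 2, seed = 5)
    expect_equal(m$resub_auc, 1)
    s <- predict_scores(m, d$x)
    expect_true(all(s >= 0 & s <= 1))
    m2 <- train_panel_model(d$x, d$g, kind, cv_repeats = 2, seed = 5)
    expect_identical(predict_scores(m2, d$x), s)
    expect_gt(m$cv$cv_auc, 0.9)
  }
})

test_that("constant features are dropped; degenerate labels rejected", {
  d <- planted_xy(p = 4, seed = 6)
  x <- cbind(d$x, CONST = 1)
  expect_warning(m <- train_panel_model(x, d$g, "rf", cv_repeats = 0, seed = 1),
                 "constant")
  expect_false("CONST" %in% m$feature_ids)
  expect_error(train_panel_model(d$x, factor(rep("PPG", nrow(d$x))), "rf"),
               "two-level")
  expect_error(predict_scores(m, d$x[, 1:2, drop = FALSE]), "missing model feature")
})

test_that("random-forest score equals the manual vote fraction", {
  d <- planted_xy(p = 4, seed = 7)
  m <- train_panel_model(d$x, d$g, "rf", ntree = 10, cv_repeats = 0, seed = 8)
  xs <- scale(d$x[, m$feature_ids], m$center, m$scale)
  votes <- stats::predict(m$fit, xs, predict.all = TRUE)$individual
  manual <- rowMeans(votes == "PPG")
  expect_equal(unname(predict_scores(m, d$x)), unname(manual), tolerance = 1e-12)
})

test_that("scores are invariant to affine rescaling of a training feature", {
  d <- planted_xy(p = 5, n_marker = 2, seed = 9)
  x2 <- d$x
  x2[, "F03"] <- 1000 * x2[, "F03"] + 5
  for (kind in c("rf", "svm")) {
    m1 <- train_panel_model(d$x, d$g, kind, cv_repeats = 0, seed = 10)
    m2 <- train_panel_model(x2, d$g, kind, cv_repeats = 0, seed = 10)
    expect_equal(unname(predict_scores(m1, d$x)), unname(predict_scores(m2, x2)),
                 tolerance = 1e-6)
  }
})

test_that("likelihood-ratio comparison matches a Newton-Raphson oracle", {
  set.seed(12)
  n <- 20
  g <- two_groups(10, 10)
  y <- as.numeric(g == "PPG")
  base <- y * 0.4 + stats::runif(n)
  new <- y * 0.3 + stats::runif(n)
  got <- lrt_compare(base, new, g)
  ll0 <- logistic_ll_oracle(cbind(1, base), y)
  ll1 <- logistic_ll_oracle(cbind(1, base, new), y)
  expect_false(got$separation)
  expect_equal(got$statistic, 2 * (ll1 - ll0), tolerance = 1e-6)
  expect_equal(got$p, stats::pchisq(got$statistic, 1, lower.tail = FALSE))

  same <- lrt_compare(base, base, g)
  expect_lt(same$statistic, 1e-6)
  expect_gt(same$p, 0.99)

  perfect <- lrt_compare(stats::runif(n), y, g)
  expect_true(perfect$separation)
  expect_lt(perfect$p, 0.001)
})

test_that("panel models survive a JSON round trip with identical scores", {
  d <- planted_xy(p = 5, n_marker = 2, seed = 13)
  newdata <- planted_xy(p = 5, n_marker = 2, seed = 14)$x
  for (kind in c("rf", "svm")) {
    m <- train_panel_model(d$x, d$g, kind, ntree = 50, cv_repeats = 0, seed = 15)
    path <- withr::local_tempfile(fileext = ".json")
    write_panel_model(m, path)
    m2 <- read_panel_model(path)
    expect_null(m2$fit)
    expect_equal(unname(predict_scores(m2, newdata)),
                 unname(predict_scores(m, newdata)), tolerance = 1e-10)
  }
})
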