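meta_of <- function(x, creatinine, total_protein = 1,
                    group = two_groups(ncol(x$values) / 2, ncol(x$values) / 2)) {
  data.frame(sample_id = colnames(abundance_values(x)),
             group = group,
             creatinine = rep_len(creatinine, ncol(abundance_values(x))),
             total_protein = rep_len(total_protein, ncol(abundance_values(x))))
}

test_that("corrected LFQ divides by the per-sample amounts", {
  x <- random_abundance(4, 6, seed = 1, stage = "raw")
  x$values[1, 2] <- NA
  m1 <- meta_of(x, creatinine = 1)
  expect_equal(abundance_values(correct_lfq(x, m1, "creatinine")),
               abundance_values(x))
  v <- abundance_values(x)
  m2 <- meta_of(x, creatinine = 2, total_protein = 3)
  expect_equal(abundance_values(correct_lfq(x, m2, "creatinine")), v / 2)
  expect_equal(abundance_values(correct_lfq(x, m2, "both")), v / 6)
  expect_true(is.na(abundance_values(correct_lfq(x, m2, "both"))[1, 2]))
  expect_identical(abundance_stage(correct_lfq(x, m2)), "corrected")
  m2$creatinine[3] <- 0
  expect_error(correct_lfq(x, m2, "creatinine"), "S03")
})

test_that("10 / 2 = 5 under creatinine correction", {
  x <- abundance_matrix(matrix(10, 1, 2, dimnames = list("P1", c("S1", "S2"))))
  meta <- data.frame(sample_id = c("S1", "S2"), creatinine = 2)
  expect_equal(unname(abundance_values(correct_lfq(x, meta, "creatinine"))[1, ]),
               c(5, 5))
})

test_that("NormFinder stability matches an independent transcription", {
  set.seed(42)
  for (case in 1:5) {
    x <- random_abundance(15, 12, stage = "corrected")
    g <- two_groups()
    got <- normfinder_stability(x, g)
    want <- normfinder_oracle(abundance_values(x), g)
    expect_equal(got$stability[match(want$protein_id, got$protein_id)],
                 want$stability, tolerance = 1e-12)
  }
})

test_that("a constant candidate is most stable; a shifted one least", {
  set.seed(5)
  n <- 20
  g <- two_groups(10, 10)
  v <- matrix(2^stats::rnorm(21 * n, 20, 0.8), 21, n,
              dimnames = list(sprintf("P%03d", 1:21), sprintf("S%02d", 1:n)))
  v["P001", ] <- 2^20                               # zero variance
  st <- normfinder_stability(abundance_matrix(v, "corrected"), g)
  expect_identical(st$protein_id[1], "P001")

  # equal-variance candidates, one with a planted group shift
  v2 <- matrix(2^(stats::rnorm(10 * n, 20, 0.5)), 10, n,
               dimnames = list(sprintf("Q%02d", 1:10), sprintf("S%02d", 1:n)))
  v2["Q05", g == "PPG"] <- v2["Q05", g == "PPG"] * 2^2
  st2 <- normfinder_stability(abundance_matrix(v2, "corrected"), g)
  expect_identical(st2$protein_id[nrow(st2)], "Q05")
})

test_that("identical group distributions give near-zero intergroup components", {
  set.seed(6)
  x <- random_abundance(12, 30, stage = "corrected")
  st <- normfinder_stability(x, two_groups(15, 15))
  expect_lt(max(st$intergroup), 0.2)
  expect_gt(stats::cor(st$stability, st$intragroup_se), 0.9)
})

test_that("normalization-protein selection applies the three criteria in order", {
  co <- generate_cohort(cohort_config(n_proteins = 300, seed = 7))
  corrected <- correct_lfq(co$abundance, co$meta)
  res <- select_normalization_proteins(corrected, co$meta$group)
  expect_setequal(res$norm_protein_ids, co$truth$norm_protein_ids)

  # criterion 1: one missing entry disqualifies even the most stable protein
  v <- abundance_values(corrected)
  v[co$truth$norm_protein_ids[1], 1] <- NA
  res1 <- select_normalization_proteins(abundance_matrix(v, "corrected"),
                                        co$meta$group)
  expect_false(co$truth$norm_protein_ids[1] %in% res1$norm_protein_ids)
  expect_false(co$truth$norm_protein_ids[1] %in% res1$candidates)

  # criterion 2: a strong group shift excludes a complete, stable protein
  v2 <- abundance_values(corrected)
  shifted <- co$truth$norm_protein_ids[2]
  v2[shifted, co$meta$group == "PPG"] <- v2[shifted, co$meta$group == "PPG"] * 4
  res2 <- select_normalization_proteins(abundance_matrix(v2, "corrected"),
                                        co$meta$group)
  expect_true(shifted %in% res2$excluded_by_test)
  expect_false(shifted %in% res2$norm_protein_ids)
})

test_that("selection fails informatively when too few candidates survive", {
  x <- random_abundance(4, 8, seed = 8)
  expect_error(select_normalization_proteins(x, two_groups(4, 4), n_select = 6),
               "survive")
})

test_that("NSF is the median of the six reference ratios", {
  med <- c(10, 20, 30, 40, 50, 60)
  r2 <- c(0.5, 0.8, 1.0, 1.2, 1.5, 2.0)
  v <- cbind(S1 = med, S2 = med * r2, S3 = med)
  rownames(v) <- sprintf("N%d", 1:6)
  res <- compute_nsf(abundance_matrix(v, "corrected"), rownames(v))
  expect_equal(unname(res$nsf_by_sample),
               c(1, 1.1, 1))                       # median of even set = central mean
  expect_equal(unname(res$protein_medians), med)

  all_same <- abundance_matrix(cbind(S1 = med, S2 = med, S3 = med,
                                     S4 = med) |>
                                 `rownames<-`(sprintf("N%d", 1:6)), "corrected")
  expect_true(all(compute_nsf(all_same, sprintf("N%d", 1:6))$nsf_by_sample == 1))
})

test_that("apply_nsf rescales, drops reference proteins, keeps missing", {
  co <- generate_cohort(cohort_config(n_proteins = 120, seed = 9))
  corrected <- correct_lfq(co$abundance, co$meta)
  res <- compute_nsf(corrected, co$truth$norm_protein_ids)
  normd <- apply_nsf(corrected, res)
  expect_identical(abundance_stage(normd), "normalized")
  expect_false(any(co$truth$norm_protein_ids %in% rownames(abundance_values(normd))))
  keep <- apply_nsf(corrected, res, drop_norm_proteins = FALSE)
  expect_true(all(co$truth$norm_protein_ids %in% rownames(abundance_values(keep))))
  j <- rownames(abundance_values(normd))
  expect_equal(abundance_values(normd),
               sweep(abundance_values(corrected)[j, ], 2, res$nsf_by_sample, "/"))
  expect_identical(is.na(abundance_values(normd)),
                   is.na(abundance_values(corrected)[j, ]))
  # unit NSF is the identity
  v <- abundance_values(corrected)
  unit <- stats::setNames(rep(1, ncol(v)), colnames(v))
  expect_equal(abundance_values(apply_nsf(corrected, unit)), v)
})

test_that("post-normalization reference ratios have median exactly one", {
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(n_proteins = 150, seed = s))
    corrected <- correct_lfq(co$abundance, co$meta)
    res <- compute_nsf(corrected, co$truth$norm_protein_ids)
    normd <- apply_nsf(corrected, res, drop_norm_proteins = FALSE)
    ratios <- sweep(abundance_values(normd)[co$truth$norm_protein_ids, ], 1,
                    res$protein_medians, "/")
    expect_equal(unname(apply(ratios, 2, stats::median)),
                 rep(1, ncol(ratios)), tolerance = 1e-12)
  }
})

test_that("normalization is equivariant to per-sample rescaling", {
  co <- generate_cohort(cohort_config(n_proteins = 100, missing_rate = 0, seed = 10))
  corrected <- correct_lfq(co$abundance, co$meta)
  v <- abundance_values(corrected)
  res <- compute_nsf(corrected, co$truth$norm_protein_ids)
  v2 <- v
  v2[, 5] <- v2[, 5] * 3
  # frozen reference medians: the property is exact against a fixed cohort
  res2 <- compute_nsf(abundance_matrix(v2, "corrected"), res)
  expect_equal(res2$nsf_by_sample[5], 3 * res$nsf_by_sample[5], tolerance = 1e-12)
  expect_equal(abundance_values(apply_nsf(abundance_matrix(v2, "corrected"), res2)),
               abundance_values(apply_nsf(corrected, res)), tolerance = 1e-12)
})

test_that("normalization shrinks between-sample variation of null proteins", {
  wins <- 0L
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(n_proteins = 150, missing_rate = 0,
                                        seed = 100 + s))
    nr <- normalize_abundance(co$abundance, co$meta)
    null_ids <- setdiff(rownames(abundance_values(nr$normalized)),
                        co$truth$marker_ids)
    cv <- function(m) apply(m, 1, function(r) stats::sd(r) / mean(r))
    cv_corr <- stats::median(cv(abundance_values(nr$corrected)[null_ids, ]))
    cv_norm <- stats::median(cv(abundance_values(nr$normalized)[null_ids, ]))
    wins <- wins + (cv_norm < cv_corr)
  }
  expect_gte(wins, 4L)
})
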