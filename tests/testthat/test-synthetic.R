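test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(n_proteins = 100, seed = 1))
  b <- generate_cohort(cohort_config(n_proteins = 100, seed = 1))
  expect_identical(abundance_values(a$abundance), abundance_values(b$abundance))
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$marker_ids, b$truth$marker_ids)
  c <- generate_cohort(cohort_config(n_proteins = 100, seed = 2))
  expect_false(identical(abundance_values(a$abundance),
                         abundance_values(c$abundance)))
})

test_that("missing_rate = 0 yields a complete matrix", {
  co <- generate_cohort(cohort_config(n_proteins = 80, missing_rate = 0, seed = 3))
  expect_false(anyNA(abundance_values(co$abundance)))
})

test_that("MNAR masking hits low-abundance entries preferentially", {
  co <- generate_cohort(cohort_config(seed = 7))
  lg <- log2(co$truth$complete)
  non_norm <- !(rownames(lg) %in% co$truth$norm_protein_ids)
  masked <- co$truth$masked[non_norm, ]
  expect_lt(mean(lg[non_norm, ][masked]), mean(lg[non_norm, ][!masked]))
})

test_that("missingness probability is non-increasing across abundance deciles", {
  co <- generate_cohort(cohort_config(n_proteins = 2000, seed = 11))
  lg <- log2(co$truth$complete)
  non_norm <- !(rownames(lg) %in% co$truth$norm_protein_ids)
  x <- lg[non_norm, ]
  m <- co$truth$masked[non_norm, ]
  dec <- cut(x, breaks = stats::quantile(x, 0:10 / 10), include.lowest = TRUE)
  frac <- tapply(as.vector(m), dec, mean)
  expect_true(all(diff(frac) <= 0.01))
  expect_gt(frac[1], frac[10])
})

test_that("normalization proteins are near-constant, never missing, no group shift", {
  co <- generate_cohort(cohort_config(n_proteins = 400, seed = 5))
  v <- abundance_values(co$abundance)
  norm <- co$truth$norm_protein_ids
  expect_false(anyNA(v[norm, ]))
  # intrinsic CV (without sample factors) below the median protein's CV
  base <- 2^co$truth$log2_base
  cv <- apply(base, 1, function(r) stats::sd(r) / mean(r))
  expect_true(all(cv[norm] < stats::median(cv)))
  expect_true(all(cv[norm] <= 0.05 * 1.5))  # sampling slack around the 4% target
})

test_that("planted markers shift between groups; non-markers center on zero", {
  co <- generate_cohort(cohort_config(n_proteins = 600, seed = 13))
  lg <- co$truth$log2_base
  ppg <- co$truth$true_group[colnames(lg)] == "PPG"
  fc <- rowMeans(lg[, ppg]) - rowMeans(lg[, !ppg])
  mk <- co$truth$marker_ids
  expect_true(all(abs(fc[mk]) > 0.25))
  expect_true(all(sign(fc[mk]) == co$truth$marker_direction[mk]))
  others <- setdiff(rownames(lg), c(mk, co$truth$norm_protein_ids))
  expect_lt(abs(mean(fc[others])), 0.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(n_proteins = 5, n_markers = 4, n_norm_proteins = 3),
               "exceeds n_proteins")
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_config(n_good = 0), "positive count")
  expect_error(cohort_config(mnar_strength = -1), "mnar_strength")
  expect_error(cohort_config(creatinine_mean = -5), "creatinine_mean")
})

test_that("expression generator plants shifts where asked and is reproducible", {
  genes <- c("ACP2", "MUC1")
  eff <- matrix(c(0, 2), 1, 2, dimnames = list("MUC1", c("CTL", "DN")))
  a <- generate_expression_dataset(c(CTL = 30, DN = 30), genes, eff, seed = 4)
  b <- generate_expression_dataset(c(CTL = 30, DN = 30), genes, eff, seed = 4)
  expect_identical(a$matrix, b$matrix)
  expect_false(anyNA(a$matrix))
  expect_true(all(genes %in% rownames(a$matrix)))
  mu_dn <- mean(a$matrix["MUC1", a$labels == "DN"])
  mu_ctl <- mean(a$matrix["MUC1", a$labels == "CTL"])
  expect_gt(mu_dn, mu_ctl)
  # no planted effect: means equal within sampling error
  d_acp2 <- mean(a$matrix["ACP2", a$labels == "DN"]) -
    mean(a$matrix["ACP2", a$labels == "CTL"])
  expect_lt(abs(d_acp2), 4 / sqrt(30))
  expect_error(generate_expression_dataset(c(CTL = 5), character(0)), "nonempty")
})

test_that("eGFR trajectories follow baseline, slope and noise settings", {
  tr <- generate_egfr_trajectories(3, baseline_mean = 90, baseline_sd = 0,
                                   slope = 0, noise_sd = 0, seed = 1)
  expect_true(all(tr$egfr == 90))
  tr2 <- generate_egfr_trajectories(1, baseline_mean = 90, baseline_sd = 0,
                                    slope = -15, follow_years = 2.5,
                                    noise_sd = 0, seed = 1)
  expect_lt(min(tr2$egfr), 60)
  a <- generate_egfr_trajectories(5, seed = 9)
  b <- generate_egfr_trajectories(5, seed = 9)
  expect_identical(a, b)
  expect_error(generate_egfr_trajectories(3, follow_years = 0), "follow_years")
})
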