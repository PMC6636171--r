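test_that("manifest generation is deterministic and honours flag fractions", {
  m1 <- generate_manifest(10000, seed = 7)
  m2 <- generate_manifest(10000, seed = 7)
  expect_identical(m1, m2)

  m <- generate_manifest(10000, list(sex_chrom = 0.03), seed = 1)
  n_sex <- sum(m$chrom %in% c("chrX", "chrY"))
  expect_gte(n_sex, 280)
  expect_lte(n_sex, 320)
  expect_identical(m$sex_chrom_flag, m$chrom %in% c("chrX", "chrY"))

  m3 <- generate_manifest(20000, list(snp_5bp = 0.05), seed = 3)
  frac <- mean(m3$snp_5bp_flag)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)

  # positions sorted within chromosome, unique probe ids
  expect_false(anyDuplicated(m$probe_id) > 0)
  by_chr <- split(m$pos, m$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("manifest generation rejects bad parameters", {
  expect_error(generate_manifest(50, seed = 1), class = "methsig_parameter_error")
  expect_error(generate_manifest(1000, list(snp_5bp = 1.2), seed = 1),
               class = "methsig_parameter_error")
  expect_error(generate_manifest(1000, list(bogus = 0.1), seed = 1),
               class = "methsig_parameter_error")
})

test_that("cell-type reference guarantees the requested marker contrast", {
  ref <- generate_celltype_reference(6, 600, separation = 0.3, seed = 4)
  contrast <- apply(ref$mean_beta, 2, function(v) max(v) - min(v))
  expect_true(all(contrast >= 0.3 - 1e-12))
  expect_true(all(ref$mean_beta >= 0 & ref$mean_beta <= 1))

  # degenerate separation is allowed, determinism holds
  ref0 <- generate_celltype_reference(3, 40, separation = 0, seed = 5)
  expect_true(all(ref0$mean_beta >= 0 & ref0$mean_beta <= 1))
  expect_identical(generate_celltype_reference(4, 50, 0.2, seed = 9),
                   generate_celltype_reference(4, 50, 0.2, seed = 9))
  expect_error(generate_celltype_reference(4, 50, separation = 1, seed = 1),
               class = "methsig_parameter_error")
  expect_error(generate_celltype_reference(4, 10, 0.2, seed = 1),
               class = "methsig_parameter_error")
})

test_that("cohorts carry exact truth deltas and betas stay inside (0,1)", {
  man <- generate_manifest(2000, seed = 2)
  ok <- man$probe_id[!(man$sex_chrom_flag | man$cross_reactive_flag |
                         man$snp_5bp_flag | man$nonspecific_flag)]
  targets <- ok[seq(1, 300, by = 3)]
  eff <- effect_spec(targets, c(0.08, 0.23))
  coh <- generate_cohort(man, 9, 23, effects = eff, seed = 11)

  expect_true(all(coh$beta > 0 & coh$beta < 1))
  expect_false(anyNA(coh$beta))

  tr <- coh$truth$probes
  planted <- tr[tr$planted, ]
  expect_setequal(planted$probe_id, targets)
  # generating means for both groups stay strictly inside (0,1), so the
  # recorded delta is exactly case mean - control mean on the pre-noise scale
  expect_true(all(planted$baseline > 0 & planted$baseline < 1))
  expect_true(all(planted$baseline + planted$delta > 0 &
                    planted$baseline + planted$delta < 1))
  expect_true(all(abs(planted$delta) >= 0.08 & abs(planted$delta) <= 0.23))

  # empirical deltas at planted probes near truth
  grp <- coh$samples$group[match(colnames(coh$beta), coh$samples$sample_id)]
  emp <- rowMeans(coh$beta[planted$probe_id, grp == "case"]) -
    rowMeans(coh$beta[planted$probe_id, grp == "control"])
  se <- 0.03 * sqrt(1 / 9 + 1 / 23)
  expect_true(all(abs(emp) > 0.08 - 3 * se & abs(emp) < 0.23 + 3 * se))
})

test_that("null cohorts show only noise-scale group differences", {
  man <- generate_manifest(500, seed = 3)
  coh <- generate_cohort(man, 8, 8, effects = NULL, noise_sd = 0.03, seed = 6)
  grp <- coh$samples$group[match(colnames(coh$beta), coh$samples$sample_id)]
  d <- rowMeans(coh$beta[, grp == "case"]) - rowMeans(coh$beta[, grp == "control"])
  expect_lt(mean(abs(d)), 3 * 0.03 / sqrt(16))
  expect_true(all(coh$truth$probes$delta == 0))
})

test_that("batch offsets shift per-batch means as specified", {
  man <- generate_manifest(800, seed = 4)
  cov <- covariate_spec(batches = c(b1 = 0, b2 = 0.05))
  coh <- generate_cohort(man, 10, 10, covariates = cov, noise_sd = 0.02,
                         seed = 8)
  sheet <- coh$samples
  b1 <- sheet$sample_id[sheet$batch == "b1"]
  b2 <- sheet$sample_id[sheet$batch == "b2"]
  diff_means <- rowMeans(coh$beta[, b2, drop = FALSE]) -
    rowMeans(coh$beta[, b1, drop = FALSE])
  # averaged over probes the planted batch shift is recovered closely
  expect_lt(abs(mean(diff_means) - 0.05), 0.005)
})

test_that("cohort generation validates targets and sizes", {
  man <- generate_manifest(300, seed = 5)
  expect_error(
    generate_cohort(man, 1, 5, seed = 1),
    class = "methsig_parameter_error")
  expect_error(
    generate_cohort(man, 5, 5,
                    effects = effect_spec("cg_missing", c(0.1, 0.2)),
                    seed = 1),
    class = "methsig_reference_error")
  man2 <- man
  man2$snp_5bp_flag[1] <- TRUE
  expect_error(
    generate_cohort(man2, 5, 5,
                    effects = effect_spec(man2$probe_id[1], c(0.1, 0.2)),
                    seed = 1),
    class = "methsig_parameter_error")
})

test_that("draw_samples reuses the stored generative model", {
  man <- generate_manifest(600, seed = 6)
  ok <- man$probe_id[!(man$sex_chrom_flag | man$cross_reactive_flag |
                         man$snp_5bp_flag | man$nonspecific_flag)]
  eff <- effect_spec(ok[1:40], c(0.1, 0.2))
  coh <- generate_cohort(man, 5, 5, effects = eff, seed = 9)
  tr <- coh$truth$probes

  cases <- draw_samples(coh, 30, "case", seed = 10)
  ctrls <- draw_samples(coh, 30, "control", seed = 10)
  planted <- tr$probe_id[tr$planted]
  emp <- rowMeans(cases$beta[planted, ]) - rowMeans(ctrls$beta[planted, ])
  expect_lt(max(abs(emp - tr$delta[tr$planted])), 0.035)
  expect_true(all(ctrls$samples$group == "control"))
  expect_identical(draw_samples(coh, 3, "control", seed = 2)$beta,
                   draw_samples(coh, 3, "control", seed = 2)$beta)
})

test_that("effect and covariate specs validate their invariants", {
  expect_error(effect_spec("cg1", c(0.3, 0.2)),
               class = "methsig_parameter_error")
  expect_error(effect_spec("cg1", c(0, 0.2)),
               class = "methsig_parameter_error")
  expect_error(effect_spec("cg1", c(0.1, 0.2), direction_mix = 1.5),
               class = "methsig_parameter_error")
  expect_error(covariate_spec(age_range = c(10, 5)),
               class = "methsig_parameter_error")
  expect_error(covariate_spec(batches = c(0, 0.1)),
               class = "methsig_parameter_error")
})
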