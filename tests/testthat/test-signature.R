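test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:1000, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "methsig_parameter_error")
})

test_that("Mann-Whitney per probe reproduces exact and worked p-values", {
  # cases {0.9, 0.8, 0.7} vs controls {0.1, 0.2}: maximal U = 6, p = 0.2
  beta <- make_beta(matrix(c(0.9, 0.8, 0.7, 0.1, 0.2), 1, 5))
  res <- mann_whitney_per_probe(beta, c("case", "case", "case",
                                        "control", "control"))
  expect_equal(res$U, 6)
  expect_equal(res$p, 0.2)
  expect_true(res$exact)

  # complete overlap (all values equal) -> U = n1 n2 / 2, p = 1
  tie <- make_beta(matrix(0.5, 1, 6))
  res_tie <- mann_whitney_per_probe(tie, rep(c("case", "control"), each = 3))
  expect_equal(res_tie$U, 4.5)
  expect_equal(res_tie$p, 1)
  expect_false(res_tie$exact)

  expect_error(
    mann_whitney_per_probe(make_beta(matrix(runif(4), 1, 4)),
                           c("case", rep("control", 3))),
    class = "methsig_parameter_error")
})

test_that("exact Mann-Whitney p equals exhaustive enumeration for n1, n2 <= 6", {
  set.seed(21)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- round(runif(n1 + n2), 6)      # continuous, ties absent
      beta <- make_beta(matrix(x, 1))
      groups <- rep(c("case", "control"), c(n1, n2))
      res <- mann_whitney_per_probe(beta, groups)
      oracle <- mwu_exact_oracle(x[seq_len(n1)], x[-seq_len(n1)])
      expect_equal(res$p, oracle, tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("delta beta is the plain group mean difference", {
  beta <- make_beta(rbind(c(0.60, 0.64, 0.50, 0.50),
                          c(0.30, 0.30, 0.30, 0.30)))
  d <- compute_delta_beta(beta, c("case", "case", "control", "control"))
  expect_equal(d$delta, c(0.12, 0))
  expect_error(compute_delta_beta(beta, rep("control", 4)),
               class = "methsig_parameter_error")
})

test_that("moderated model handles the shrinkage limits exactly", {
  # identical residual variance on every probe: estimated prior df is
  # infinite and the moderated t equals the ordinary t with common variance
  e <- c(-0.02, 0, 0.02)
  rows <- rbind(c(0.40 + e, 0.50 + e),
                c(0.60 + e, 0.55 + e),
                c(0.30 + e, 0.38 + e),
                c(0.52 + e, 0.47 + e))
  beta <- make_beta(rows)
  sheet <- make_sheet(beta, rep(c("case", "control"), each = 3),
                      age = rep(10, 6), sex = "M")
  # ages chosen so no covariate column is collinear with the shared
  # residual pattern (which would zero out every residual)
  sheet$age <- c(7, 12, 9, 8, 14, 10)
  sheet$sex <- rep(c("M", "F"), 3)

  fit <- fit_moderated_model(beta, sheet)
  expect_true(is.infinite(fit$df_prior))
  expect_equal(fit$s2_prior, mean(fit$table$sigma2))
  # all sigma2 equal -> shrinkage is a no-op up to the common value
  expect_equal(stats::var(fit$table$sigma2), 0, tolerance = 1e-20)

  # forcing prior df to zero gives the ordinary per-probe t
  fit0 <- fit_moderated_model(beta, sheet, prior_df = 0)
  X <- fit0$design
  ols_t <- apply(beta, 1, function(y) {
    f <- stats::lm(y ~ X - 1)
    summary(f)$coefficients["Xgroup", "t value"]
  })
  expect_equal(fit0$table$t, unname(ols_t), tolerance = 1e-10)

  collinear <- sheet
  collinear$age <- as.numeric(collinear$sex == "M")
  expect_error(fit_moderated_model(beta, collinear),
               class = "methsig_parameter_error")
})

test_that("moderated statistics agree with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(31)
  n <- 16
  beta <- make_beta(matrix(runif(300 * n, 0.2, 0.8), 300, n))
  sheet <- make_sheet(beta, rep(c("case", "control"), each = n / 2))
  fit <- fit_moderated_model(beta, sheet)

  X <- fit$design
  lf <- limma::eBayes(limma::lmFit(beta, X))
  expect_equal(fit$df_prior, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s2_prior, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lf$t[, "group"]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lf$p.value[, "group"]), tolerance = 1e-8)
})

test_that("moderated test is calibrated under the null", {
  set.seed(5)
  n <- 30
  beta <- make_beta(matrix(
    pmin(pmax(runif(5000, 0.2, 0.8) + rnorm(5000 * n, 0, 0.03), 0), 1),
    5000, n))
  sheet <- make_sheet(beta, rep(c("case", "control"), each = 15))
  fit <- fit_moderated_model(beta, sheet)
  frac <- mean(fit$table$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("signature derivation applies strict intersection semantics", {
  probe_ids <- sprintf("cg%03d", 1:4)
  fit <- structure(list(table = tibble::tibble(
    probe_id = probe_ids,
    delta_adj = c(0.1, 0.1, 0.1, 0.1), sigma2 = 1, t = 1, df_total = 10,
    p = c(0.001, 0.001, 0.2, 0.001),
    q = c(0.01, 0.01, 0.40, 0.001))), class = "methsig_modfit")
  mwu <- tibble::tibble(probe_id = probe_ids, U = 1,
                        p = c(0.01, 0.08, 0.01, 0.001),
                        q = c(0.04, 0.20, 0.04, 0.001), exact = TRUE)
  deltas <- tibble::tibble(probe_id = probe_ids,
                           delta = c(0.10, 0.10, 0.10, 0.04))

  # probe 1: passes all three; probe 2 fails MWU q; probe 3 fails model q;
  # probe 4 fails the effect-size requirement
  sig <- derive_signature(fit, mwu, deltas, q_thresh = 0.05,
                          delta_thresh = 0.05)
  expect_equal(sig$probe_id, "cg001")
  expect_equal(sig$direction, "hyper")

  # unadjusted mode replaces both q conditions with the raw model p
  sig_u <- derive_signature(fit, mwu, deltas, q_thresh = 0.001,
                            delta_thresh = 0.05, mode = "unadjusted_p")
  expect_equal(nrow(sig_u), 0)
  sig_u2 <- derive_signature(fit, mwu, deltas, q_thresh = 0.01,
                             delta_thresh = 0.05, mode = "unadjusted_p")
  expect_setequal(sig_u2$probe_id, c("cg001", "cg002"))

  expect_error(derive_signature(fit, mwu[-1, ], deltas),
               class = "methsig_parameter_error")
})

test_that("stricter q threshold derives a subset signature", {
  man <- generate_manifest(3000, seed = 12)
  ok <- man$probe_id[!(man$sex_chrom_flag | man$cross_reactive_flag |
                         man$snp_5bp_flag | man$nonspecific_flag)]
  eff <- effect_spec(ok[seq(1, 600, 4)], c(0.05, 0.3))
  coh <- generate_cohort(man, 7, 21, effects = eff, seed = 13)
  vf <- variance_filter(filter_probes(coh$beta, man)$beta, 0.02)
  fit <- fit_moderated_model(vf$beta, coh$samples)
  mwu <- mann_whitney_per_probe(vf$beta, coh$samples)
  del <- compute_delta_beta(vf$beta, coh$samples)
  sig05 <- derive_signature(fit, mwu, del, q_thresh = 0.05)
  sig01 <- derive_signature(fit, mwu, del, q_thresh = 0.01)
  expect_gt(nrow(sig01), 0)
  expect_true(all(sig01$probe_id %in% sig05$probe_id))
  expect_lte(nrow(sig01), nrow(sig05))
  # directions match the sign of delta
  expect_identical(sig05$direction, ifelse(sig05$delta > 0, "hyper", "hypo"))
})
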