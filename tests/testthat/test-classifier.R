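make_refs <- function(n = 30, seed = 1) {
  set.seed(seed)
  case_m <- runif(n, 0.1, 0.9)
  ctrl_m <- runif(n, 0.1, 0.9)
  structure(tibble::tibble(probe_id = sprintf("sig%03d", seq_len(n)),
                           case_median = case_m, control_median = ctrl_m),
            class = c("methsig_refprofiles", "tbl_df", "tbl", "data.frame"))
}

test_that("reference profiles are per-group medians in signature order", {
  sig_ids <- c("cg002", "cg001", "cg003")
  beta <- make_beta(rbind(c(0.2, 0.4, 0.9, 0.5, 0.6),
                          c(0.1, 0.1, 0.1, 0.8, 0.8),
                          c(0.3, 0.5, 0.7, 0.2, 0.4)),
                    probe_ids = c("cg001", "cg002", "cg003"))
  refs <- build_reference_profiles(beta, sig_ids,
                                   case_ids = c("s01", "s02", "s03"),
                                   control_ids = c("s04", "s05"))
  expect_equal(refs$probe_id, sig_ids)           # signature order kept
  expect_equal(refs$case_median, c(0.1, 0.4, 0.5))
  expect_equal(refs$control_median, c(0.8, 0.55, 0.3))

  # permutation of sample order changes nothing
  refs2 <- build_reference_profiles(beta[, 5:1], sig_ids,
                                    case_ids = c("s03", "s01", "s02"),
                                    control_ids = c("s05", "s04"))
  expect_equal(refs2, refs)

  expect_error(
    build_reference_profiles(beta, c("cg001", "nope"),
                             c("s01", "s02"), c("s04", "s05")),
    class = "methsig_reference_error")
  expect_error(
    build_reference_profiles(beta, sig_ids, "s01", c("s04", "s05")),
    class = "methsig_parameter_error")
})

test_that("scores separate case-like and control-like samples by sign", {
  refs <- make_refs(40)

  self_case <- setNames(refs$case_median, refs$probe_id)
  sc <- score_sample(self_case, refs, "x")
  expect_gt(sc$score, 0)
  expect_equal(sc$call, "case_like")
  expect_equal(sc$r_case, 1)

  self_ctrl <- setNames(refs$control_median, refs$probe_id)
  sc2 <- score_sample(self_ctrl, refs, "y")
  expect_lt(sc2$score, 0)
  expect_equal(sc2$call, "control_like")

  # symmetric geometry: references with equal variance, sample the midpoint
  set.seed(2)
  case_m <- runif(25, 0.1, 0.9)
  ctrl_m <- sample(case_m)                        # same variance by permutation
  refs_sym <- structure(tibble::tibble(probe_id = sprintf("p%02d", 1:25),
                                       case_median = case_m,
                                       control_median = ctrl_m),
                        class = class(refs))
  mid <- setNames((case_m + ctrl_m) / 2, refs_sym$probe_id)
  sc3 <- score_sample(mid, refs_sym, "mid")
  expect_lt(abs(sc3$score), 1e-6)
  expect_equal(sc3$call, "control_like")          # ties go to control

  expect_error(score_sample(setNames(rep(0.5, 40), refs$probe_id), refs),
               class = "methsig_validation_error")
  expect_error(score_sample(self_case[1:5], refs),
               class = "methsig_parameter_error")
})

test_that("scores are invariant to increasing affine transforms", {
  refs <- make_refs(30, seed = 3)
  set.seed(4)
  x <- setNames(runif(30, 0.1, 0.9), refs$probe_id)
  base <- score_sample(x, refs)$score
  refs_t <- refs
  refs_t$case_median <- 0.5 * refs$case_median + 0.2
  refs_t$control_median <- 0.5 * refs$control_median + 0.2
  x_t <- 0.5 * x + 0.2
  expect_equal(score_sample(x_t, refs_t)$score, base, tolerance = 1e-12)
})

test_that("platform intersection restricts the signature and reports k/n", {
  refs <- make_refs(103)
  sig <- tibble::tibble(probe_id = refs$probe_id, delta = 0.1,
                        direction = "hyper", p_model = 0.001,
                        q_model = 0.005, q_mwu = 0.005)
  class(sig) <- c("methsig_signature", class(sig))

  available <- c(sig$probe_id[1:92], sprintf("other%03d", 1:500))
  sub <- intersect_platform(sig, available)
  expect_equal(nrow(sub), 92)
  expect_equal(attr(sub, "n_retained"), 92)
  expect_equal(attr(sub, "n_original"), 103)

  full <- intersect_platform(sig, sig$probe_id)
  expect_equal(nrow(full), 103)

  expect_error(intersect_platform(sig, "unrelated"),
               class = "methsig_reference_error")
  expect_error(intersect_platform(sig, sig$probe_id[1:5]),
               class = "methsig_parameter_error")
})

test_that("classification evaluation computes sensitivity and specificity", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:169),
    score = c(rep(0.2, 7), rep(-0.1, 161), 0.05),
    call = c(rep("case_like", 7), rep("control_like", 161), "case_like"),
    r_case = 0.5, r_control = 0.5, n_probes_used = 100)
  truth <- tibble::tibble(sample_id = scores$sample_id,
                          label = c(rep("carrier", 7), rep("non_carrier", 162)))
  ev <- evaluate_classification(scores, truth)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 161 / 162)
  expect_equal(ev$n_non_carriers, 162)

  # empty carrier class: sensitivity undefined, flagged, specificity intact
  ev2 <- evaluate_classification(scores[8:169, ], truth[8:169, ])
  expect_true(is.na(ev2$sensitivity))
  expect_match(ev2$notes, "sensitivity undefined")
  expect_equal(ev2$specificity, 161 / 162)

  bad_truth <- truth
  bad_truth$label[1] <- "positive"
  expect_error(evaluate_classification(scores, bad_truth),
               class = "methsig_validation_error")
  expect_error(evaluate_classification(scores, truth[-1, ]),
               class = "methsig_reference_error")
})

test_that("a 50/50 mosaic sample scores between carriers and controls", {
  man <- generate_manifest(3000, seed = 41)
  ok <- man$probe_id[!(man$sex_chrom_flag | man$cross_reactive_flag |
                         man$snp_5bp_flag | man$nonspecific_flag)]
  eff <- effect_spec(ok[seq(1, 400, 4)], c(0.08, 0.23))
  coh <- generate_cohort(man, 9, 23, effects = eff, seed = 42)
  vf <- variance_filter(filter_probes(coh$beta, man)$beta, 0.02)
  fit <- fit_moderated_model(vf$beta, coh$samples)
  mwu <- mann_whitney_per_probe(vf$beta, coh$samples)
  del <- compute_delta_beta(vf$beta, coh$samples)
  sig <- derive_signature(fit, mwu, del)
  expect_gte(nrow(sig), 10)

  sheet <- coh$samples
  refs <- build_reference_profiles(
    coh$beta, sig,
    sheet$sample_id[sheet$group == "case"],
    sheet$sample_id[sheet$group == "control"])

  carriers <- draw_samples(coh, 10, "case", seed = 43)
  controls <- draw_samples(coh, 10, "control", seed = 44)
  sc_car <- score_samples(carriers$beta[sig$probe_id, ], refs)
  sc_ctl <- score_samples(controls$beta[sig$probe_id, ], refs)

  # mosaic: the average of a carrier and a control methylome (half the
  # planted shift) lands strictly between the two score distributions
  mosaic <- (carriers$beta[sig$probe_id, 1] + controls$beta[sig$probe_id, 1]) / 2
  sc_mos <- score_sample(mosaic, refs, "mosaic")
  expect_lt(sc_mos$score, mean(sc_car$score))
  expect_gt(sc_mos$score, mean(sc_ctl$score))
})
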