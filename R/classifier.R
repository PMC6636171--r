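#' Build median reference profiles at signature CpGs
#'
#' For each signature CpG, computes the median beta over the training cases
#' and, separately, over the training controls. These two vectors anchor the
#' correlation-based classification of independent samples.
#'
#' @param beta Probes x samples beta matrix containing every signature probe.
#' @param signature A `methsig_signature` (or character vector of probe ids).
#' @param case_ids,control_ids Sample ids of the two training cohorts
#'   (each >= 2).
#' @return An object of class `methsig_refprofiles`: tibble with `probe_id`
#'   (signature order), `case_median`, `control_median`.
#' @export
build_reference_profiles <- function(beta, signature, case_ids, control_ids) {
  assert_beta_matrix(beta)
  sig_ids <- if (is.character(signature)) signature else signature$probe_id
  miss <- setdiff(sig_ids, rownames(beta))
  if (length(miss) > 0) {
    abort(paste0("Signature probes absent from beta matrix: ",
                 paste(head(miss, 10), collapse = ", ")),
          class = "methsig_reference_error")
  }
  if (length(case_ids) < 2 || length(control_ids) < 2) {
    abort("Both cohorts need >= 2 samples.", class = "methsig_parameter_error")
  }
  missing_samples <- setdiff(c(case_ids, control_ids), colnames(beta))
  if (length(missing_samples) > 0) {
    abort(paste0("Samples absent from beta matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")),
          class = "methsig_reference_error")
  }
  sub <- beta[sig_ids, , drop = FALSE]
  out <- tibble::tibble(
    probe_id = sig_ids,
    case_median = unname(apply(sub[, case_ids, drop = FALSE], 1, median)),
    control_median = unname(apply(sub[, control_ids, drop = FALSE], 1, median)))
  class(out) <- c("methsig_refprofiles", class(out))
  out
}

cor_fun <- function(method) {
  function(x, y) stats::cor(x, y, method = method)
}

#' Score one sample against the reference profiles
#'
#' Classification score = Pearson correlation of the sample's beta values
#' with the case median profile minus its correlation with the control median
#' profile, over the intersection of available signature probes. Positive
#' scores are case-like; the decision threshold is fixed at 0 and a tied
#' score of exactly 0 is called control-like.
#'
#' @param sample_beta Named numeric vector of beta values over (a subset of)
#'   the signature probes.
#' @param refs A `methsig_refprofiles`.
#' @param sample_id Optional label for the output row.
#' @param method Correlation estimator: `"pearson"` (default) or
#'   `"spearman"`.
#' @return One-row tibble: `sample_id`, `score` (in `[-2, 2]`), `call`,
#'   `r_case`, `r_control`, `n_probes_used`.
#' @export
score_sample <- function(sample_beta, refs, sample_id = "sample",
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(sample_beta))) {
    abort("`sample_beta` must be named by probe id.",
          class = "methsig_parameter_error")
  }
  common <- intersect(refs$probe_id, names(sample_beta))
  if (length(common) < 10) {
    abort("Fewer than 10 signature probes available for scoring.",
          class = "methsig_parameter_error")
  }
  r <- refs[match(common, refs$probe_id), ]
  x <- sample_beta[common]
  if (sd(x) == 0) {
    abort("Sample vector is constant over signature probes; correlation undefined.",
          class = "methsig_validation_error")
  }
  if (sd(r$case_median) == 0 || sd(r$control_median) == 0) {
    abort("Degenerate reference profile (constant vector).",
          class = "methsig_validation_error")
  }
  cf <- cor_fun(method)
  r_case <- cf(x, r$case_median)
  r_control <- cf(x, r$control_median)
  score <- r_case - r_control
  tibble::tibble(sample_id = sample_id, score = score,
                 call = ifelse(score > 0, "case_like", "control_like"),
                 r_case = r_case, r_control = r_control,
                 n_probes_used = length(common))
}

#' Score every column of a beta matrix
#'
#' Vectorised [score_sample()] over the samples of a beta matrix.
#'
#' @param beta Probes x samples beta matrix.
#' @param refs A `methsig_refprofiles`.
#' @param method Correlation estimator.
#' @return Tibble of class `methsig_scores`, one row per sample.
#' @export
score_samples <- function(beta, refs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_beta_matrix(beta)
  out <- purrr::map_dfr(colnames(beta), function(s) {
    score_sample(beta[, s], refs, sample_id = s, method = method)
  })
  class(out) <- c("methsig_scores", class(out))
  out
}

#' Restrict a signature to the probes available on another platform
#'
#' Cross-platform classification (e.g. a 450K-derived signature applied to
#' EPIC-array samples) uses only the signature probes present on the scoring
#' platform. The realised intersection size is recorded; fewer than 10
#' retained probes is an error.
#'
#' @param signature A `methsig_signature`.
#' @param available_probe_ids Probe ids measurable on the scoring platform.
#' @return The restricted signature; attributes `n_retained` and `n_original`
#'   record the k/n intersection.
#' @export
intersect_platform <- function(signature, available_probe_ids) {
  keep <- signature$probe_id %in% available_probe_ids
  if (!any(keep)) {
    abort("No signature probes available on the target platform.",
          class = "methsig_reference_error")
  }
  if (sum(keep) < 10) {
    abort(sprintf("Only %d signature probes available (< 10).", sum(keep)),
          class = "methsig_parameter_error")
  }
  out <- signature[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_original") <- nrow(signature)
  out
}

#' Sensitivity and specificity of classification calls
#'
#' @param scores A `methsig_scores` tibble.
#' @param truth Tibble with `sample_id` and `label` in
#'   `{"carrier", "non_carrier"}` covering every scored sample.
#' @return A list of class `methsig_eval`: `sensitivity`, `specificity`
#'   (`NA` when the denominator class is empty, flagged in `notes`),
#'   `n_carriers`, `n_non_carriers`, and the per-sample `table`.
#' @export
evaluate_classification <- function(scores, truth) {
  miss <- setdiff(scores$sample_id, truth$sample_id)
  if (length(miss) > 0) {
    abort(paste0("Samples without truth labels: ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "methsig_reference_error")
  }
  lab <- truth$label[match(scores$sample_id, truth$sample_id)]
  if (!all(lab %in% c("carrier", "non_carrier"))) {
    abort("Truth labels must be 'carrier' or 'non_carrier'.",
          class = "methsig_validation_error")
  }
  tab <- dplyr::mutate(scores, label = lab,
                       correct = (lab == "carrier") ==
                         (.data$call == "case_like"))
  n_car <- sum(lab == "carrier")
  n_non <- sum(lab == "non_carrier")
  sens <- if (n_car > 0) {
    sum(tab$call == "case_like" & lab == "carrier") / n_car
  } else {
    NA_real_
  }
  spec <- if (n_non > 0) {
    sum(tab$call == "control_like" & lab == "non_carrier") / n_non
  } else {
    NA_real_
  }
  notes <- c(
    if (n_car == 0) "sensitivity undefined: no carriers",
    if (n_non == 0) "specificity undefined: no non-carriers")
  structure(list(sensitivity = sens, specificity = spec,
                 n_carriers = n_car, n_non_carriers = n_non,
                 table = tab, notes = notes),
            class = "methsig_eval")
}

#' @export
print.methsig_eval <- function(x, ...) {
  cat(sprintf("Sensitivity: %s (%d carriers); Specificity: %s (%d non-carriers)\n",
              format(x$sensitivity), x$n_carriers,
              format(x$specificity), x$n_non_carriers))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @method glance methsig_eval
#' @export
glance.methsig_eval <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 n_carriers = x$n_carriers, n_non_carriers = x$n_non_carriers)
}

#' Classification plot (correlation plane)
#'
#' Plots each sample's correlation to the case reference profile against its
#' correlation to the control reference profile; the diagonal is the decision
#' boundary (score = 0). Case-like samples fall below/right of the diagonal.
#'
#' @param object A `methsig_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methsig_scores
#' @export
autoplot.methsig_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r_control, .data$r_case,
                                       colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "r (control reference)", y = "r (case reference)",
                  colour = NULL, title = "Episignature classification")
}
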