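#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (q-values): the adjusted value for
#' the i-th smallest p is `min over j >= i of (m * p_(j) / j)`, capped at 1,
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.",
          class = "methsig_parameter_error")
  }
  p.adjust(p, method = "BH")
}

# Invert the trigamma function by Newton's method (monotone decreasing on
# (0, Inf)); used for the empirical-Bayes prior-df moment estimate.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Method-of-moments fit of the scaled inverse chi-square prior for per-probe
# variances (moments of log s^2). Returns df_prior (possibly Inf) and s2_prior.
fit_variance_prior <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  G <- length(e)
  evar <- sum((e - mean(e))^2) / (G - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion of the variances: infinite prior df, common
    # variance estimated unbiasedly on the raw scale
    df_prior <- Inf
    s2_prior <- mean(s2)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

build_design <- function(beta, samples, cellprops = NULL) {
  grp <- group_indicator(beta, samples)
  s <- samples[match(colnames(beta), samples$sample_id), ]
  X <- cbind(intercept = 1,
             group = as.numeric(grp == "case"),
             age = s$age,
             sexM = as.numeric(s$sex == "M"))
  if (!is.null(cellprops)) {
    cp <- as.data.frame(cellprops)
    rownames(cp) <- cp$sample_id
    ct_cols <- setdiff(colnames(cp), c("sample_id", "residual"))
    # drop one cell type: proportions sum to 1 and would be collinear with
    # the intercept
    ct_cols <- ct_cols[-length(ct_cols)]
    cp <- as.matrix(cp[colnames(beta), ct_cols, drop = FALSE])
    X <- cbind(X, cp)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is collinear; dependent columns: ",
                 paste(dep, collapse = ", ")),
          class = "methsig_parameter_error")
  }
  if (nrow(X) <= ncol(X)) {
    abort("More design columns than samples; model is unidentifiable.",
          class = "methsig_parameter_error")
  }
  X
}

#' Empirical-Bayes moderated differential methylation model
#'
#' Fits, per probe, an ordinary least-squares regression of beta values on
#' group (case vs control) adjusting for age, sex and (optionally) estimated
#' cell-type proportions (one cell type dropped to avoid collinearity with
#' the intercept). Per-probe residual variances are then shrunk towards a
#' common prior by empirical Bayes: the scaled inverse chi-square prior
#' `(d0, s0^2)` is estimated by method of moments on `log s^2` (trigamma
#' inversion by Newton's method), the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t-statistic for the
#' group coefficient is referred to a t-distribution on `d0 + d` degrees of
#' freedom.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet tibble (`sample_id`, `group`, `age`, `sex`).
#' @param cellprops Optional [estimate_cell_proportions()] result.
#' @param prior_df Override the estimated prior df: `NULL` (estimate, the
#'   default), `0` (no shrinkage; ordinary per-probe t) or `Inf` (common
#'   variance for all probes).
#' @return An object of class `methsig_modfit`: `table` (tibble with
#'   `probe_id`, `delta_adj` — the covariate-adjusted group effect on the
#'   beta scale — `sigma2`, `t`, `df_total`, `p`, `q`), plus `df_resid`,
#'   `df_prior`, `s2_prior` and the `design` matrix.
#' @export
fit_moderated_model <- function(beta, samples, cellprops = NULL,
                                prior_df = NULL) {
  assert_beta_matrix(beta)
  X <- build_design(beta, samples, cellprops)
  n <- nrow(X)
  p <- ncol(X)
  d <- n - p

  fit <- stats::lm.fit(X, t(beta))
  coefs <- t(fit$coefficients)              # probes x p
  res <- t(fit$residuals)                   # probes x n
  s2 <- rowSums(res^2) / d
  v_group <- chol2inv(qr.R(qr(X)))          # unscaled (X'X)^-1
  v_group <- v_group[2, 2]

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else if (identical(prior_df, 0)) {
    prior <- list(df_prior = 0, s2_prior = NA_real_)
  } else if (is.infinite(prior_df)) {
    prior <- list(df_prior = Inf, s2_prior = mean(s2))
  } else {
    abort("`prior_df` must be NULL, 0 or Inf.",
          class = "methsig_parameter_error")
  }

  s2_post <- if (prior$df_prior == 0) {
    s2
  } else if (is.infinite(prior$df_prior)) {
    rep(prior$s2_prior, length(s2))
  } else {
    (prior$df_prior * prior$s2_prior + d * s2) / (prior$df_prior + d)
  }
  # total df capped at the pooled residual df: with an infinite prior the
  # common variance is still estimated from finitely many residuals
  df_total <- min(prior$df_prior + d, nrow(beta) * d)
  tstat <- coefs[, 2] / sqrt(s2_post * v_group)
  pval <- 2 * pt(-abs(tstat), df = df_total)

  structure(list(
    table = tibble::tibble(
      probe_id = rownames(beta),
      delta_adj = unname(coefs[, 2]),
      sigma2 = unname(s2),
      t = unname(tstat),
      df_total = df_total,
      p = unname(pval),
      q = bh_adjust(unname(pval))),
    df_resid = d, df_prior = prior$df_prior, s2_prior = prior$s2_prior,
    design = X),
    class = "methsig_modfit")
}

#' @export
print.methsig_modfit <- function(x, ...) {
  cat(sprintf(
    "Moderated fit: %d probes, %d samples; residual df %d, prior df %s\n",
    nrow(x$table), nrow(x$design), x$df_resid, format(x$df_prior)))
  invisible(x)
}

#' @method tidy methsig_modfit
#' @export
tidy.methsig_modfit <- function(x, ...) x$table

#' @method glance methsig_modfit
#' @export
glance.methsig_modfit <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x$table), n_samples = nrow(x$design),
                 df_resid = x$df_resid, df_prior = x$df_prior,
                 s2_prior = x$s2_prior)
}

resolve_groups <- function(beta, groups) {
  if (is.data.frame(groups)) {
    groups <- group_indicator(beta, groups)
  }
  if (length(groups) != ncol(beta)) {
    abort("`groups` must supply one label per sample.",
          class = "methsig_parameter_error")
  }
  if (!all(groups %in% c("case", "control"))) {
    abort("Group labels must be 'case' or 'control'.",
          class = "methsig_validation_error")
  }
  groups
}

# Two-sided Mann-Whitney p for one probe from case midrank sum.
mwu_p_single <- function(x, is_case, n1, n2) {
  r <- rank(x)
  U <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(x) > 0
  mid <- n1 * n2 / 2
  if (!ties && n1 * n2 <= 400) {
    p <- if (U > mid) {
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else if (U < mid) {
      2 * pwilcox(U, n1, n2)
    } else {
      1
    }
    exact <- TRUE
  } else {
    N <- n1 + n2
    tie_tab <- table(x)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mid - 0.5 * sign(U - mid)) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    exact <- FALSE
  }
  c(U = U, p = min(p, 1), exact = as.numeric(exact))
}

#' Per-probe Mann-Whitney U tests
#'
#' Rank-sum (Mann-Whitney U) test of case vs control per probe, with midranks
#' for ties. The two-sided p-value is exact (from the enumerated null U
#' distribution) when there are no ties and `n1 * n2 <= 400`; otherwise a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param beta Probes x samples beta matrix.
#' @param groups Character vector of `"case"`/`"control"` labels aligned to
#'   the columns of `beta`, or a sample sheet tibble.
#' @return An object of class `methsig_mwu`: tibble with `probe_id`, `U`
#'   (case-oriented statistic in `[0, n1*n2]`), `p`, `q` and `exact`.
#' @export
mann_whitney_per_probe <- function(beta, groups) {
  assert_beta_matrix(beta)
  groups <- resolve_groups(beta, groups)
  is_case <- groups == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) {
    abort("Both groups need >= 2 samples for the Mann-Whitney test.",
          class = "methsig_parameter_error")
  }
  res <- t(apply(beta, 1, mwu_p_single, is_case = is_case, n1 = n1, n2 = n2))
  out <- tibble::tibble(
    probe_id = rownames(beta),
    U = unname(res[, "U"]),
    p = unname(res[, "p"]),
    q = bh_adjust(unname(res[, "p"])),
    exact = res[, "exact"] == 1)
  class(out) <- c("methsig_mwu", class(out))
  out
}

#' Per-probe effect size (delta beta)
#'
#' Arithmetic mean beta of cases minus mean beta of controls, per probe — the
#' beta-scale effect size thresholded during signature derivation.
#'
#' @inheritParams mann_whitney_per_probe
#' @return Tibble with `probe_id` and `delta`.
#' @export
compute_delta_beta <- function(beta, groups) {
  assert_beta_matrix(beta)
  groups <- resolve_groups(beta, groups)
  is_case <- groups == "case"
  if (!any(is_case) || all(is_case)) {
    abort("Both groups must be non-empty.", class = "methsig_parameter_error")
  }
  tibble::tibble(
    probe_id = rownames(beta),
    delta = unname(rowMeans(beta[, is_case, drop = FALSE]) -
                     rowMeans(beta[, !is_case, drop = FALSE])))
}

#' Derive a DNA methylation episignature
#'
#' Intersection-based signature derivation: a probe enters the signature only
#' if it passes the moderated-regression q-value threshold AND the
#' Mann-Whitney q-value threshold AND the absolute effect-size requirement
#' (`|delta beta| >= delta_thresh`). The conservative intersection of a
#' covariate-adjusted parametric test with a non-parametric test is the core
#' derivation rule. `mode = "unadjusted_p"` replaces both q conditions with
#' an unadjusted moderated-regression p threshold (the screening mode used
#' when no probe survives FDR correction).
#'
#' @param fit A `methsig_modfit`.
#' @param mwu A `methsig_mwu` on the same probe set.
#' @param deltas [compute_delta_beta()] result on the same probe set.
#' @param q_thresh Threshold applied to both q-vectors (or, in
#'   `"unadjusted_p"` mode, to the raw regression p). Defaults: 0.05 for the
#'   primary signature, 0.01 for the stringent classification signature.
#' @param delta_thresh Minimum `|delta beta|`; default 0.05.
#' @param mode `"adjusted"` (default) or `"unadjusted_p"`.
#' @return An object of class `methsig_signature`: a tibble with `probe_id`,
#'   `delta`, `direction` (`"hyper"`/`"hypo"` in cases), `p_model`,
#'   `q_model`, `q_mwu`; thresholds and hypo/hyper counts in attributes.
#' @export
derive_signature <- function(fit, mwu, deltas, q_thresh = 0.05,
                             delta_thresh = 0.05,
                             mode = c("adjusted", "unadjusted_p")) {
  mode <- match.arg(mode)
  assert_fraction(q_thresh, "q_thresh", open_hi = TRUE)
  assert_fraction(delta_thresh, "delta_thresh", open_hi = TRUE)
  ids <- fit$table$probe_id
  if (!setequal(ids, mwu$probe_id) || !setequal(ids, deltas$probe_id)) {
    abort("fit, mwu and deltas must cover the same probe set.",
          class = "methsig_parameter_error")
  }
  tab <- fit$table |>
    dplyr::select("probe_id", p_model = "p", q_model = "q") |>
    dplyr::left_join(dplyr::select(mwu, "probe_id", q_mwu = "q"),
                     by = "probe_id") |>
    dplyr::left_join(deltas, by = "probe_id")
  keep <- if (mode == "adjusted") {
    tab$q_model < q_thresh & tab$q_mwu < q_thresh
  } else {
    tab$p_model < q_thresh
  }
  keep <- keep & abs(tab$delta) >= delta_thresh
  sig <- tab[keep, , drop = FALSE] |>
    dplyr::mutate(direction = ifelse(.data$delta > 0, "hyper", "hypo")) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta))) |>
    dplyr::select("probe_id", "delta", "direction",
                  "p_model", "q_model", "q_mwu")
  structure(sig,
            class = c("methsig_signature", class(sig)),
            q_thresh = q_thresh, delta_thresh = delta_thresh, mode = mode,
            n_hypo = sum(sig$direction == "hypo"),
            n_hyper = sum(sig$direction == "hyper"),
            n_background = length(ids))
}

#' @export
print.methsig_signature <- function(x, ...) {
  cat(sprintf(
    "Episignature: %d CpGs (%d hypo, %d hyper) at %s < %g, |delta beta| >= %g\n",
    nrow(x), attr(x, "n_hypo"), attr(x, "n_hyper"),
    if (attr(x, "mode") == "adjusted") "q" else "p",
    attr(x, "q_thresh"), attr(x, "delta_thresh")))
  NextMethod()
}

#' @method glance methsig_signature
#' @export
glance.methsig_signature <- function(x, ...) {
  tibble::tibble(n_cpgs = nrow(x), n_hypo = attr(x, "n_hypo"),
                 n_hyper = attr(x, "n_hyper"),
                 q_thresh = attr(x, "q_thresh"),
                 delta_thresh = attr(x, "delta_thresh"),
                 mode = attr(x, "mode"),
                 n_background = attr(x, "n_background"))
}

#' Volcano plot of a signature derivation
#'
#' Plots per-probe effect size against `-log10` of the moderated-regression
#' q-value, highlighting signature members.
#'
#' @param object A `methsig_signature`.
#' @param fit The `methsig_modfit` it was derived from.
#' @param deltas The effect-size table used for derivation.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methsig_signature
#' @export
autoplot.methsig_signature <- function(object, fit, deltas, ...) {
  dat <- dplyr::left_join(deltas,
                          dplyr::select(fit$table, "probe_id", "q"),
                          by = "probe_id") |>
    dplyr::mutate(member = .data$probe_id %in% object$probe_id)
  ggplot2::ggplot(dat, ggplot2::aes(.data$delta, -log10(pmax(.data$q, 1e-300)),
                                    colour = .data$member)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "delta_thresh"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_thresh")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey60", "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * beta ~ "(case - control)"),
                  y = expression(-log[10] ~ q),
                  title = "Episignature volcano")
}
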