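#' Find candidate differentially methylated regions
#'
#' Bump-hunting candidate discovery: within each chromosome, probes are
#' position-sorted and maximal runs of consecutive probes are formed in which
#' every probe has `|delta beta| >= delta_thresh`, all deltas share one sign,
#' and consecutive member probes are at most `max_gap` bp apart. Each maximal
#' run is one candidate region; its summary statistic is the area
#' `sum(|delta|)` over member probes.
#'
#' Coordinates are emitted 0-based half-open (BED convention): `start` is the
#' minimum 1-based probe position minus one, `end` the maximum position.
#'
#' @param deltas Tibble with `probe_id` and `delta` ([compute_delta_beta()]).
#' @param ann Probe annotation with `chrom` and `pos` for every probe.
#' @param delta_thresh Per-probe absolute effect threshold; default 0.05.
#' @param max_gap Maximum gap between neighbouring member CpGs, bp;
#'   default 500.
#' @return A tibble of class `methsig_dmr`: `chrom`, `start`, `end`,
#'   `probe_ids` (list column, position order), `n_cpgs`, `mean_delta`,
#'   `area`, `p_boot` (`NA` until [bootstrap_region_pvalues()]),
#'   `overlaps_signature` (`NA` until [filter_dmrs()]).
#' @export
find_candidate_regions <- function(deltas, ann, delta_thresh = 0.05,
                                   max_gap = 500) {
  assert_fraction(delta_thresh, "delta_thresh", open_hi = TRUE)
  miss <- setdiff(deltas$probe_id, ann$probe_id)
  if (length(miss) > 0) {
    abort(paste0("Probes without coordinates: ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "methsig_reference_error")
  }
  dat <- dplyr::left_join(deltas,
                          dplyr::select(ann, "probe_id", "chrom", "pos"),
                          by = "probe_id") |>
    dplyr::arrange(.data$chrom, .data$pos)

  out <- list()
  for (cc in unique(dat$chrom)) {
    d <- dat[dat$chrom == cc, ]
    qual <- abs(d$delta) >= delta_thresh
    if (!any(qual)) next
    # run breaks: non-qualifying probe, sign change, or gap > max_gap
    # between consecutive qualifying probes that are adjacent in the array
    n <- nrow(d)
    run_id <- integer(n)
    current <- 0L
    prev_ok <- FALSE
    for (i in seq_len(n)) {
      if (!qual[i]) {
        prev_ok <- FALSE
        next
      }
      new_run <- !prev_ok ||
        sign(d$delta[i]) != sign(d$delta[i - 1L]) ||
        (d$pos[i] - d$pos[i - 1L]) > max_gap
      if (new_run) current <- current + 1L
      run_id[i] <- current
      prev_ok <- TRUE
    }
    for (r in seq_len(current)) {
      m <- d[run_id == r & qual, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cc,
        start = min(m$pos) - 1L,
        end = max(m$pos),
        probe_ids = list(m$probe_id),
        n_cpgs = nrow(m),
        mean_delta = mean(m$delta),
        area = sum(abs(m$delta)))
    }
  }
  res <- if (length(out) == 0) {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   probe_ids = list(), n_cpgs = integer(),
                   mean_delta = numeric(), area = numeric())
  } else {
    dplyr::bind_rows(out)
  }
  res$p_boot <- NA_real_
  res$overlaps_signature <- NA
  class(res) <- c("methsig_dmr", class(res))
  res
}

#' Bootstrap p-values for candidate regions
#'
#' Assigns each candidate region an empirical p-value from a residual
#' bootstrap under the null of no group effect. A per-probe null model with
#' covariates only (intercept, age, sex, optional cell proportions — no group
#' term) is fitted; in each of `B` iterations the residual columns are
#' resampled with replacement, a null beta matrix `fitted + resampled
#' residuals` (clipped to `[0, 1]`) is assembled, candidate discovery is
#' re-run with identical parameters on its group deltas, and the maximum null
#' area of the iteration is recorded. The p-value of a candidate with
#' observed area `A` is `(1 + #{max null area >= A}) / (B + 1)` — family-wise
#' across candidates, with add-one smoothing so p is never 0.
#'
#' @param beta Probes x samples beta matrix (the tested, e.g.
#'   variance-filtered, probe universe).
#' @param samples Sample sheet tibble.
#' @param cellprops Optional cell-proportion covariates.
#' @param candidates [find_candidate_regions()] result from the same probe
#'   universe.
#' @param ann Probe annotation (needed to re-discover regions per iteration).
#' @param B Number of bootstrap iterations (>= 1); default 1000.
#' @param seed Integer seed.
#' @param delta_thresh,max_gap Discovery parameters; must match those used
#'   for `candidates`.
#' @return `candidates` with `p_boot` filled in.
#' @export
bootstrap_region_pvalues <- function(beta, samples, cellprops = NULL,
                                     candidates, ann, B = 1000, seed,
                                     delta_thresh = 0.05, max_gap = 500) {
  assert_beta_matrix(beta)
  if (B < 1) abort("`B` must be >= 1.", class = "methsig_parameter_error")
  if (nrow(candidates) == 0) return(candidates)
  miss <- setdiff(unlist(candidates$probe_ids), rownames(beta))
  if (length(miss) > 0) {
    abort("Candidates reference probes outside the beta matrix.",
          class = "methsig_reference_error")
  }
  grp <- group_indicator(beta, samples)
  X <- build_design(beta, samples, cellprops)
  X0 <- X[, colnames(X) != "group", drop = FALSE]

  fit0 <- stats::lm.fit(X0, t(beta))
  fitted0 <- t(X0 %*% fit0$coefficients)
  resid0 <- beta - fitted0
  n <- ncol(beta)
  is_case <- grp == "case"

  ann_sub <- ann[match(rownames(beta), ann$probe_id), ]

  max_null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      beta_star <- pmin(pmax(fitted0 + resid0[, idx, drop = FALSE], 0), 1)
      delta_star <- rowMeans(beta_star[, is_case, drop = FALSE]) -
        rowMeans(beta_star[, !is_case, drop = FALSE])
      cand <- find_candidate_regions(
        tibble::tibble(probe_id = rownames(beta), delta = delta_star),
        ann_sub, delta_thresh = delta_thresh, max_gap = max_gap)
      if (nrow(cand) == 0) 0 else max(cand$area)
    }, numeric(1))
  })

  candidates$p_boot <- vapply(candidates$area, function(a) {
    (1 + sum(max_null >= a)) / (B + 1)
  }, numeric(1))
  candidates
}

#' Post-filter candidate regions into reported DMRs
#'
#' Retains candidates satisfying all of: bootstrap `p < p_thresh`, average
#' methylation difference `|mean_delta| >= delta_thresh`, at least `min_cpgs`
#' consecutive CpGs, and overlap with at least one episignature CpG.
#'
#' @param candidates Candidates with `p_boot` set.
#' @param signature A `methsig_signature` (or character vector of probe ids).
#' @param p_thresh Bootstrap p threshold; default 0.05.
#' @param delta_thresh Minimum `|mean_delta|`; default 0.05.
#' @param min_cpgs Minimum member CpGs; default 3.
#' @return Filtered `methsig_dmr` tibble with `overlaps_signature` set.
#' @export
filter_dmrs <- function(candidates, signature, p_thresh = 0.05,
                        delta_thresh = 0.05, min_cpgs = 3) {
  if (anyNA(candidates$p_boot)) {
    abort("`p_boot` must be set on all candidates; run bootstrap_region_pvalues().",
          class = "methsig_parameter_error")
  }
  sig_ids <- if (is.character(signature)) signature else signature$probe_id
  if (length(sig_ids) == 0) {
    warn("Empty signature: every candidate fails the overlap requirement.")
  }
  candidates$overlaps_signature <- vapply(
    candidates$probe_ids, function(p) any(p %in% sig_ids), logical(1))
  keep <- candidates$p_boot < p_thresh &
    abs(candidates$mean_delta) >= delta_thresh &
    candidates$n_cpgs >= min_cpgs &
    candidates$overlaps_signature
  candidates[keep, , drop = FALSE]
}
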