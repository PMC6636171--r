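#' Remove quality-flagged probes
#'
#' Drops probes carrying any of the standard array QC flags: sex-chromosome
#' probes, autosomal probes cross-reacting with sex chromosomes, non-specific
#' probes, and probes within 5 bp of a common SNP. A probe is removed once but
#' counted under every reason that applies.
#'
#' @param beta Probes x samples beta matrix.
#' @param ann Probe annotation tibble covering every probe in `beta`.
#' @return A list of class `methsig_qc`: `beta` (filtered matrix) and
#'   `report`, a tibble of removal counts per reason plus totals.
#' @export
filter_probes <- function(beta, ann) {
  assert_beta_matrix(beta)
  miss <- setdiff(rownames(beta), ann$probe_id)
  if (length(miss) > 0) {
    abort(paste0("Probes missing from annotation: ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "methsig_reference_error")
  }
  a <- ann[match(rownames(beta), ann$probe_id), ]
  reasons <- c(sex_chrom = "sex_chrom_flag", cross_reactive = "cross_reactive_flag",
               snp_5bp = "snp_5bp_flag", nonspecific = "nonspecific_flag")
  flag_mat <- vapply(reasons, function(col) a[[col]], logical(nrow(a)))
  drop <- rowSums(flag_mat) > 0
  report <- tibble::tibble(
    reason = c(names(reasons), "total_removed", "retained"),
    n = unname(c(colSums(flag_mat), sum(drop), sum(!drop))))
  structure(list(beta = beta[!drop, , drop = FALSE], report = report),
            class = "methsig_qc")
}

#' @export
print.methsig_qc <- function(x, ...) {
  cat("Probe QC filter:", x$report$n[x$report$reason == "retained"],
      "probes retained\n")
  print(x$report)
  invisible(x)
}

#' Batch correction by mean-centering
#'
#' Per probe, subtracts each batch's mean and adds back the grand mean, so
#' after correction all per-probe batch means are equal (to within machine
#' precision) while the probe's grand mean is preserved. With a single batch
#' the input is returned untouched. Output is clipped to `[0, 1]`.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet with `sample_id` and `batch` columns covering
#'   every column of `beta`; every batch must contain >= 2 samples.
#' @return Corrected beta matrix.
#' @export
mean_center_batches <- function(beta, samples) {
  assert_beta_matrix(beta)
  batch <- samples$batch[match(colnames(beta), samples$sample_id)]
  if (anyNA(batch)) {
    abort("Every sample needs a batch label in the sample sheet.",
          class = "methsig_reference_error")
  }
  if (length(unique(batch)) == 1L) {
    return(beta)
  }
  sizes <- table(batch)
  if (any(sizes < 2)) {
    abort(paste0("Batches with a single sample: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "),
                 "; mean-centering is undefined for them."),
          class = "methsig_parameter_error")
  }
  grand <- rowMeans(beta)
  out <- beta
  for (b in unique(batch)) {
    j <- batch == b
    out[, j] <- beta[, j, drop = FALSE] -
      rowMeans(beta[, j, drop = FALSE]) + grand
  }
  pmin(pmax(out, 0), 1)
}

#' Filter probes by variance
#'
#' Retains probes whose sample standard deviation (denominator `n - 1`) is at
#' least `var_fraction` times the maximal probe SD in the matrix — the
#' standard pre-test prioritisation step, blinded to group labels. The
#' documented pipeline default is `var_fraction = 0.02` (drop sites with SD
#' below 2% of the maximum SD).
#'
#' @param beta Probes x samples beta matrix (>= 2 samples).
#' @param var_fraction Fraction of the maximal SD, in `[0, 1)`.
#' @return A list of class `methsig_varfilter`: `beta` (retained rows),
#'   `n_retained`, `threshold` (absolute SD cut-off) and `max_sd`.
#' @export
variance_filter <- function(beta, var_fraction = 0.02) {
  assert_beta_matrix(beta)
  assert_fraction(var_fraction, "var_fraction", open_hi = TRUE)
  sds <- row_sds(beta)
  max_sd <- max(sds)
  thr <- var_fraction * max_sd
  keep <- sds >= thr
  if (max_sd == 0 && var_fraction > 0) {
    warn("All probes are constant; nothing retained.")
    keep <- rep(FALSE, length(sds))
  }
  structure(list(beta = beta[keep, , drop = FALSE],
                 n_retained = sum(keep), threshold = thr, max_sd = max_sd),
            class = "methsig_varfilter")
}

# Euclidean projection of a vector onto the probability simplex (Duchi et al.)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Reference-based cell-type deconvolution
#'
#' Estimates per-sample blood cell-type proportions by constrained projection
#' onto a purified cell-type reference: per sample, minimises
#' `||beta_markers - t(M) w||^2` subject to `w >= 0`, `sum(w) = 1`, solved by
#' projected gradient descent with exact Euclidean projection onto the
#' probability simplex (convergence tolerance 1e-8 on the iterate change).
#'
#' @param beta Probes x samples beta matrix containing the reference's marker
#'   probes (at least as many as there are cell types).
#' @param ref A `methsig_celltype_ref`.
#' @return A tibble of class `methsig_cellprops`: `sample_id`, one proportion
#'   column per cell type (rows on the probability simplex), and `residual`
#'   (achieved root-mean-square fit residual).
#' @export
estimate_cell_proportions <- function(beta, ref) {
  assert_beta_matrix(beta)
  stopifnot(inherits(ref, "methsig_celltype_ref"))
  markers <- intersect(ref$marker_probe_ids, rownames(beta))
  k <- nrow(ref$mean_beta)
  if (length(markers) < k) {
    abort("Fewer marker probes available than cell types.",
          class = "methsig_parameter_error")
  }
  A <- t(ref$mean_beta[, markers, drop = FALSE])   # markers x celltypes
  if (qr(A)$rank < k) {
    abort("Cell-type reference is rank deficient (indistinguishable cell types).",
          class = "methsig_parameter_error")
  }
  B <- beta[markers, , drop = FALSE]
  AtA <- crossprod(A)
  L <- 2 * max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  W <- matrix(NA_real_, ncol(B), k,
              dimnames = list(colnames(B), rownames(ref$mean_beta)))
  resid <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    Atb <- crossprod(A, b)
    w <- rep(1 / k, k)
    for (it in seq_len(20000L)) {
      g <- 2 * (AtA %*% w - Atb)
      w_new <- project_simplex(as.numeric(w - step * g))
      if (max(abs(w_new - w)) < 1e-8) {
        w <- w_new
        break
      }
      w <- w_new
    }
    W[j, ] <- w
    resid[j] <- sqrt(mean((b - A %*% w)^2))
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(B)),
                          tibble::as_tibble(W))
  out$residual <- resid
  class(out) <- c("methsig_cellprops", class(out))
  out
}
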