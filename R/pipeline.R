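#' Pipeline configuration
#'
#' Collects the file paths and analysis parameters for [run_pipeline()].
#' Parameter defaults are the pipeline's documented settings: variance filter
#' `var = 0.02`, signature thresholds `q < 0.05` (primary) and `q < 0.01`
#' (stringent, used for classification), effect size `|delta beta| >= 0.05`,
#' DMR gaps `<= 500` bp with `>= 3` CpGs and 1000 bootstrap iterations at
#' `p < 0.05`, Pearson classification scores.
#'
#' @param beta,manifest,samples Paths to the beta TSV, manifest CSV and
#'   sample sheet CSV.
#' @param cell_reference Optional path to a cell-type reference CSV; when
#'   given, estimated cell proportions enter the regression and bootstrap as
#'   covariates.
#' @param out_dir Output directory.
#' @param var_fraction,q_thresh,q_thresh_strict,delta_thresh Analysis
#'   thresholds.
#' @param dmr List of DMR parameters: `max_gap`, `min_cpgs`, `B`, `p`.
#' @param classifier_method `"pearson"` or `"spearman"`.
#' @param seed Integer seed (drives the DMR bootstrap; stage seeds are
#'   salted from it so changing one stage's settings leaves others
#'   untouched).
#' @return A `methsig_config` list.
#' @export
pipeline_config <- function(beta, manifest, samples, cell_reference = NULL,
                            out_dir, var_fraction = 0.02, q_thresh = 0.05,
                            q_thresh_strict = 0.01, delta_thresh = 0.05,
                            dmr = list(max_gap = 500, min_cpgs = 3,
                                       B = 1000, p = 0.05),
                            classifier_method = "pearson", seed = 1L) {
  for (nm in c("q_thresh", "q_thresh_strict", "delta_thresh")) {
    assert_fraction(get(nm), nm, open_hi = TRUE)
  }
  assert_fraction(var_fraction, "var_fraction", open_hi = TRUE)
  if (dmr$B < 1) abort("`dmr$B` must be >= 1.", class = "methsig_parameter_error")
  structure(list(beta = beta, manifest = manifest, samples = samples,
                 cell_reference = cell_reference, out_dir = out_dir,
                 var_fraction = var_fraction, q_thresh = q_thresh,
                 q_thresh_strict = q_thresh_strict,
                 delta_thresh = delta_thresh, dmr = dmr,
                 classifier_method = classifier_method,
                 seed = as.integer(seed)),
            class = "methsig_config")
}

log_stage <- function(report, stage, ...) {
  info <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(info), vapply(info, function(x)
                    paste(format(x), collapse = ","), ""),
                    sep = "=", collapse = " ")))
  report$stages[[stage]] <- info
  report
}

#' Run the full episignature pipeline
#'
#' End-to-end orchestration on files named in a [pipeline_config()]:
#' probe QC filtering, batch mean-centering (only when the sheet has more
#' than one batch), variance filtering, cell-type deconvolution (when a
#' reference is configured), signature derivation at both the primary and
#' stringent thresholds, DMR detection with the bootstrap null, median
#' reference profiles from the training samples, classification of all
#' `role == "test"` samples with the stringent signature, and feature
#' enrichment against the variance-filtered background. Every stage logs its
#' input/output dimensions and parameters, and the run report (also written
#' as `run_report.json`) records them all. Outputs are deterministic given
#' the config seed.
#'
#' @param config A `methsig_config`.
#' @return A run-report list (invisibly: stages, parameters, output paths,
#'   and the in-memory `results`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "methsig_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[c(
    "var_fraction", "q_thresh", "q_thresh_strict", "delta_thresh",
    "dmr", "classifier_method", "seed")], stages = list())

  beta <- read_beta_matrix(config$beta)
  manifest <- read_manifest(config$manifest)
  samples <- read_sample_sheet(config$samples)
  report <- log_stage(report, "load", n_probes = nrow(beta),
                      n_samples = ncol(beta))

  qc <- filter_probes(beta, manifest)
  report <- log_stage(report, "qc",
                      removed = sum(qc$report$n[qc$report$reason == "total_removed"]),
                      retained = nrow(qc$beta))

  centered <- mean_center_batches(qc$beta, samples)
  report <- log_stage(report, "batch_centering",
                      n_batches = length(unique(samples$batch)))

  train <- samples$sample_id[samples$role == "train"]
  test <- samples$sample_id[samples$role == "test"]
  beta_train <- centered[, train, drop = FALSE]

  vf <- variance_filter(beta_train, config$var_fraction)
  report <- log_stage(report, "variance_filter",
                      var_fraction = config$var_fraction,
                      retained = vf$n_retained, threshold = vf$threshold)

  cellprops <- NULL
  if (!is.null(config$cell_reference)) {
    ref <- read_cell_reference(config$cell_reference)
    cellprops <- estimate_cell_proportions(beta_train, ref)
    report <- log_stage(report, "cell_proportions",
                        n_celltypes = length(ref$cell_type_names),
                        mean_residual = mean(cellprops$residual))
  }

  train_sheet <- samples[samples$role == "train", ]
  fit <- fit_moderated_model(vf$beta, train_sheet, cellprops)
  mwu <- mann_whitney_per_probe(vf$beta, train_sheet)
  deltas <- compute_delta_beta(vf$beta, train_sheet)
  sig_primary <- derive_signature(fit, mwu, deltas,
                                  q_thresh = config$q_thresh,
                                  delta_thresh = config$delta_thresh)
  sig_strict <- derive_signature(fit, mwu, deltas,
                                 q_thresh = config$q_thresh_strict,
                                 delta_thresh = config$delta_thresh)
  report <- log_stage(report, "signature",
                      q_thresh = config$q_thresh,
                      q_thresh_strict = config$q_thresh_strict,
                      delta_thresh = config$delta_thresh,
                      n_primary = nrow(sig_primary),
                      n_strict = nrow(sig_strict))
  write_signature(sig_primary, manifest,
                  file.path(config$out_dir, "signature_primary.tsv"))
  write_signature(sig_strict, manifest,
                  file.path(config$out_dir, "signature_strict.tsv"))

  cand <- find_candidate_regions(deltas, manifest,
                                 delta_thresh = config$delta_thresh,
                                 max_gap = config$dmr$max_gap)
  if (nrow(cand) > 0) {
    cand <- bootstrap_region_pvalues(
      vf$beta, train_sheet, cellprops, cand, manifest,
      B = config$dmr$B, seed = config$seed + 101L,
      delta_thresh = config$delta_thresh, max_gap = config$dmr$max_gap)
  }
  dmrs <- filter_dmrs(cand, sig_primary, p_thresh = config$dmr$p,
                      delta_thresh = config$delta_thresh,
                      min_cpgs = config$dmr$min_cpgs)
  report <- log_stage(report, "dmr", B = config$dmr$B,
                      max_gap = config$dmr$max_gap,
                      min_cpgs = config$dmr$min_cpgs, p = config$dmr$p,
                      n_candidates = nrow(cand), n_dmrs = nrow(dmrs))
  write_dmrs(dmrs, bed_path = file.path(config$out_dir, "dmrs.bed"),
             tsv_path = file.path(config$out_dir, "dmrs.tsv"))

  scores <- NULL
  evaluation <- NULL
  if (nrow(sig_strict) >= 10 && length(test) > 0) {
    case_ids <- train_sheet$sample_id[train_sheet$group == "case"]
    ctrl_ids <- train_sheet$sample_id[train_sheet$group == "control"]
    refs <- build_reference_profiles(beta_train, sig_strict,
                                     case_ids, ctrl_ids)
    scores <- score_samples(centered[, test, drop = FALSE], refs,
                            method = config$classifier_method)
    truth <- tibble::tibble(
      sample_id = test,
      label = ifelse(samples$group[match(test, samples$sample_id)] == "case",
                     "carrier", "non_carrier"))
    evaluation <- evaluate_classification(scores, truth)
    report <- log_stage(report, "classification",
                        n_signature = nrow(sig_strict),
                        n_test = length(test),
                        sensitivity = evaluation$sensitivity,
                        specificity = evaluation$specificity)
    write_scores(scores, file.path(config$out_dir, "scores.tsv"))
  } else {
    report <- log_stage(report, "classification", skipped = TRUE,
                        n_signature = nrow(sig_strict), n_test = length(test))
  }

  enr <- feature_enrichment(sig_primary, rownames(vf$beta), manifest)
  report <- log_stage(report, "enrichment",
                      n_categories = nrow(enr),
                      n_flagged = sum(enr$direction != "ns"))
  readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))

  report$results <- list(qc = qc$report, signature_primary = sig_primary,
                         signature_strict = sig_strict, dmrs = dmrs,
                         scores = scores, evaluation = evaluation,
                         enrichment = enr)
  jsonlite::write_json(
    list(parameters = report$parameters, stages = report$stages),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}

#' Z-score normalisation and PCA for visualisation
#'
#' Per-probe z-scoring (mean 0, variance 1 across samples; zero-variance
#' probes excluded with a warning) followed by principal component analysis
#' via singular value decomposition of the sample-centred z-matrix — the
#' normalisation used for heat maps and PCA panels.
#'
#' @param beta Probes x samples matrix (>= 2 probes, >= 2 samples).
#' @param n_components Number of components to return; default 3.
#' @return A list of class `methsig_pca`: `z` (z-scored matrix), `scores`
#'   (tibble: `sample_id`, `PC1`..), `var_explained`.
#' @export
normalize_for_visualization <- function(beta, n_components = 3) {
  if (nrow(beta) < 2 || ncol(beta) < 2) {
    abort("Need >= 2 probes and >= 2 samples.",
          class = "methsig_parameter_error")
  }
  sds <- row_sds(beta)
  if (any(sds == 0)) {
    warn(sprintf("Excluding %d zero-variance probes.", sum(sds == 0)))
    beta <- beta[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (beta - rowMeans(beta)) / sds
  X <- t(z)                         # samples x probes; columns have mean 0
  sv <- svd(X)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(
    z = z,
    scores = dplyr::bind_cols(tibble::tibble(sample_id = colnames(beta)),
                              tibble::as_tibble(scores)),
    var_explained = sv$d^2 / sum(sv$d^2))
  class(out) <- "methsig_pca"
  out
}

#' PCA plot of normalised samples
#'
#' @param x A `methsig_pca`.
#' @param colour Optional vector (aligned to samples) mapped to colour,
#'   e.g. group labels.
#' @return A ggplot object.
#' @export
plot_pca <- function(x, colour = NULL) {
  stopifnot(inherits(x, "methsig_pca"))
  dat <- x$scores
  if (!is.null(colour)) dat$colour <- colour
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]))
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}
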