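#' Read a beta-value matrix from TSV
#'
#' Expects a tab-separated file whose first column (`probe_id`) holds probe
#' ids and whose header row holds sample ids. Values are validated to lie in
#' `[0, 1]`; the first offending cell is named in the error. Duplicate probe
#' or sample ids are rejected. Missing values are rejected unless
#' `impute = TRUE`, in which case they are replaced by the probe mean.
#'
#' @param path TSV file path.
#' @param impute Impute missing entries by per-probe means; default `FALSE`.
#' @return Probes x samples numeric matrix.
#' @export
read_beta_matrix <- function(path, impute = FALSE) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(dat)[1] != "probe_id") {
    abort("First column must be `probe_id`.", class = "methsig_parse_error")
  }
  if (anyDuplicated(dat$probe_id)) {
    abort("Duplicate probe ids in beta matrix.", class = "methsig_parse_error")
  }
  if (anyDuplicated(names(dat))) {
    abort("Duplicate sample ids in beta matrix.", class = "methsig_parse_error")
  }
  m <- as.matrix(dat[, -1, drop = FALSE])
  rownames(m) <- dat$probe_id
  if (anyNA(m)) {
    if (!impute) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      abort(sprintf("Missing value at probe %s, sample %s (set impute = TRUE to mean-impute).",
                    rownames(m)[bad[1]], colnames(m)[bad[2]]),
            class = "methsig_parse_error")
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
    }
  }
  out_of_range <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    abort(sprintf("Beta value outside [0, 1] at probe %s, sample %s.",
                  rownames(m)[out_of_range[1, 1]],
                  colnames(m)[out_of_range[1, 2]]),
          class = "methsig_parse_error")
  }
  m
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]; values at full precision.
#'
#' @param beta Probes x samples matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  assert_beta_matrix(beta)
  dat <- dplyr::bind_cols(tibble::tibble(probe_id = rownames(beta)),
                          tibble::as_tibble(beta))
  readr::write_tsv(dat, path)
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' @param path CSV file path.
#' @return Sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "group", "role", "age", "sex", "batch", "platform")
  miss <- setdiff(needed, names(s))
  if (length(miss) > 0) {
    abort(paste0("Sample sheet missing columns: ", paste(miss, collapse = ", ")),
          class = "methsig_parse_error")
  }
  if (anyDuplicated(s$sample_id)) {
    abort("Duplicate sample ids in sample sheet.", class = "methsig_parse_error")
  }
  if (anyNA(s[needed])) {
    abort("Sample sheet has missing covariate values.",
          class = "methsig_parse_error")
  }
  s
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Read / write a probe manifest (CSV)
#'
#' @param path CSV file path.
#' @return Manifest tibble (see [generate_manifest()] for columns).
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(m$probe_id)) {
    abort("Duplicate probe ids in manifest.", class = "methsig_parse_error")
  }
  if ("pos" %in% names(m)) m$pos <- as.integer(m$pos)
  if ("gene" %in% names(m)) m$gene <- dplyr::coalesce(m$gene, "")
  m
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Read / write a cell-type reference (CSV)
#'
#' Wide CSV: first column `cell_type`, remaining columns marker probe ids.
#'
#' @param path CSV file path.
#' @return A `methsig_celltype_ref`.
#' @export
read_cell_reference <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(dat)[1] != "cell_type") {
    abort("First column must be `cell_type`.", class = "methsig_parse_error")
  }
  M <- as.matrix(dat[, -1, drop = FALSE])
  rownames(M) <- dat$cell_type
  if (any(M < 0 | M > 1)) {
    abort("Cell reference values must lie in [0, 1].",
          class = "methsig_parse_error")
  }
  structure(list(mean_beta = M, marker_probe_ids = colnames(M),
                 cell_type_names = dat$cell_type),
            class = "methsig_celltype_ref")
}

#' @rdname read_cell_reference
#' @param ref A `methsig_celltype_ref`.
#' @export
write_cell_reference <- function(ref, path) {
  dat <- dplyr::bind_cols(tibble::tibble(cell_type = rownames(ref$mean_beta)),
                          tibble::as_tibble(ref$mean_beta))
  readr::write_csv(dat, path)
  invisible(path)
}

#' Write a synthetic cohort to an output directory
#'
#' Emits `beta.tsv`, `samples.csv`, `truth_probes.tsv` and (when cell
#' structure was simulated) `truth_cell_props.tsv`.
#'
#' @param cohort A `methsig_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "methsig_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.csv"))
  readr::write_tsv(cohort$truth$probes, file.path(dir, "truth_probes.tsv"))
  if (!is.null(cohort$truth$cell_props)) {
    readr::write_tsv(cohort$truth$cell_props,
                     file.path(dir, "truth_cell_props.tsv"))
  }
  invisible(dir)
}

#' Write a signature table (TSV)
#'
#' Annotates the signature with coordinates and gene symbols and writes a
#' TSV with `probe_id`, `chrom`, `pos`, `gene`, `delta`, `q_model`, `q_mwu`,
#' `direction`.
#'
#' @param signature A `methsig_signature`.
#' @param ann Probe annotation.
#' @param path Output TSV path.
#' @return The annotated tibble, invisibly.
#' @export
write_signature <- function(signature, ann, path) {
  out <- dplyr::left_join(
    tibble::as_tibble(signature),
    dplyr::select(ann, "probe_id", "chrom", "pos", "gene"),
    by = "probe_id") |>
    dplyr::select("probe_id", "chrom", "pos", "gene", "delta",
                  "q_model", "q_mwu", "direction")
  readr::write_tsv(out, path)
  invisible(out)
}

#' Write DMRs as BED and full TSV
#'
#' The BED file is 0-based half-open with columns chrom, start, end, name,
#' and `-log10(p_boot)` rounded to 3 decimals as score. The TSV carries all
#' fields with member probes `;`-collapsed.
#'
#' @param dmrs A `methsig_dmr` tibble with `p_boot` set.
#' @param bed_path,tsv_path Output paths (`NULL` skips that file).
#' @return The flat tibble, invisibly.
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  flat <- dmrs |>
    dplyr::mutate(name = sprintf("DMR_%03d", dplyr::row_number()),
                  probe_ids = purrr::map_chr(.data$probe_ids, paste,
                                             collapse = ";")) |>
    tibble::as_tibble()
  if (!is.null(bed_path)) {
    bed <- dplyr::transmute(flat, .data$chrom, .data$start, .data$end,
                            .data$name,
                            score = round(-log10(.data$p_boot), 3))
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  if (!is.null(tsv_path)) readr::write_tsv(flat, tsv_path)
  invisible(flat)
}

#' Write classification scores (TSV)
#'
#' Scores are printed to 5 decimal places.
#'
#' @param scores A `methsig_scores` tibble.
#' @param path Output TSV path.
#' @return The formatted tibble, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- dplyr::mutate(scores,
                       score = sprintf("%.5f", .data$score),
                       r_case = sprintf("%.5f", .data$r_case),
                       r_control = sprintf("%.5f", .data$r_control))
  readr::write_tsv(out, path)
  invisible(out)
}
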