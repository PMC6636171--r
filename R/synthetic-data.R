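#' Generate a 450K-like probe manifest
#'
#' Builds a synthetic Illumina-450K-style probe annotation table: probes are
#' placed on chr1-chr22/chrX/chrY with sorted, clustered positions (a mixture
#' of short CpG-cluster gaps and long inter-cluster gaps), assigned gene
#' symbols in positional blocks, island-relation and RefSeq-group categories,
#' and the quality-control and feature flags the downstream filtering and
#' enrichment steps consume.
#'
#' Sex-chromosome probes are allocated exactly (`round(n_probes * fraction)`)
#' so the requested fraction is honoured deterministically; all other flags
#' are independent per-probe Bernoulli draws, so their realised fractions
#' concentrate within about +/-2% (absolute) of the request for
#' `n_probes >= 10000`.
#'
#' @param n_probes Number of probes (>= 100).
#' @param flag_fractions Named list overriding default category fractions.
#'   Recognised names: `sex_chrom`, `cross_reactive`, `snp_5bp`, `nonspecific`,
#'   `promoter`, `enhancer`, `dhs`, `rdmr`, `cdmr`, `cdmr_generic`, `on_epic`.
#' @param seed Integer seed; output is byte-identical for identical seeds.
#'
#' @return A tibble with one row per probe: `probe_id`, `chrom`, `pos`,
#'   `gene`, `refseq_group`, `island_relation`, `promoter_flag`,
#'   `enhancer_flag`, `dhs_flag`, `dmr_class`, `sex_chrom_flag`,
#'   `cross_reactive_flag`, `snp_5bp_flag`, `nonspecific_flag`, `on_450k`,
#'   `on_epic`.
#' @export
generate_manifest <- function(n_probes, flag_fractions = list(), seed) {
  if (!is.numeric(n_probes) || length(n_probes) != 1L || n_probes < 100) {
    abort("`n_probes` must be a single integer >= 100.",
          class = "methsig_parameter_error")
  }
  n_probes <- as.integer(n_probes)
  defaults <- list(
    sex_chrom = 0.03, cross_reactive = 0.06, snp_5bp = 0.05,
    nonspecific = 0.02, promoter = 0.20, enhancer = 0.15, dhs = 0.12,
    rdmr = 0.03, cdmr = 0.02, cdmr_generic = 0.02, on_epic = 0.92
  )
  unknown <- setdiff(names(flag_fractions), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown flag_fractions entries: ",
                 paste(unknown, collapse = ", ")),
          class = "methsig_parameter_error")
  }
  fr <- utils::modifyList(defaults, as.list(flag_fractions))
  for (nm in names(fr)) assert_fraction(fr[[nm]], paste0("flag_fractions$", nm))

  with_seed(seed, {
    n_sex <- round(n_probes * fr$sex_chrom)
    n_auto <- n_probes - n_sex
    # autosome weights roughly proportional to chromosome length
    auto_w <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 134,
                135, 134, 115, 107, 102, 90, 83, 78, 59, 63, 48, 51)
    chrom_auto <- sample(paste0("chr", 1:22), n_auto, replace = TRUE,
                         prob = auto_w / sum(auto_w))
    chrom_sex <- if (n_sex > 0) {
      sample(c("chrX", "chrY"), n_sex, replace = TRUE, prob = c(0.85, 0.15))
    } else {
      character(0)
    }
    chrom <- c(chrom_auto, chrom_sex)

    # per-chromosome positions: clustered gaps, strictly increasing
    pos <- integer(n_probes)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      k <- length(idx)
      clustered <- runif(k) < 0.55
      gaps <- ifelse(clustered,
                     round(runif(k, 30, 450)),
                     round(rexp(k, 1 / 15000)) + 501)
      pos[idx] <- round(runif(1, 1e4, 1e5)) + cumsum(gaps)
    }

    # gene blocks along each chromosome; ~25% of probes intergenic
    gene <- character(n_probes)
    gene_counter <- 0L
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      idx <- idx[order(pos[idx])]
      i <- 1L
      while (i <= length(idx)) {
        block <- min(1L + stats::rgeom(1, 1 / 3), length(idx) - i + 1L)
        if (runif(1) < 0.75) {
          gene_counter <- gene_counter + 1L
          gene[idx[i:(i + block - 1L)]] <- sprintf("GENE%05d", gene_counter)
        }
        i <- i + block
      }
    }

    refseq_levels <- c("TSS1500", "TSS200", "5'UTR", "Body", "3'UTR")
    refseq_group <- ifelse(
      gene == "", "Intergenic",
      sample(refseq_levels, n_probes, replace = TRUE,
             prob = c(0.15, 0.12, 0.12, 0.45, 0.16)))
    island_relation <- sample(
      c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
      n_probes, replace = TRUE,
      prob = c(0.31, 0.12, 0.11, 0.047, 0.045, 0.368))
    dmr_class <- sample(
      c("RDMR", "cDMR", "DMR", "none"), n_probes, replace = TRUE,
      prob = c(fr$rdmr, fr$cdmr, fr$cdmr_generic,
               1 - fr$rdmr - fr$cdmr - fr$cdmr_generic))

    out <- tibble::tibble(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      chrom = chrom,
      pos = as.integer(pos),
      gene = gene,
      refseq_group = refseq_group,
      island_relation = island_relation,
      promoter_flag = runif(n_probes) < fr$promoter,
      enhancer_flag = runif(n_probes) < fr$enhancer,
      dhs_flag = runif(n_probes) < fr$dhs,
      dmr_class = dmr_class,
      sex_chrom_flag = chrom %in% c("chrX", "chrY"),
      cross_reactive_flag = runif(n_probes) < fr$cross_reactive,
      snp_5bp_flag = runif(n_probes) < fr$snp_5bp,
      nonspecific_flag = runif(n_probes) < fr$nonspecific,
      on_450k = TRUE,
      on_epic = runif(n_probes) < fr$on_epic
    )
    dplyr::arrange(out, .data$chrom, .data$pos)
  })
}

#' Generate a synthetic purified cell-type methylation reference
#'
#' Emulates purified blood cell-type methylation profiles (the kind of data
#' used for reference-based deconvolution and the cell-type confound check).
#' For `separation > 0` every marker probe is constructed with a guaranteed
#' max-min contrast of exactly `separation` across cell types.
#'
#' @param n_celltypes Number of cell types (>= 2).
#' @param n_markers Number of marker probes (>= 10 * n_celltypes).
#' @param separation Guaranteed per-marker contrast between the most extreme
#'   cell types, on the beta scale; must be < 1. `0` disables the guarantee.
#' @param seed Integer seed.
#' @param probe_ids Optional pool of probe ids (e.g. a manifest's) from which
#'   marker probes are sampled; default generates standalone ids.
#' @param cell_type_names Optional names; defaults to common blood cell types.
#'
#' @return An object of class `methsig_celltype_ref`: a list with `mean_beta`
#'   (cell types x markers matrix in `[0,1]`), `marker_probe_ids` and
#'   `cell_type_names`.
#' @export
generate_celltype_reference <- function(n_celltypes = 6, n_markers = 60 * n_celltypes,
                                        separation = 0.3, seed,
                                        probe_ids = NULL,
                                        cell_type_names = NULL) {
  if (n_celltypes < 2) {
    abort("`n_celltypes` must be >= 2.", class = "methsig_parameter_error")
  }
  if (n_markers < 10 * n_celltypes) {
    abort("`n_markers` must be >= 10 * n_celltypes.",
          class = "methsig_parameter_error")
  }
  if (!is.numeric(separation) || separation < 0 || separation >= 1) {
    abort("`separation` must be in [0, 1).", class = "methsig_parameter_error")
  }
  if (is.null(cell_type_names)) {
    base_names <- c("Gran", "CD4T", "CD8T", "Bcell", "NK", "Mono")
    cell_type_names <- if (n_celltypes <= length(base_names)) {
      base_names[seq_len(n_celltypes)]
    } else {
      c(base_names, sprintf("Cell%02d", seq_len(n_celltypes - length(base_names))))
    }
  }
  with_seed(seed, {
    markers <- if (is.null(probe_ids)) {
      sprintf("mk%06d", seq_len(n_markers))
    } else {
      if (length(probe_ids) < n_markers) {
        abort("`probe_ids` pool smaller than `n_markers`.",
              class = "methsig_parameter_error")
      }
      sample(probe_ids, n_markers)
    }
    M <- matrix(0, nrow = n_celltypes, ncol = n_markers,
                dimnames = list(cell_type_names, markers))
    for (j in seq_len(n_markers)) {
      if (separation > 0) {
        low <- runif(1, 0.02, 0.98 - separation)
        v <- runif(n_celltypes, low, low + separation)
        ext <- sample(n_celltypes, 2)
        v[ext[1]] <- low
        v[ext[2]] <- low + separation
      } else {
        v <- runif(n_celltypes, 0.02, 0.98)
      }
      M[, j] <- v
    }
    structure(list(mean_beta = M,
                   marker_probe_ids = markers,
                   cell_type_names = cell_type_names),
              class = "methsig_celltype_ref")
  })
}

#' Specify a planted differential-methylation effect
#'
#' @param target_probes Character vector of probe ids to shift in cases.
#' @param delta_range Length-2 numeric, `0 < min <= max < 1`: the absolute
#'   beta-scale shift magnitudes, drawn uniformly per probe.
#' @param direction_mix Fraction of target probes hypomethylated in cases
#'   (shift applied with negative sign).
#' @return An object of class `methsig_effect_spec`.
#' @export
effect_spec <- function(target_probes, delta_range, direction_mix = 2 / 3) {
  if (length(delta_range) != 2 || delta_range[1] <= 0 ||
      delta_range[1] > delta_range[2] || delta_range[2] >= 1) {
    abort("`delta_range` must satisfy 0 < min <= max < 1.",
          class = "methsig_parameter_error")
  }
  assert_fraction(direction_mix, "direction_mix")
  structure(list(target_probes = as.character(target_probes),
                 delta_range = as.numeric(delta_range),
                 direction_mix = direction_mix),
            class = "methsig_effect_spec")
}

#' Specify cohort covariate structure
#'
#' Controls the demographic and technical covariates the cohort generator
#' plants: sampling ranges for age and sex, batch labels with beta-scale
#' offsets, and the fractions of probes carrying age slopes (per year) or
#' sex effects.
#'
#' @param age_range Length-2 numeric, years.
#' @param male_fraction Probability a sample is male.
#' @param batches Named numeric vector: batch label -> beta-scale offset
#'   applied to every probe of samples in that batch.
#' @param age_probe_fraction,sex_probe_fraction Fractions of (non-planted,
#'   non-marker) probes given an age slope / sex effect.
#' @param age_slope_sd SD of per-year beta-scale age slopes.
#' @param sex_delta_sd SD of beta-scale male-vs-female offsets.
#' @return An object of class `methsig_covariate_spec`.
#' @export
covariate_spec <- function(age_range = c(3, 16), male_fraction = 0.7,
                           batches = c(batch1 = 0),
                           age_probe_fraction = 0.02, age_slope_sd = 0.003,
                           sex_probe_fraction = 0.02, sex_delta_sd = 0.03) {
  if (length(age_range) != 2 || age_range[1] <= 0 || age_range[1] > age_range[2]) {
    abort("`age_range` must be increasing and positive.",
          class = "methsig_parameter_error")
  }
  if (is.null(names(batches)) || any(names(batches) == "")) {
    abort("`batches` must be a named numeric vector.",
          class = "methsig_parameter_error")
  }
  assert_fraction(male_fraction, "male_fraction")
  structure(list(age_range = age_range, male_fraction = male_fraction,
                 batches = batches,
                 age_probe_fraction = age_probe_fraction,
                 age_slope_sd = age_slope_sd,
                 sex_probe_fraction = sex_probe_fraction,
                 sex_delta_sd = sex_delta_sd),
            class = "methsig_covariate_spec")
}

# Build the per-probe generative model shared by the training cohort and any
# later test samples: baselines, planted deltas, covariate effects, markers.
build_cohort_model <- function(manifest, effects, covariates, celltype,
                               celltype_alpha, noise_sd, baseline = NULL) {
  n <- nrow(manifest)
  probe_ids <- manifest$probe_id

  if (is.null(baseline)) {
    comp <- runif(n) < 0.5
    baseline <- inv_logit(rnorm(n, mean = ifelse(comp, 2.2, -2.2), sd = 1.0))
    baseline <- pmin(pmax(baseline, 0.02), 0.98)
  } else {
    if (length(baseline) != n || any(baseline <= 0 | baseline >= 1)) {
      abort("`baseline` must give one mean in (0, 1) per manifest probe.",
            class = "methsig_parameter_error")
    }
  }

  delta <- numeric(n)
  planted <- logical(n)
  if (!is.null(effects)) {
    miss <- setdiff(effects$target_probes, probe_ids)
    if (length(miss) > 0) {
      abort(paste0("Effect target probes absent from manifest: ",
                   paste(head(miss, 5), collapse = ", ")),
            class = "methsig_reference_error")
    }
    idx <- match(effects$target_probes, probe_ids)
    flagged <- manifest$sex_chrom_flag[idx] | manifest$cross_reactive_flag[idx] |
      manifest$snp_5bp_flag[idx] | manifest$nonspecific_flag[idx]
    if (any(flagged)) {
      abort("Effect target probes must exclude QC-flagged probes.",
            class = "methsig_parameter_error")
    }
    sgn <- ifelse(runif(length(idx)) < effects$direction_mix, -1, 1)
    mag <- runif(length(idx), effects$delta_range[1], effects$delta_range[2])
    d <- sgn * mag
    # redraw baselines so both group means stay inside (0, 1): truth deltas
    # are then exact on the generating scale
    lo <- 0.02 + pmax(0, -d)
    hi <- 0.98 - pmax(0, d)
    baseline[idx] <- runif(length(idx), lo, hi)
    delta[idx] <- d
    planted[idx] <- TRUE
  }

  marker_idx <- integer(0)
  if (!is.null(celltype)) {
    miss <- setdiff(celltype$marker_probe_ids, probe_ids)
    if (length(miss) > 0) {
      abort(paste0("Cell-type marker probes absent from manifest: ",
                   paste(head(miss, 5), collapse = ", ")),
            class = "methsig_reference_error")
    }
    marker_idx <- match(celltype$marker_probe_ids, probe_ids)
    if (any(planted[marker_idx])) {
      abort("Cell-type marker probes overlap planted effect probes.",
            class = "methsig_parameter_error")
    }
    if (is.null(celltype_alpha)) {
      base_props <- c(0.55, 0.15, 0.08, 0.06, 0.05, 0.11)
      k <- length(celltype$cell_type_names)
      p <- if (k <= 6) base_props[seq_len(k)] else rep(1, k)
      celltype_alpha <- 30 * p / sum(p)
    }
  }

  eligible <- which(!planted & !(seq_len(n) %in% marker_idx))
  n_age <- round(covariates$age_probe_fraction * n)
  n_sex <- round(covariates$sex_probe_fraction * n)
  age_slope <- numeric(n)
  sex_delta <- numeric(n)
  if (n_age > 0) {
    a_idx <- sample(eligible, min(n_age, length(eligible)))
    age_slope[a_idx] <- rnorm(length(a_idx), 0, covariates$age_slope_sd)
    eligible <- setdiff(eligible, a_idx)
  }
  if (n_sex > 0) {
    s_idx <- sample(eligible, min(n_sex, length(eligible)))
    sex_delta[s_idx] <- rnorm(length(s_idx), 0, covariates$sex_delta_sd)
  }

  list(probe_ids = probe_ids, baseline = baseline, delta = delta,
       planted = planted, age_slope = age_slope, sex_delta = sex_delta,
       age_center = mean(covariates$age_range),
       marker_idx = marker_idx, celltype = celltype,
       celltype_alpha = celltype_alpha, covariates = covariates,
       noise_sd = noise_sd)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Draw beta values for a set of samples from a built model. `is_case` toggles
# the planted shift; ages/sexes/batches are vectors aligned to samples.
draw_beta <- function(model, sample_ids, is_case, ages, sexes, batch_labels) {
  n <- length(model$probe_ids)
  m <- length(sample_ids)
  mu <- matrix(model$baseline, nrow = n, ncol = m)
  if (any(is_case)) {
    mu[, is_case] <- mu[, is_case] + model$delta
  }
  mu <- mu + outer(model$age_slope, ages - model$age_center)
  mu <- mu + outer(model$sex_delta, as.numeric(sexes == "M"))

  W <- NULL
  if (length(model$marker_idx) > 0) {
    W <- rdirichlet(m, model$celltype_alpha)
    colnames(W) <- model$celltype$cell_type_names
    mu[model$marker_idx, ] <- t(W %*% model$celltype$mean_beta)
  }

  offsets <- model$covariates$batches[batch_labels]
  mu <- sweep(mu, 2, offsets, "+")

  beta <- clip_beta(mu + matrix(rnorm(n * m, 0, model$noise_sd), nrow = n))
  dimnames(beta) <- list(model$probe_ids, sample_ids)
  list(beta = beta, W = W)
}

draw_demographics <- function(model, m) {
  cov <- model$covariates
  list(
    age = round(runif(m, cov$age_range[1], cov$age_range[2]), 1),
    sex = ifelse(runif(m) < cov$male_fraction, "M", "F"),
    batch = sample(names(cov$batches), m, replace = TRUE)
  )
}

#' Generate a synthetic case/control methylation cohort
#'
#' Simulates a blood-methylation training cohort on a given manifest. Per-probe
#' baseline means are drawn from a bimodal logit-normal (the characteristic
#' two-peaked beta-value distribution); planted case shifts are additive on
#' the beta scale with baselines redrawn so both group-generating means stay
#' inside (0,1), making the recorded truth deltas exact; Gaussian noise of SD
#' `noise_sd` is added on the beta scale and values clipped to
#' `[1e-6, 1 - 1e-6]`. Optional structure: per-year age slopes and sex offsets
#' at random probe subsets, per-batch mean shifts, and cell-type mixtures
#' `W %*% M` at marker probes with per-sample Dirichlet proportions `W`.
#'
#' The fitted generative model is stored in the returned object so that
#' [draw_samples()] can later draw independent test samples (carriers or
#' controls) from exactly the same model.
#'
#' @param manifest Probe annotation tibble from [generate_manifest()].
#' @param n_cases,n_controls Group sizes (each >= 2).
#' @param effects Optional [effect_spec()]; `NULL` plants nothing.
#' @param covariates A [covariate_spec()].
#' @param celltype Optional [generate_celltype_reference()] result whose
#'   marker probes all exist in `manifest`.
#' @param celltype_alpha Optional Dirichlet concentration vector (one entry
#'   per cell type); default emulates whole-blood proportions.
#' @param noise_sd Beta-scale noise SD; default 0.03.
#' @param seed Integer seed.
#' @param baseline Optional per-probe population mean vector (manifest order),
#'   e.g. another cohort's `truth$probes$baseline`: cohorts emulating
#'   comparisons drawn from one population share their baseline methylome.
#'   Baselines at this cohort's planted probes are redrawn so the truth
#'   deltas stay exact.
#'
#' @return An object of class `methsig_cohort`: list with `beta` (probes x
#'   samples matrix), `samples` (sample-sheet tibble), `truth` (list of
#'   `probes` and `cell_props` tibbles) and the stored generative `model`.
#' @export
generate_cohort <- function(manifest, n_cases, n_controls, effects = NULL,
                            covariates = covariate_spec(), celltype = NULL,
                            celltype_alpha = NULL, noise_sd = 0.03, seed,
                            baseline = NULL) {
  if (n_cases < 2 || n_controls < 2) {
    abort("`n_cases` and `n_controls` must each be >= 2.",
          class = "methsig_parameter_error")
  }
  assert_fraction(noise_sd, "noise_sd", open_hi = TRUE)
  with_seed(seed, {
    model <- build_cohort_model(manifest, effects, covariates, celltype,
                                celltype_alpha, noise_sd, baseline)
    m <- n_cases + n_controls
    ids <- c(sprintf("case_%02d", seq_len(n_cases)),
             sprintf("ctrl_%02d", seq_len(n_controls)))
    grp <- rep(c("case", "control"), c(n_cases, n_controls))
    demo <- draw_demographics(model, m)
    drawn <- draw_beta(model, ids, grp == "case", demo$age, demo$sex, demo$batch)

    samples <- tibble::tibble(
      sample_id = ids, group = grp, role = "train",
      age = demo$age, sex = demo$sex, batch = demo$batch, platform = "450K")
    truth_probes <- tibble::tibble(
      probe_id = model$probe_ids, baseline = model$baseline,
      delta = model$delta, planted = model$planted,
      age_slope = model$age_slope, sex_delta = model$sex_delta,
      is_marker = seq_along(model$probe_ids) %in% model$marker_idx)
    cell_props <- if (!is.null(drawn$W)) {
      dplyr::bind_cols(tibble::tibble(sample_id = ids),
                       tibble::as_tibble(drawn$W))
    } else {
      NULL
    }
    structure(list(beta = drawn$beta, samples = samples,
                   truth = list(probes = truth_probes, cell_props = cell_props),
                   model = model),
              class = "methsig_cohort")
  })
}

#' Draw independent samples from a cohort's generative model
#'
#' Draws new samples (fresh demographics, cell proportions and noise) from the
#' stored generative model of a [generate_cohort()] result. `group = "case"`
#' applies the cohort's planted effect; `group = "control"` draws from the
#' null model.
#'
#' @param cohort A `methsig_cohort`.
#' @param n Number of samples.
#' @param group `"case"` or `"control"`.
#' @param seed Integer seed.
#' @param prefix Sample-id prefix; default derived from `group`.
#' @param platform Recorded platform label, `"450K"` or `"EPIC"`.
#' @return A list with `beta`, `samples` (role `"test"`), and `cell_props`.
#' @export
draw_samples <- function(cohort, n, group = c("control", "case"), seed,
                         prefix = NULL, platform = "450K") {
  stopifnot(inherits(cohort, "methsig_cohort"))
  group <- match.arg(group)
  if (n < 1) abort("`n` must be >= 1.", class = "methsig_parameter_error")
  if (is.null(prefix)) prefix <- if (group == "case") "test_case" else "test_ctrl"
  with_seed(seed, {
    model <- cohort$model
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    demo <- draw_demographics(model, n)
    drawn <- draw_beta(model, ids, rep(group == "case", n),
                       demo$age, demo$sex, demo$batch)
    samples <- tibble::tibble(
      sample_id = ids, group = group, role = "test",
      age = demo$age, sex = demo$sex, batch = demo$batch, platform = platform)
    cell_props <- if (!is.null(drawn$W)) {
      dplyr::bind_cols(tibble::tibble(sample_id = ids),
                       tibble::as_tibble(drawn$W))
    } else {
      NULL
    }
    list(beta = drawn$beta, samples = samples, cell_props = cell_props)
  })
}

#' Draw purified cell-type profiles from a cohort's model
#'
#' Constructs one noisy profile per cell type: the cohort baseline everywhere
#' except at marker probes, which are set to that cell type's reference row
#' (a vertex of the mixture simplex). Used for the cell-type confound check:
#' none of these profiles carries a planted effect, so a sound episignature
#' classifier must call them all control-like.
#'
#' @param cohort A `methsig_cohort` generated with a cell-type reference.
#' @param seed Integer seed.
#' @return A beta matrix with one column per cell type.
#' @export
draw_celltype_profiles <- function(cohort, seed) {
  stopifnot(inherits(cohort, "methsig_cohort"))
  model <- cohort$model
  if (length(model$marker_idx) == 0) {
    abort("Cohort was generated without a cell-type reference.",
          class = "methsig_parameter_error")
  }
  with_seed(seed, {
    M <- model$celltype$mean_beta
    k <- nrow(M)
    n <- length(model$probe_ids)
    beta <- matrix(model$baseline, nrow = n, ncol = k)
    beta[model$marker_idx, ] <- t(M)
    beta <- clip_beta(beta + matrix(rnorm(n * k, 0, model$noise_sd), nrow = n))
    dimnames(beta) <- list(model$probe_ids, rownames(M))
    beta
  })
}
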