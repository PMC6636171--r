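#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rbinom rexp rgamma median sd qnorm pnorm pt
#'   phyper p.adjust prcomp dwilcox pwilcox
#' @importFrom utils head
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "methsig_parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Clip to the open unit interval used throughout for stored beta values.
clip_beta <- function(x, eps = 1e-6) {
  pmin(pmax(x, eps), 1 - eps)
}

row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) abort("At least 2 samples are required to compute SDs.")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

assert_beta_matrix <- function(beta, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric probes x samples matrix.", arg),
          class = "methsig_parameter_error")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort(sprintf("`%s` must have probe rownames and sample colnames.", arg),
          class = "methsig_parameter_error")
  }
  if (anyDuplicated(rownames(beta))) {
    abort(sprintf("`%s` has duplicated probe ids.", arg),
          class = "methsig_validation_error")
  }
  if (anyDuplicated(colnames(beta))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg),
          class = "methsig_validation_error")
  }
  if (anyNA(beta)) {
    abort(sprintf("`%s` contains missing values.", arg),
          class = "methsig_validation_error")
  }
  if (any(beta < 0) || any(beta > 1)) {
    abort(sprintf("`%s` contains values outside [0, 1].", arg),
          class = "methsig_validation_error")
  }
  invisible(beta)
}

assert_fraction <- function(x, arg, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a number in [%s, %s%s.", arg, lo, hi,
                  if (open_hi) ")" else "]"),
          class = "methsig_parameter_error")
  }
  invisible(x)
}

# Case/control labels aligned to the columns of a beta matrix.
group_indicator <- function(beta, samples) {
  stopifnot(is.data.frame(samples))
  missing <- setdiff(colnames(beta), samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples absent from sample sheet: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "methsig_reference_error")
  }
  grp <- samples$group[match(colnames(beta), samples$sample_id)]
  if (!all(grp %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control' for every sample.",
          class = "methsig_validation_error")
  }
  grp
}
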