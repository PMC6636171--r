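# Independent brute-force oracles used to verify the fast implementations.

# Step-up FDR adjustment straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- qs
  q
}

# Exhaustive two-sided Mann-Whitney p: enumerate every assignment of n1 case
# labels to the pooled values and count |U - n1 n2 / 2| at least as extreme.
mwu_exact_oracle <- function(x_case, x_ctrl) {
  pool <- c(x_case, x_ctrl)
  n1 <- length(x_case)
  n2 <- length(x_ctrl)
  mid <- n1 * n2 / 2
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pool), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# Hypergeometric tails by explicit log-space summation.
hyper_tails_oracle <- function(k, K, N, n) {
  supp <- max(0, n - (N - K)):min(n, K)
  logp <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
  pm <- exp(logp)
  list(upper = sum(pm[supp >= k]), lower = sum(pm[supp <= k]))
}

# Brute-force maximal-run enumerator for DMR candidate discovery on one
# chromosome: checks every window [i, j] for validity and maximality.
region_oracle <- function(pos, delta, delta_thresh = 0.05, max_gap = 500) {
  o <- order(pos)
  pos <- pos[o]
  delta <- delta[o]
  n <- length(pos)
  valid <- function(i, j) {
    d <- delta[i:j]
    if (any(abs(d) < delta_thresh)) return(FALSE)
    if (length(unique(sign(d))) > 1) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > max_gap)) return(FALSE)
    TRUE
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (valid(i, j) &&
          (i == 1 || !valid(i - 1, j)) &&
          (j == n || !valid(i, j + 1))) {
        out[[length(out) + 1]] <- c(start = pos[i], end = pos[j],
                                    n_cpgs = j - i + 1)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), n_cpgs = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Small annotation builder for fixtures.
make_ann <- function(probe_id, chrom = "chr1", pos = seq_along(probe_id) * 1000,
                     gene = "", sex_chrom = FALSE, cross_reactive = FALSE,
                     snp_5bp = FALSE, nonspecific = FALSE) {
  n <- length(probe_id)
  tibble::tibble(
    probe_id = probe_id, chrom = rep_len(chrom, n), pos = as.integer(pos),
    gene = rep_len(gene, n), refseq_group = "Body",
    island_relation = "OpenSea", promoter_flag = FALSE,
    enhancer_flag = FALSE, dhs_flag = FALSE, dmr_class = "none",
    sex_chrom_flag = rep_len(sex_chrom, n),
    cross_reactive_flag = rep_len(cross_reactive, n),
    snp_5bp_flag = rep_len(snp_5bp, n),
    nonspecific_flag = rep_len(nonspecific, n),
    on_450k = TRUE, on_epic = TRUE)
}

make_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%03d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probe_ids, sample_ids)
  m
}

make_sheet <- function(beta, group, age = NULL, sex = NULL, batch = "b1",
                       role = "train") {
  n <- ncol(beta)
  if (is.null(age)) age <- seq(5, 15, length.out = n)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  tibble::tibble(sample_id = colnames(beta), group = rep_len(group, n),
                 role = rep_len(role, n), age = age, sex = rep_len(sex, n),
                 batch = rep_len(batch, n), platform = "450K")
}
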