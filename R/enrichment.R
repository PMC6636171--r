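default_feature_categories <- function() {
  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea",
    "Promoter", "Enhancer", "DHS", "RDMR", "cDMR", "DMR",
    "TSS1500", "TSS200", "5'UTR", "Body", "3'UTR", "Intergenic")
}

category_members <- function(ann, category) {
  switch(category,
    Island = , N_Shore = , S_Shore = , N_Shelf = , S_Shelf = , OpenSea =
      ann$probe_id[ann$island_relation == category],
    Promoter = ann$probe_id[ann$promoter_flag],
    Enhancer = ann$probe_id[ann$enhancer_flag],
    DHS = ann$probe_id[ann$dhs_flag],
    RDMR = , cDMR = , DMR = ann$probe_id[ann$dmr_class == category],
    TSS1500 = , TSS200 = , `5'UTR` = , Body = , `3'UTR` = , Intergenic =
      ann$probe_id[ann$refseq_group == category],
    abort(paste0("Unknown category: ", category),
          class = "methsig_parameter_error")
  )
}

#' Genomic-feature enrichment of signature CpGs
#'
#' Tests each feature category (CpG islands, shores, shelves, open sea,
#' promoters, enhancers, DNase hypersensitivity sites, reference DMR classes,
#' RefSeq gene groups) for enrichment or depletion of signature CpGs relative
#' to the variance-filtered background, with one-sided hypergeometric tails:
#' with `N` background probes of which `K` are in the category and a
#' signature of size `n` containing `k` category probes,
#' `p_enrich = P(X >= k)` and `p_deplete = P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Both tails include `P(X = k)` and are
#' reported separately (no two-sided doubling); the direction flag uses
#' p < 0.05.
#'
#' @param signature A `methsig_signature` (or character probe-id vector),
#'   a subset of the background.
#' @param background_probe_ids The variance-filtered probe universe.
#' @param ann Probe annotation covering the background.
#' @param categories Character vector of categories; see
#'   `default_feature_categories()`.
#' @return A tibble of class `methsig_enrichment`: `category`, `k`, `K`,
#'   `n`, `N`, `p_enrich`, `p_deplete`, `direction`.
#' @export
feature_enrichment <- function(signature, background_probe_ids, ann,
                               categories = default_feature_categories()) {
  sig_ids <- if (is.character(signature)) signature else signature$probe_id
  if (!all(sig_ids %in% background_probe_ids)) {
    abort("Signature must be a subset of the background probe set.",
          class = "methsig_parameter_error")
  }
  bg <- unique(background_probe_ids)
  N <- length(bg)
  n <- length(unique(sig_ids))
  rows <- purrr::map_dfr(categories, function(cat) {
    members <- intersect(category_members(ann, cat), bg)
    K <- length(members)
    k <- sum(sig_ids %in% members)
    p_enrich <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_deplete <- phyper(k, K, N - K, n)
    tibble::tibble(category = cat, k = k, K = K, n = n, N = N,
                   p_enrich = p_enrich, p_deplete = p_deplete,
                   direction = if (p_enrich < 0.05) "enriched"
                               else if (p_deplete < 0.05) "depleted"
                               else "ns")
  })
  class(rows) <- c("methsig_enrichment", class(rows))
  rows
}

#' Map probes to unique gene symbols
#'
#' @param probes Character vector of probe ids.
#' @param ann Probe annotation with `probe_id` and `gene`.
#' @return A list: `genes` (unique, sorted symbols of probes with a non-empty
#'   gene annotation), `n_unannotated` (probes dropped for lacking a gene or
#'   an annotation row).
#' @export
map_probes_to_genes <- function(probes, ann) {
  g <- ann$gene[match(probes, ann$probe_id)]
  dropped <- sum(is.na(g) | g == "")
  genes <- sort(unique(g[!is.na(g) & g != ""]))
  list(genes = genes, n_unannotated = dropped)
}

#' Hypergeometric gene-set overlap test
#'
#' Overlap of two gene sets within a stated universe, with
#' `p = P(X >= |A intersect B|)` for
#' `X ~ Hypergeometric(|U|, |B|, |A|)` — the chance of an overlap at least
#' this large when `A` is drawn uniformly from the universe.
#'
#' @param set_a,set_b Character gene vectors, both subsets of `universe`.
#' @param universe Character gene vector.
#' @return A list: `overlap` (sorted genes), `n_overlap`, `p`, and the sizes
#'   `n_a`, `n_b`, `n_universe`.
#' @export
gene_overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad) > 0) {
    abort(paste0("Genes outside the universe: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "methsig_parameter_error")
  }
  ov <- sort(intersect(set_a, set_b))
  k <- length(ov)
  p <- phyper(k - 1, length(set_b), length(universe) - length(set_b),
              length(set_a), lower.tail = FALSE)
  list(overlap = ov, n_overlap = k, p = p,
       n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe))
}
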