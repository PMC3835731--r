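#' Analysis configuration
#'
#' Bundles every tunable of the pipeline in one object so that a run is fully
#' determined by (inputs, config). Defaults follow the published study design:
#' five score levels with spacing three, a Fisher-z correlation cutoff of 0.52
#' (one-sided tail probability about 0.3), expression filtering at top 10,000
#' in at least 30% of samples, differential expression at adjusted p < 1e-4,
#' 10,000 permutation replicates and a reporting threshold of q < 0.1.
#'
#' @param K number of discretized score levels.
#' @param b spacing between adjacent score levels (levels are `1, 1+b, ...,
#'   1+b*(K-1)`).
#' @param R number of stratified permutation replicates for the empirical
#'   null. 10,000 for production runs; 1,000 is adequate for desk-scale work.
#' @param z_cutoff Fisher-z cutoff used to translate a correlation into the
#'   clustering stop rule.
#' @param de_alpha adjusted-p threshold declaring a gene differentially
#'   expressed.
#' @param top_n,sample_fraction expression filter: keep a gene when it ranks
#'   within the `top_n` highest values in at least
#'   `ceiling(sample_fraction * n_samples)` samples.
#' @param q_threshold q-value below which a miRNA family is reported as
#'   perturbed.
#' @param min_size minimum signature size (genes).
#' @param max_size_fraction maximum signature size as a fraction of the number
#'   of differentially expressed genes.
#' @param dedup_jaccard signatures with Jaccard similarity at or above this
#'   value to an already-kept signature are suppressed.
#' @param seed integer seed governing every stochastic step.
#' @param paired use a paired t-test (requires a pairing in the study);
#'   otherwise Welch's two-sample t-test.
#' @param cor_method `"pearson"` or `"spearman"` gene-gene correlation.
#' @param abs_cor cluster on `|r|` instead of signed correlation.
#' @param n_swaps_per_edge attempted double-edge swaps per edge and per score
#'   level when randomizing the target network.
#' @return a list of class `mirhic_config`.
#' @export
mirhic_config <- function(K = 5L, b = 3L, R = 10000L,
                          z_cutoff = 0.52, de_alpha = 1e-4,
                          top_n = 10000L, sample_fraction = 0.3,
                          q_threshold = 0.1,
                          min_size = 30L, max_size_fraction = 0.8,
                          dedup_jaccard = 0.9,
                          seed = 1L, paired = FALSE,
                          cor_method = c("pearson", "spearman"),
                          abs_cor = FALSE,
                          n_swaps_per_edge = 10) {
  cor_method <- match.arg(cor_method)
  stopifnot(K >= 1, b >= 1, R >= 1, de_alpha > 0, de_alpha <= 1,
            top_n >= 1, sample_fraction > 0, sample_fraction <= 1,
            min_size >= 2, max_size_fraction > 0, max_size_fraction <= 1,
            dedup_jaccard > 0, dedup_jaccard <= 1, n_swaps_per_edge > 0)
  structure(list(K = as.integer(K), b = as.integer(b), R = as.integer(R),
                 z_cutoff = z_cutoff, de_alpha = de_alpha,
                 top_n = as.integer(top_n), sample_fraction = sample_fraction,
                 q_threshold = q_threshold,
                 min_size = as.integer(min_size),
                 max_size_fraction = max_size_fraction,
                 dedup_jaccard = dedup_jaccard,
                 seed = as.integer(seed), paired = paired,
                 cor_method = cor_method, abs_cor = abs_cor,
                 n_swaps_per_edge = n_swaps_per_edge),
            class = "mirhic_config")
}

#' @export
print.mirhic_config <- function(x, ...) {
  cat("mirhic_config\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
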