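#' miRDeG baseline: enrichment in the flat DE gene set
#'
#' Runs the identical permutation machinery with the whole differentially
#' expressed gene set as the only signature, so the P-score step is
#' degenerate. This is the natural comparator for the hierarchical method: a
#' family whose targets concentrate in one small co-expression module is
#' diluted over the full DE set here.
#'
#' @param study an `expression_study`.
#' @param net a `target_network`.
#' @param config a [mirhic_config()].
#' @return a `mirhic_result` with `method = "miRDeG"`.
#' @export
run_mirdeg <- function(study, net, config = mirhic_config()) {
  fs <- filter_low_expression(study, config$top_n, config$sample_fraction)
  de <- differential_expression(fs, config$paired, config$de_alpha)
  if (!length(de$de_genes)) stop("no differentially expressed genes")
  res <- run_mirhic(study, net, config,
                    signatures = flat_signature(de$de_genes))
  res$method <- "miRDeG"
  res
}

#' miRKM baseline: k-means signatures
#'
#' Partitions the DE genes into `k` clusters by k-means on their
#' expression profiles (rows standardized to zero mean and unit variance,
#' Euclidean distance, seeded initialization with multiple restarts) and
#' feeds the clusters to the same enrichment chain. `k = 5` and `k = 10` are
#' the conventional settings (miRKM5, miRKM10); `k = 1` degenerates to
#' miRDeG.
#'
#' @param study an `expression_study`.
#' @param net a `target_network`.
#' @param config a [mirhic_config()].
#' @param k number of clusters.
#' @return a `mirhic_result` with `method = "miRKM<k>"`.
#' @export
run_mirkm <- function(study, net, config = mirhic_config(), k = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  fs <- filter_low_expression(study, config$top_n, config$sample_fraction)
  de <- differential_expression(fs, config$paired, config$de_alpha)
  if (!length(de$de_genes)) stop("no differentially expressed genes")
  if (k > length(de$de_genes)) stop("k exceeds the number of DE genes")
  if (k == 1L) {
    sigs <- flat_signature(de$de_genes)
  } else {
    x <- fs$matrix[de$de_genes, , drop = FALSE]
    x <- t(scale(t(x)))
    x[!is.finite(x)] <- 0  # constant genes standardize to all-zero profiles
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
    km <- stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L)
    sigs <- lapply(sort(unique(km$cluster)), function(cl) {
      g <- names(km$cluster)[km$cluster == cl]
      list(id = paste0("K", cl), genes = g, size = length(g),
           level_correlation = NA_real_)
    })
  }
  res <- run_mirhic(study, net, config, signatures = sigs)
  res$method <- paste0("miRKM", k)
  res
}

#' Hypergeometric enrichment test
#'
#' Classical gene-set over-representation: the upper-tail hypergeometric
#' probability of drawing at least the observed number of target genes when
#' `|S|` genes are sampled from the universe. Deterministic — no permutation
#' involved — and blind to regulation-strength scores.
#'
#' @param gene_set signature or DE gene set (list with `genes`, or character
#'   vector); intersected with `universe`.
#' @param family miRNA family identifier in `net`.
#' @param net a `target_network` (discretization not required).
#' @param universe background gene universe (e.g. the filtered expression
#'   genes).
#' @return the upper-tail p-value.
#' @export
hypergeometric_test <- function(gene_set, family, net, universe) {
  if (is.list(gene_set)) gene_set <- gene_set$genes
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  S <- intersect(gene_set, universe)
  p <- net$pairs
  if (!any(p$family == family)) stop("unknown miRNA family: ", family)
  T_u <- intersect(p$gene[p$family == family], universe)
  ov <- length(intersect(S, T_u))
  stats::phyper(ov - 1, length(T_u), length(universe) - length(T_u),
                length(S), lower.tail = FALSE)
}
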