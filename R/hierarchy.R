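#' Pairwise gene-gene co-expression correlations
#'
#' Computes the symmetric gene x gene correlation matrix over all samples
#' (both groups: co-expression structure, not differential signal, drives the
#' hierarchy). A zero-variance gene gets correlation 0 to every other gene,
#' with a warning.
#'
#' @param study an `expression_study`.
#' @param genes genes to include (default: all rows).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return similarity matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
pairwise_correlation <- function(study, genes = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("gene(s) absent from the study: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 genes")
  if (ncol(m) < 4L) stop("need at least 4 samples")
  sds <- apply(m, 1L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(t(m), method = method))
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s): correlations set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  r
}

#' Correlation cutoff from a Fisher-z threshold
#'
#' Translates a z-score cutoff into a correlation on the sample-size scale:
#' `r* = tanh(z / sqrt(n - 3))`, inverting the Fisher transformation
#' `z = atanh(r) * sqrt(n - 3)` under which a sample correlation is
#' approximately standard normal. The implied one-sided normal tail
#' probability `1 - pnorm(z)` is reported in a message (z = 0.52 gives about
#' 0.3).
#'
#' @param z_cutoff z-score threshold (default 0.52).
#' @param n_samples number of samples used for the correlations (> 3).
#' @return the correlation cutoff r*.
#' @export
correlation_cutoff <- function(z_cutoff = 0.52, n_samples) {
  if (n_samples <= 3) stop("need more than 3 samples for the Fisher transform")
  rstar <- tanh(z_cutoff / sqrt(n_samples - 3))
  message(sprintf("z cutoff %.3g -> one-sided tail p %.3g, r* = %.4g at n = %d",
                  z_cutoff, 1 - stats::pnorm(z_cutoff), rstar,
                  as.integer(n_samples)))
  rstar
}

#' Average-linkage co-expression dendrogram with a stop rule
#'
#' Agglomerates genes by average linkage on the correlation matrix: at each
#' step the two clusters with the highest average inter-cluster correlation
#' merge. Clustering stops when the best available merge correlation falls
#' below `cutoff_r`, so the result may be a forest. (Average linkage on the
#' distance `1 - r` performs the identical agglomeration, and the linkage is
#' monotone, so the merges below the cutoff are exactly a suffix of the merge
#' list.)
#'
#' @param similarity symmetric correlation matrix with gene names.
#' @param cutoff_r minimum merge correlation; use `-1` to always build the
#'   full tree.
#' @return object of class `coexp_dendrogram`: the underlying
#'   [stats::hclust()] tree, `merge_correlation` per merge, the number of
#'   merges actually performed (`n_merges`), and the applied cutoff.
#' @export
build_dendrogram <- function(similarity, cutoff_r) {
  if (is.null(dim(similarity)) || nrow(similarity) == 0L)
    stop("empty similarity matrix")
  if (nrow(similarity) != ncol(similarity) ||
      max(abs(similarity - t(similarity))) > 1e-8)
    stop("similarity matrix must be symmetric")
  if (is.null(rownames(similarity)))
    stop("similarity matrix needs gene names")
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  mc <- 1 - hc$height
  below <- which(mc < cutoff_r)
  n_merges <- if (length(below)) min(below) - 1L else length(mc)
  structure(list(hclust = hc, merge_correlation = mc,
                 n_merges = n_merges, cutoff = cutoff_r,
                 leaves = rownames(similarity)),
            class = "coexp_dendrogram")
}

#' @export
print.coexp_dendrogram <- function(x, ...) {
  cat(sprintf("coexp_dendrogram: %d genes, %d/%d merges kept (cutoff r >= %.4g)\n",
              length(x$leaves), x$n_merges, length(x$merge_correlation),
              x$cutoff))
  invisible(x)
}

# gene sets of the internal nodes (merges) of an hclust tree, in merge order
merge_gene_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    parts <- lapply(hc$merge[k, ], function(v)
      if (v < 0) hc$labels[-v] else sets[[v]])
    sets[[k]] <- c(parts[[1]], parts[[2]])
  }
  sets
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Extract multi-scale co-expression signatures
#'
#' Walks the dendrogram leaf-to-root and collects the stable clusters as
#' signatures. Candidates are all internal nodes of every tree in the forest
#' whose size lies in `[min_size, max_size_fraction * n_genes]`; visiting
#' them in merge order (small, tight clusters first), a candidate is dropped
#' when its Jaccard similarity with an already-kept signature reaches
#' `dedup_jaccard` — so of two nearly identical nested clusters the smaller,
#' higher-correlation one survives, while genuinely distinct coarser scales
#' are kept as well. Output is ordered by size (ascending) with ids C1, C2,
#' ...
#'
#' @param dendro a `coexp_dendrogram`.
#' @param min_size minimum genes per signature (default 30).
#' @param max_size_fraction cap on signature size as a fraction of the
#'   clustered genes (default 0.8).
#' @param dedup_jaccard similarity at which a candidate is considered a
#'   duplicate (default 0.9).
#' @return list of signatures, each a list with `id`, `genes`, `size`,
#'   `level_correlation` (the merge correlation at which the cluster forms).
#'   Empty, with a warning, when nothing survives the bounds.
#' @export
extract_signatures <- function(dendro, min_size = 30L,
                               max_size_fraction = 0.8,
                               dedup_jaccard = 0.9) {
  stopifnot(inherits(dendro, "coexp_dendrogram"),
            min_size >= 2, max_size_fraction > 0, max_size_fraction <= 1,
            dedup_jaccard > 0, dedup_jaccard <= 1)
  n_genes <- length(dendro$leaves)
  max_size <- floor(max_size_fraction * n_genes)
  sets <- merge_gene_sets(dendro$hclust)
  kept <- list()
  for (k in seq_len(dendro$n_merges)) {
    g <- sets[[k]]
    if (length(g) < min_size || length(g) > max_size) next
    dup <- any(vapply(kept, function(s) jaccard(s$genes, g) >= dedup_jaccard,
                      logical(1)))
    if (dup) next
    kept[[length(kept) + 1L]] <- list(genes = g, size = length(g),
                                      level_correlation =
                                        dendro$merge_correlation[k])
  }
  if (!length(kept)) {
    warning("no signature satisfies the size bounds")
    return(list())
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "size"))]
  for (i in seq_along(kept)) kept[[i]]$id <- paste0("C", i)
  lapply(kept, function(s) s[c("id", "genes", "size", "level_correlation")])
}

#' Export a dendrogram in Newick format
#'
#' Leaf names are genes; branch lengths derive from `1 - merge correlation`.
#' The full tree (ignoring the stop rule) is written, since Newick has no
#' forest notion. Requires the `ape` package.
#'
#' @param dendro a `coexp_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  invisible(path)
}
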