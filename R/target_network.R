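#' Construct a miRNA-target network
#'
#' A target network is a weighted bipartite graph between miRNA families and
#' genes. Each (family, gene) pair carries the summarized context score
#' provided by the target-prediction table (a non-positive number; more
#' negative means stronger predicted repression) and, after
#' [discretize_scores()], an integer score level.
#'
#' @param pairs data.frame with columns `family`, `gene`, `context_score` and
#'   optionally `discretized_score`. One row per unique (family, gene) pair.
#' @param K,b discretization parameters recorded on the network once
#'   [discretize_scores()] has run, `NULL` before.
#' @return an object of class `target_network`: a list with elements `pairs`
#'   (the edge table), `K`, `b`.
#' @export
target_network <- function(pairs, K = NULL, b = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("family", "gene", "context_score") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("target network has no edges")
  pairs$family <- as.character(pairs$family)
  pairs$gene <- as.character(pairs$gene)
  pairs$context_score <- as.numeric(pairs$context_score)
  if (anyDuplicated(pairs[c("family", "gene")]))
    stop("duplicate (family, gene) pairs in target network")
  if (is.null(pairs$discretized_score))
    pairs$discretized_score <- NA_integer_
  structure(list(pairs = pairs[c("family", "gene", "context_score",
                                 "discretized_score")],
                 K = K, b = b),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  p <- x$pairs
  cat(sprintf("target_network: %d pairs, %d families, %d genes\n",
              nrow(p), length(unique(p$family)), length(unique(p$gene))))
  if (!is.null(x$K))
    cat(sprintf("  discretized: K=%d, b=%d, levels {%s}\n", x$K, x$b,
                paste(sort(unique(p$discretized_score)), collapse = ",")))
  else cat("  scores not discretized\n")
  invisible(x)
}

#' Number of edges in a target network
#' @param net a `target_network`.
#' @return integer edge count (the `N` of the discretization formula).
#' @export
n_pairs <- function(net) nrow(net$pairs)

#' Target gene sets per family
#' @param net a `target_network`.
#' @return named list mapping each miRNA family to its character vector of
#'   target genes.
#' @export
target_sets <- function(net) split(net$pairs$gene, net$pairs$family)

#' Read a miRNA-target table
#'
#' Reads a TargetScan-style tab-separated table with one row per
#' (miRNA family, gene) pair and a summarized context score. The reader
#' consumes a pre-summarized table: it never aggregates individual binding
#' sites itself. When the file carries duplicate (family, gene) rows the most
#' negative (strongest) score is kept and a warning is issued. Plain and
#' gzip-compressed files are both accepted.
#'
#' @param path path to the TSV file (header required).
#' @param family_col,gene_col,score_col column names in the header; defaults
#'   cover the generic dialect written by [write_edge_list()]. Column names
#'   are configurable because prediction-table headers drift between releases.
#' @return an undiscretized [target_network()].
#' @export
load_target_pairs <- function(path, family_col = "family",
                              gene_col = "gene",
                              score_col = "context_score") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty target table: ", path)
  for (col in c(family_col, gene_col, score_col))
    if (!col %in% names(d))
      stop(sprintf("target table %s is missing column '%s' (found: %s)",
                   path, col, paste(names(d), collapse = ", ")))
  pairs <- data.frame(family = as.character(d[[family_col]]),
                      gene = as.character(d[[gene_col]]),
                      context_score = as.numeric(d[[score_col]]),
                      stringsAsFactors = FALSE)
  dup <- duplicated(pairs[c("family", "gene")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (family, gene) rows; keeping most negative score",
                    sum(dup)))
    pairs <- collapse_pairs(pairs)
  }
  target_network(pairs)
}

# keep the most negative context score per (family, gene)
collapse_pairs <- function(pairs) {
  o <- order(pairs$family, pairs$gene, pairs$context_score)
  p <- pairs[o, , drop = FALSE]
  keep <- !duplicated(p[c("family", "gene")])
  rownames(p) <- NULL
  p[keep, , drop = FALSE]
}

#' Merge miRNA families
#'
#' Re-keys the edges of a network by a family label so that miRNAs sharing a
#' seed are treated as a single regulator. The merged family targets the union
#' of the member target sets; when several members target the same gene the
#' most negative context score is kept. Names absent from the map pass through
#' unchanged (a message reports how many).
#'
#' @param net a `target_network` (or a bare pairs data.frame).
#' @param family_map named character vector, member miRNA name -> family
#'   label. The identity map leaves the network unchanged.
#' @return a `target_network` with re-keyed, collapsed pairs; any existing
#'   discretization is dropped (scores must be re-discretized after merging).
#' @export
merge_families <- function(net, family_map) {
  pairs <- if (inherits(net, "target_network")) net$pairs else net
  stopifnot(!is.null(names(family_map)))
  hit <- pairs$family %in% names(family_map)
  if (any(!hit))
    message(sum(!hit), " miRNA name(s) not in family map; passed through")
  pairs$family[hit] <- unname(family_map[pairs$family[hit]])
  pairs$discretized_score <- NULL
  target_network(collapse_pairs(pairs))
}

#' Discretize context scores into K levels
#'
#' All pairs are sorted by context score in decreasing order, so the pairs at
#' the top of the ranking have the weakest predicted regulation. With 0-based
#' rank r among N pairs the discretized score is `1 + b * floor(r*K/N)`: the
#' weakest 1/K of pairs get score 1 and the strongest 1/K get `1 + b*(K-1)`.
#' Ties in context score are broken by a stable sort on (gene, family) so the
#' assignment is reproducible across platforms.
#'
#' @param net a `target_network`.
#' @param K number of levels (default 5).
#' @param b level spacing (default 3).
#' @return the network with `discretized_score` filled in and `K`, `b`
#'   recorded. Re-running the operation is idempotent.
#' @export
discretize_scores <- function(net, K = 5L, b = 3L) {
  stopifnot(inherits(net, "target_network"))
  K <- as.integer(K); b <- as.integer(b)
  if (K < 1L || b < 1L) stop("K and b must be positive integers")
  N <- n_pairs(net)
  if (K > N) stop(sprintf("K = %d exceeds the number of pairs N = %d", K, N))
  p <- net$pairs
  o <- order(-p$context_score, p$gene, p$family)
  p <- p[o, , drop = FALSE]
  r <- seq_len(N) - 1L
  p$discretized_score <- as.integer(1L + b * (r * K) %/% N)
  rownames(p) <- NULL
  net$pairs <- p
  net$K <- K
  net$b <- b
  net
}

#' Export target sets as GMT
#'
#' One line per gene set: name, description, then tab-separated genes — the
#' standard gene-matrix-transposed format.
#'
#' @param sets named list of character vectors, or a `target_network` (whose
#'   per-family target sets are written), or a signature list from
#'   [extract_signatures()].
#' @param path output file.
#' @param description single description string recycled per line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "mirhic") {
  if (inherits(sets, "target_network")) sets <- target_sets(sets)
  if (is.list(sets) && length(sets) && is.list(sets[[1]]) &&
      !is.null(sets[[1]]$genes)) {
    nm <- vapply(sets, function(s) s$id, "")
    sets <- stats::setNames(lapply(sets, function(s) s$genes), nm)
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a target network as an edge-list TSV
#'
#' Columns: family, gene, context_score, discretized_score.
#'
#' @param net a `target_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
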