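# Internal integer-index view of a discretized network, shared by the
# permutation and enrichment machinery. Factor levels fix the family/gene
# index <-> name mapping for a whole analysis.
net_index <- function(net) {
  if (is.null(net$K) || anyNA(net$pairs$discretized_score))
    stop("target network must be discretized first (see discretize_scores)")
  p <- net$pairs
  fams <- sort(unique(p$family))
  genes <- sort(unique(p$gene))
  list(fam = match(p$family, fams),
       gene = match(p$gene, genes),
       level = p$discretized_score,
       score = p$context_score,
       families = fams, genes = genes)
}

# rebuild a target_network from an index view with a new gene assignment
net_from_index <- function(net, ix, new_gene) {
  p <- net$pairs
  p$gene <- ix$genes[new_gene]
  net$pairs <- p
  net
}

#' Score-stratified randomization of a target network
#'
#' Randomizes the bipartite miRNA-target graph by repeated double-edge swaps
#' restricted to edges sharing a discretized score level: two edges
#' (m1,g1), (m2,g2) at the same level are replaced by (m1,g2), (m2,g1) unless
#' that would duplicate an existing edge at any level, in which case the
#' proposal is rejected. Per-level family degrees and per-level gene degrees
#' are therefore conserved exactly, and so is every family's target-set size
#' and total discretized-score mass. Levels with fewer than two edges are
#' left untouched.
#'
#' The swap budget counts attempted swaps (rejections included):
#' `ceiling(n_swaps_per_edge * edges-at-level)` per level. Because the
#' proposal is symmetric and rejections leave the state unchanged, the chain
#' is uniform over the graphs reachable under the degree and simplicity
#' constraints.
#'
#' @param net a discretized `target_network`.
#' @param seed integer seed (the replicate is a deterministic function of it).
#' @param n_swaps_per_edge attempted swaps per edge per level (default 10).
#' @return a `target_network` with the same families, levels and scores but
#'   permuted gene endpoints.
#' @export
permute_within_strata <- function(net, seed, n_swaps_per_edge = 10) {
  stopifnot(n_swaps_per_edge > 0)
  seed <- as.integer(seed)  # force before saving RNG state: the argument
                            # expression may itself consume random numbers
  ix <- net_index(net)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g2 <- stratified_swap_cpp(ix$fam - 1L, ix$gene - 1L, ix$level,
                            length(ix$families), length(ix$genes),
                            n_swaps_per_edge) + 1L
  net_from_index(net, ix, g2)
}

# save/restore the global RNG state so seeded internals do not clobber the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a collection of control networks
#'
#' Produces `R` independent stratified permutations of the source network.
#' Replicate `r` is generated with seed `seed + r`, so the collection is
#' reproducible, and any single replicate can be regenerated without the
#' others. By default replicates are not stored: [control_replicate()]
#' rebuilds them on demand, which keeps memory flat for large `R`.
#'
#' @param net a discretized `target_network`.
#' @param R number of replicates (>= 1).
#' @param seed base seed; replicate seeds are `seed + 1 ... seed + R`.
#' @param n_swaps_per_edge passed to [permute_within_strata()].
#' @param materialize store all replicate edge assignments in memory.
#' @return an object of class `control_collection`.
#' @export
generate_controls <- function(net, R, seed, n_swaps_per_edge = 10,
                              materialize = FALSE) {
  R <- as.integer(R)
  if (R < 1L) stop("R must be >= 1")
  cc <- structure(list(net = net, R = R, seed = as.integer(seed),
                       n_swaps_per_edge = n_swaps_per_edge,
                       replicates = NULL),
                  class = "control_collection")
  if (materialize)
    cc$replicates <- lapply(seq_len(R), function(r)
      control_replicate(cc, r))
  cc
}

#' Fetch one control replicate
#'
#' @param controls a `control_collection`.
#' @param r replicate index in `1..R`.
#' @return the r-th permuted `target_network`.
#' @export
control_replicate <- function(controls, r) {
  stopifnot(r >= 1, r <= controls$R)
  if (!is.null(controls$replicates)) return(controls$replicates[[r]])
  permute_within_strata(controls$net, controls$seed + as.integer(r),
                        controls$n_swaps_per_edge)
}

#' @export
print.control_collection <- function(x, ...) {
  cat(sprintf("control_collection: R=%d replicates (seed %d, %s)\n",
              x$R, x$seed,
              if (is.null(x$replicates)) "lazy" else "materialized"))
  invisible(x)
}
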