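# Independent oracles and toy builders used across the suite. These are
# deliberately naive (quadratic/cubic loops, exhaustive enumeration) and
# share no code with the package internals they check.

# -- naive average-linkage agglomeration (O(n^3)) ---------------------------
# Returns the merge sequence on a similarity matrix: at each step the pair of
# clusters with the largest mean inter-cluster similarity merges. Each merge
# records the merged label set (sorted) and the linkage value.
naive_avg_linkage <- function(sim) {
  labs <- rownames(sim)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_val <- -Inf
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1)) {
        v <- mean(sim[clusters[[a]], clusters[[b]]])
        if (v > best_val) { best_val <- v; best <- c(a, b) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- list(set = merged, value = best_val)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# -- exhaustive enumeration of score-stratified permutations ----------------
# All simple bipartite graphs sharing the source network's per-level family
# degrees and per-level gene degrees. Feasible only for toy graphs.

distinct_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    sub <- distinct_perms(rest)
    out[[length(out) + 1]] <- cbind(u, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

canon_edges <- function(pairs) {
  paste(sort(paste(pairs$family, pairs$gene, pairs$discretized_score,
                   sep = "|")), collapse = ";")
}

enumerate_stratified <- function(net) {
  p <- net$pairs
  lev <- sort(unique(p$discretized_score))
  per_level <- lapply(lev, function(l) {
    rows <- which(p$discretized_score == l)
    perms <- distinct_perms(p$gene[rows])
    # drop assignments duplicating a (family, gene) pair within the level
    ok <- apply(perms, 1, function(g)
      !anyDuplicated(paste(p$family[rows], g)))
    list(rows = rows, perms = perms[ok, , drop = FALSE])
  })
  combos <- expand.grid(lapply(per_level, function(x) seq_len(nrow(x$perms))))
  graphs <- list()
  for (i in seq_len(nrow(combos))) {
    q <- p
    for (k in seq_along(per_level))
      q$gene[per_level[[k]]$rows] <-
        per_level[[k]]$perms[combos[i, k], ]
    if (anyDuplicated(paste(q$family, q$gene))) next
    graphs[[canon_edges(q)]] <- q
  }
  graphs  # named list keyed by canonical form; keys are unique states
}

# -- toy network builders ----------------------------------------------------

# network with explicit discretized scores (bypasses ranking)
toy_net <- function(family, gene, level, K = 5L, b = 3L) {
  net <- target_network(data.frame(family = family, gene = gene,
                                   context_score = -as.numeric(level),
                                   stringsAsFactors = FALSE))
  net$pairs$discretized_score <- as.integer(level)
  net$K <- K
  net$b <- b
  net
}

random_net <- function(n_fam, n_gene, n_edges, seed) {
  set.seed(seed)
  all <- expand.grid(family = sprintf("m%02d", seq_len(n_fam)),
                     gene = sprintf("g%03d", seq_len(n_gene)),
                     stringsAsFactors = FALSE)
  take <- all[sample(nrow(all), n_edges), ]
  take$context_score <- -round(runif(n_edges, 0.01, 1), 4)
  target_network(take)
}

# small two-group study from an explicit matrix
toy_study <- function(m, n_case = NULL) {
  if (is.null(n_case)) n_case <- ncol(m) %/% 2
  expression_study(m, rep(c("case", "control"),
                          c(n_case, ncol(m) - n_case)))
}

# block-structured similarity matrix (deterministic)
block_sim <- function(blocks, within, between = 0) {
  genes <- unlist(blocks)
  s <- matrix(between, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_along(blocks))
    s[blocks[[i]], blocks[[i]]] <- within[i]
  diag(s) <- 1
  s
}

per_level_degrees <- function(net) {
  p <- net$pairs
  list(fam = table(p$family, p$discretized_score),
       gene = table(p$gene, p$discretized_score))
}
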