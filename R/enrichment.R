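# -- internal enrichment-score machinery ------------------------------------

# compressed gene -> signature membership (CSR over network gene indices)
signature_membership <- function(ix, signatures) {
  ng <- length(ix$genes)
  hits <- lapply(seq_along(signatures), function(j) {
    h <- match(signatures[[j]]$genes, ix$genes)
    h <- h[!is.na(h)]
    cbind(gene = h, sig = rep.int(j, length(h)))
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) hits <- cbind(gene = integer(), sig = integer())
  o <- order(hits[, "gene"])
  hits <- hits[o, , drop = FALSE]
  ptr <- c(0L, cumsum(tabulate(hits[, "gene"], nbins = ng)))
  list(ptr = as.integer(ptr), sig = as.integer(hits[, "sig"] - 1L),
       n_sig = length(signatures),
       ids = vapply(signatures, `[[`, "", "id"))
}

# ES matrix (families x signatures) for one gene assignment
es_matrix <- function(ix, gene_idx, M) {
  es <- es_sparse_cpp(ix$fam - 1L, gene_idx - 1L, ix$level,
                      length(ix$families), M$n_sig, M$ptr, M$sig)
  dimnames(es) <- list(ix$families, M$ids)
  es
}

#' Enrichment score of one miRNA family in one signature
#'
#' The raw enrichment score `ES` is the sum of discretized target scores over
#' the genes shared by the family's target set `T_i` and the signature `S_j`:
#' strong predicted targets count more than weak ones. `ES = 0` exactly when
#' the overlap is empty.
#'
#' @param signature a signature (list with `genes`) or a plain character
#'   vector of genes.
#' @param family miRNA family identifier present in the network.
#' @param net a discretized `target_network`.
#' @return list with `overlap` (character vector) and `es` (numeric).
#' @export
enrichment_score <- function(signature, family, net) {
  if (is.list(signature)) signature <- signature$genes
  p <- net$pairs
  if (is.null(net$K) || anyNA(p$discretized_score))
    stop("target network must be discretized first")
  rows <- p$family == family
  if (!any(rows)) stop("unknown miRNA family: ", family)
  hit <- rows & (p$gene %in% signature)
  list(overlap = p$gene[hit], es = sum(p$discretized_score[hit]))
}

#' Per-signature empirical enrichment p-values
#'
#' For every (family i, signature j) the p-value is the right-tail empirical
#' proportion of control replicates whose enrichment score reaches the
#' observed one: `p_ij = #{r : ES_ij(r) >= ES_ij} / R`. Ties count toward
#' significance and the plain `#/R` convention is used, so an observed score
#' exceeding every control yields `p_ij = 0` (to be read as "< 1/R"). The
#' full control score array is returned because the nested empirical p-value
#' reuses it.
#'
#' @param net a discretized `target_network`.
#' @param controls a `control_collection` built from `net`.
#' @param signatures signature list from [extract_signatures()] (or any list
#'   of `list(id=, genes=)`).
#' @return list with `es` (observed family x signature score matrix), `p`
#'   (matching p-value matrix) and `control_es` (family x signature x R
#'   array).
#' @export
signature_pvalues <- function(net, controls, signatures) {
  stopifnot(inherits(controls, "control_collection"), length(signatures) >= 1)
  R <- controls$R
  ix <- net_index(net)
  M <- signature_membership(ix, signatures)
  obs <- es_matrix(ix, ix$gene, M)
  ctrl <- array(0, dim = c(nrow(obs), ncol(obs), R),
                dimnames = list(rownames(obs), colnames(obs), NULL))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(R)) {
    set.seed(controls$seed + r)
    g2 <- stratified_swap_cpp(ix$fam - 1L, ix$gene - 1L, ix$level,
                              length(ix$families), length(ix$genes),
                              controls$n_swaps_per_edge) + 1L
    ctrl[, , r] <- es_matrix(ix, g2, M)
  }
  p <- rowSums(sweep(ctrl, c(1, 2), obs, ">="), dims = 2) / R
  list(es = obs, p = p, control_es = ctrl)
}

#' P-score: best enrichment across the hierarchy
#'
#' The P-score of a miRNA family is the p-value of its most significant
#' signature enrichment, `P_i = min_j p_ij`. Being a minimum over dependent
#' p-values it is biased toward 0 and must be calibrated by
#' [empirical_pvalue()] before use.
#'
#' @param p_row numeric vector of per-signature p-values for one family, or a
#'   family x signature matrix (one P-score per row).
#' @return numeric.
#' @export
p_score <- function(p_row) {
  if (is.matrix(p_row)) {
    if (ncol(p_row) == 0L) stop("no signatures: empty p-value matrix")
    return(apply(p_row, 1L, min))
  }
  if (!length(p_row)) stop("no signatures: empty p-value vector")
  min(p_row)
}

#' Nested empirical p-value of the P-score
#'
#' Calibrates the minimum-over-signatures bias of the P-score by scoring each
#' control replicate with the very procedure applied to the observation: for
#' replicate r, `p_ij(r) = #{r' : ES_ij(r') >= ES_ij(r)} / R` (rank of the
#' replicate's score within the control score distribution, self included),
#' `P_i(r) = min_j p_ij(r)`, and finally
#' `p_i = #{r : P_i(r) <= P_i} / R`. Reusing the single control array for
#' both levels replaces the quadratic nested permutation — which would cost
#' R fresh control sets per replicate — with a self-rank that is unbiased to
#' O(k/R), k being the number of effectively distinct signatures: a control's
#' P-score is bounded below by 1/R while the observed P-score can reach 0,
#' so an observation more enriched than every control is reported as exactly
#' 0 (displayed as "< 1/R"). The price is a small anticonservative atom at
#' p = 0 of that same order under the null, vanishing as R grows.
#'
#' @param observed_P per-family P-scores (named numeric, as from
#'   [p_score()]).
#' @param control_es the family x signature x R array from
#'   [signature_pvalues()].
#' @param R number of control replicates (defaults to `dim(control_es)[3]`).
#' @return named per-family empirical p-values in `[0, 1]`.
#' @export
empirical_pvalue <- function(observed_P, control_es,
                             R = dim(control_es)[3]) {
  if (is.null(control_es)) stop("control score array is required")
  stopifnot(length(dim(control_es)) == 3, dim(control_es)[3] == R)
  nf <- dim(control_es)[1]; ns <- dim(control_es)[2]
  Pr <- matrix(Inf, nrow = nf, ncol = R)
  for (i in seq_len(nf)) {
    for (j in seq_len(ns)) {
      x <- control_es[i, j, ]
      # #{r' : x[r'] >= x[r]} = R - (#{r' : x[r'] < x[r]}) = R - rank_min + 1
      pij_r <- (R - rank(x, ties.method = "min") + 1) / R
      Pr[i, ] <- pmin(Pr[i, ], pij_r)
    }
  }
  out <- vapply(seq_len(nf), function(i) mean(Pr[i, ] <= observed_P[i]),
                numeric(1))
  names(out) <- dimnames(control_es)[[1]]
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values, reported as q-values for the per-family
#' empirical p-values (monotone, capped at 1, never below the raw p-value).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method only `"bh"`.
#' @return adjusted values, same names and order as `p`.
#' @export
q_values <- function(p, method = c("bh")) {
  match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# -- full pipeline -----------------------------------------------------------

#' Run the full hierarchical enrichment analysis
#'
#' Executes the whole pipeline: expression filtering, differential
#' expression, the co-expression hierarchy and signature extraction, then the
#' permutation enrichment chain (ES, per-signature p, P-score, nested
#' empirical p, q-values). Families with `q < q_threshold` are reported with
#' their best signature and overlap genes as the inferred perturbed
#' sub-network.
#'
#' @param study an `expression_study`.
#' @param net a `target_network`; discretized with the config's `K`, `b` if
#'   not already.
#' @param config a [mirhic_config()].
#' @param signatures optional signature list overriding the hierarchy step
#'   (the flat DE-set signature reproduces the miRDeG baseline exactly).
#' @return object of class `mirhic_result`: `table` (one row per family:
#'   mirna, n_targets, best_signature, ES, P_score, empirical_p, q),
#'   `network` (edge list mirna/gene/signature/discretized_score for
#'   reported families), `signatures`, `de`, `config`.
#' @export
run_mirhic <- function(study, net, config = mirhic_config(),
                       signatures = NULL) {
  stopifnot(inherits(study, "expression_study"),
            inherits(net, "target_network"),
            inherits(config, "mirhic_config"))
  fs <- filter_low_expression(study, config$top_n, config$sample_fraction)
  de <- differential_expression(fs, config$paired, config$de_alpha)
  if (!length(de$de_genes))
    stop("no differentially expressed genes at adjusted p < ", config$de_alpha,
         "; relax de_alpha or check the group labels")
  if (is.null(signatures)) {
    sim <- pairwise_correlation(fs, de$de_genes, config$cor_method)
    if (config$abs_cor) sim <- abs(sim)
    rstar <- suppressMessages(
      correlation_cutoff(config$z_cutoff, ncol(fs$matrix)))
    dendro <- build_dendrogram(sim, rstar)
    signatures <- extract_signatures(dendro, config$min_size,
                                     config$max_size_fraction,
                                     config$dedup_jaccard)
    if (!length(signatures)) {
      warning("no signatures extracted; falling back to the flat DE set")
      signatures <- flat_signature(de$de_genes)
    }
  }
  if (is.null(net$K) || anyNA(net$pairs$discretized_score))
    net <- discretize_scores(net, config$K, config$b)
  controls <- generate_controls(net, config$R, config$seed,
                                config$n_swaps_per_edge)
  sp <- signature_pvalues(net, controls, signatures)
  P <- p_score(sp$p)
  pe <- empirical_pvalue(P, sp$control_es, config$R)
  q <- q_values(pe)

  # best signature per family: smallest p, ties broken by the largest
  # standardized exceedance of the observed score over its control mean
  zmar <- matrix(0, nrow(sp$es), ncol(sp$es))
  for (j in seq_len(ncol(sp$es))) {
    slab <- matrix(sp$control_es[, j, ], nrow = nrow(sp$es))
    mu <- rowMeans(slab)
    sdv <- apply(slab, 1L, stats::sd)
    zmar[, j] <- (sp$es[, j] - mu) / pmax(sdv, 1e-12)
  }
  best <- vapply(seq_len(nrow(sp$p)), function(i) {
    cand <- which(sp$p[i, ] == min(sp$p[i, ]))
    cand[which.max(zmar[i, cand])]
  }, integer(1))
  fam <- rownames(sp$p)
  sizes <- vapply(target_sets(net)[fam], length, integer(1))
  tab <- data.frame(mirna = fam,
                    n_targets = unname(sizes),
                    best_signature = colnames(sp$p)[best],
                    ES = sp$es[cbind(seq_along(fam), best)],
                    P_score = unname(P),
                    empirical_p = unname(pe),
                    q = unname(q),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$q, tab$empirical_p, tab$mirna), ]
  rownames(tab) <- NULL

  hits <- tab$mirna[tab$q < config$q_threshold]
  network <- do.call(rbind, lapply(hits, function(f) {
    j <- tab$best_signature[tab$mirna == f]
    sig <- signatures[[match(j, vapply(signatures, `[[`, "", "id"))]]
    ov <- enrichment_score(sig, f, net)
    if (!length(ov$overlap)) return(NULL)
    s <- net$pairs$discretized_score[net$pairs$family == f &
                                       net$pairs$gene %in% ov$overlap]
    data.frame(mirna = f, gene = ov$overlap, signature = j,
               discretized_score = s, stringsAsFactors = FALSE)
  }))
  if (is.null(network))
    network <- data.frame(mirna = character(), gene = character(),
                          signature = character(),
                          discretized_score = integer(),
                          stringsAsFactors = FALSE)

  structure(list(table = tab, network = network, signatures = signatures,
                 de = de, config = config, method = "miRHiC"),
            class = "mirhic_result")
}

# the single flat signature used by the miRDeG baseline
flat_signature <- function(de_genes) {
  list(list(id = "DE", genes = de_genes, size = length(de_genes),
            level_correlation = NA_real_))
}

#' @export
print.mirhic_result <- function(x, ...) {
  cat(sprintf("%s result: %d families, %d signatures, R = %d\n",
              x$method, nrow(x$table), length(x$signatures), x$config$R))
  hits <- x$table[x$table$q < x$config$q_threshold, , drop = FALSE]
  cat(sprintf("  %d family(ies) with q < %g\n", nrow(hits),
              x$config$q_threshold))
  if (nrow(hits)) print(utils::head(hits, 20))
  invisible(x)
}

#' Write the main results table
#' @param result a `mirhic_result`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  tab <- result$table
  tab$empirical_p <- ifelse(tab$empirical_p == 0,
                            paste0("<", format(1 / result$config$R)),
                            format(tab$empirical_p))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- null calibration --------------------------------------------------------

#' Null calibration of the empirical p-values
#'
#' The bias check run on every analysis design: stratified control target
#' sets, which are true nulls by construction, are scored as if they were
#' observations. If the nested empirical p-value is unbiased, the resulting
#' per-family p-values are uniform on `[0, 1]` and independent of target-set
#' size.
#'
#' @param net a discretized `target_network`.
#' @param signatures signature list.
#' @param R control replicates forming the null distribution.
#' @param n_sets control sets evaluated as observations per family.
#' @param seed base seed (`seed+1 ... seed+R` drive the null replicates,
#'   `seed+R+1 ...` the evaluated sets).
#' @param n_swaps_per_edge passed to the randomizer.
#' @return data.frame with one row per (family, evaluated set): `family`,
#'   `set`, `size` (target-set size `|T_i|`), `empirical_p`.
#' @export
calibrate_null <- function(net, signatures, R, n_sets, seed,
                           n_swaps_per_edge = 10) {
  seed <- as.integer(seed)
  controls <- generate_controls(net, R, seed, n_swaps_per_edge)
  sp <- signature_pvalues(net, controls, signatures)
  R <- controls$R
  nf <- dim(sp$control_es)[1]; ns <- dim(sp$control_es)[2]
  # self-rank P-scores of the null replicates, and sorted control scores for
  # fast right-tail counts against new observations
  sorted <- vector("list", nf * ns)
  Pr <- matrix(Inf, nrow = nf, ncol = R)
  for (i in seq_len(nf)) {
    for (j in seq_len(ns)) {
      x <- sp$control_es[i, j, ]
      Pr[i, ] <- pmin(Pr[i, ], (R - rank(x, ties.method = "min") + 1) / R)
      sorted[[(i - 1L) * ns + j]] <- sort(x)
    }
  }
  ix <- net_index(net)
  M <- signature_membership(ix, signatures)
  sizes <- vapply(target_sets(net)[ix$families], length, integer(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  res <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(seed + R + s)
    g2 <- stratified_swap_cpp(ix$fam - 1L, ix$gene - 1L, ix$level,
                              length(ix$families), length(ix$genes), n_swaps_per_edge) + 1L
    es <- es_matrix(ix, g2, M)
    p_obs <- matrix(0, nf, ns)
    for (i in seq_len(nf)) for (j in seq_len(ns)) {
      # scores are integer sums: count of controls >= x via binary search
      p_obs[i, j] <- (R - findInterval(es[i, j] - 0.5,
                                       sorted[[(i - 1L) * ns + j]])) / R
    }
    P_obs <- apply(p_obs, 1L, min)
    p_i <- vapply(seq_len(nf), function(i) mean(Pr[i, ] <= P_obs[i]),
                  numeric(1))
    res[[s]] <- data.frame(family = ix$families, set = s,
                           size = unname(sizes), empirical_p = p_i,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
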