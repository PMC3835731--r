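#' Define a synthetic ground truth
#'
#' Describes a seeded synthetic study: a two-group expression matrix whose
#' differentially expressed genes are organized into correlated blocks, plus
#' a miRNA-target network in which one optional "planted" family
#' concentrates strong targets inside a single block. This emulates the
#' situation the hierarchical method is built for — a regulator whose targets
#' form a small, tightly co-expressed subset of the DE genes — while every
#' structural parameter stays known, so calibration and recovery are
#' testable without any external download.
#'
#' Default sizes are desk-scale: 8 blocks of 60 genes (all shifted between
#' groups, hence differentially expressed) over a universe of 800 genes, 20
#' case and 20 control samples, 30 miRNA families with log-uniform degrees
#' between 50 and 300. The planted family has 250 targets of which 15 sit in
#' the first block with the most negative context scores; the remaining
#' targets are scattered uniformly, so its enrichment in the *whole* DE set
#' is heavily diluted.
#'
#' @param n_blocks number of correlated gene blocks.
#' @param block_size genes per block.
#' @param block_shift per-block case-minus-control mean shift (in noise-sd
#'   units) making block genes differentially expressed.
#' @param block_cor expected pairwise within-block correlation, in `[0, 1)`.
#' @param n_background unstructured, unshifted genes.
#' @param n_case,n_control samples per group.
#' @param noise_sd residual standard deviation.
#' @param n_families miRNA families in the network (including the planted
#'   one when `planted = TRUE`).
#' @param planted plant a perturbed family?
#' @param planted_size planted targets inside the first block.
#' @param planted_degree total targets of the planted family.
#' @param degree_range range of the log-uniform family degree distribution;
#'   a length-1 value gives every family that constant degree.
#' @param seed integer seed; all generated objects derive from it.
#' @return list of class `synthetic_truth` (gene names per block, background
#'   genes, the planted target set, and all parameters).
#' @export
synthetic_truth <- function(n_blocks = 8L, block_size = 60L,
                            block_shift = 2, block_cor = 0.6,
                            n_background = 320L,
                            n_case = 20L, n_control = 20L,
                            noise_sd = 1,
                            n_families = 30L, planted = TRUE,
                            planted_size = 15L, planted_degree = 250L,
                            degree_range = c(50L, 300L),
                            seed = 1L) {
  if (block_cor < 0 || block_cor >= 1)
    stop("block_cor must be in [0, 1)")
  if (planted && planted_size > planted_degree)
    stop("planted_size exceeds planted_degree")
  if (planted && planted_size > block_size)
    stop("planted_size exceeds block_size")
  seed <- as.integer(seed)
  blocks <- lapply(seq_len(n_blocks), function(b)
    sprintf("gB%02d_%03d", b, seq_len(block_size)))
  names(blocks) <- sprintf("block%02d", seq_len(n_blocks))
  background <- sprintf("gN%04d", seq_len(n_background))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  planted_targets <- if (planted) sample(blocks[[1]], planted_size)
                     else character()
  structure(list(blocks = blocks, background = background,
                 block_shift = block_shift, block_cor = block_cor,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 noise_sd = noise_sd,
                 n_families = as.integer(n_families), planted = planted,
                 planted_family = if (planted) "miR-planted" else NA_character_,
                 planted_targets = planted_targets,
                 planted_degree = as.integer(planted_degree),
                 degree_range = degree_range,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d blocks x %d genes (+%d background), ",
                     "%d/%d samples, %d families%s, seed %d\n"),
              length(x$blocks), length(x$blocks[[1]]), length(x$background),
              x$n_case, x$n_control, x$n_families,
              if (x$planted) sprintf(", planted '%s' (%d/%d targets in %s)",
                                     x$planted_family,
                                     length(x$planted_targets),
                                     x$planted_degree, names(x$blocks)[1])
              else "", x$seed))
  invisible(x)
}

#' Generate the synthetic expression matrix
#'
#' Block genes follow a single-factor model: for block b with target
#' correlation rho, each gene is `sqrt(rho) * f_s + sqrt(1 - rho) * e`,
#' with `f_s` a per-sample block factor and `e` independent noise (both on
#' the `noise_sd` scale), plus the block's mean shift added to case samples.
#' The expected within-block pairwise correlation is exactly rho and
#' generation is O(genes x samples). Background genes are i.i.d. noise.
#'
#' @param truth a `synthetic_truth`.
#' @return an `expression_study` (samples case_1..., control_1...).
#' @export
generate_expression <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed + 1L)
  ns <- truth$n_case + truth$n_control
  group <- rep(c("case", "control"), c(truth$n_case, truth$n_control))
  samples <- c(sprintf("case_%02d", seq_len(truth$n_case)),
               sprintf("control_%02d", seq_len(truth$n_control)))
  rho <- truth$block_cor
  rows <- list()
  for (b in seq_along(truth$blocks)) {
    genes <- truth$blocks[[b]]
    f <- stats::rnorm(ns)
    e <- matrix(stats::rnorm(length(genes) * ns), nrow = length(genes))
    x <- (sqrt(rho) * matrix(f, length(genes), ns, byrow = TRUE) +
            sqrt(1 - rho) * e) * truth$noise_sd
    x[, group == "case"] <- x[, group == "case"] + truth$block_shift
    rownames(x) <- genes
    rows[[b]] <- x
  }
  bg <- matrix(stats::rnorm(length(truth$background) * ns,
                            sd = truth$noise_sd),
               nrow = length(truth$background),
               dimnames = list(truth$background, NULL))
  m <- do.call(rbind, c(rows, list(bg)))
  colnames(m) <- samples
  expression_study(m, group)
}

#' Generate the synthetic miRNA-target network
#'
#' Families draw their degree from a log-uniform distribution over
#' `degree_range` and their targets uniformly (without replacement) from the
#' whole gene universe, so a non-planted family's overlap with any block is
#' hypergeometric. The planted family's target set is forced to contain the
#' planted in-block targets, which receive the most negative context scores
#' in the network (they land in the top discretized level); its remaining
#' targets are uniform off-block draws. Other context scores follow an
#' exponential tail toward zero (`-rexp(rate = 4)`), echoing the skewed,
#' non-positive distribution of summarized context scores.
#'
#' @param truth a `synthetic_truth`.
#' @param n_families,degree_range override the values stored in `truth`.
#' @return an undiscretized `target_network`.
#' @export
generate_network <- function(truth, n_families = truth$n_families,
                             degree_range = truth$degree_range) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- c(unlist(truth$blocks, use.names = FALSE), truth$background)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed + 2L)
  n_random <- n_families - as.integer(truth$planted)
  if (n_random < 1L) stop("need at least 2 families")
  lo <- min(degree_range); hi <- max(degree_range)
  deg <- if (lo == hi) rep(lo, n_random)
         else round(exp(stats::runif(n_random, log(lo), log(hi))))
  deg <- pmin(pmax(deg, 1L), length(genes))
  fams <- sprintf("miR-%03d", seq_len(n_random))
  pairs <- do.call(rbind, lapply(seq_len(n_random), function(i) {
    tg <- sample(genes, deg[i])
    data.frame(family = fams[i], gene = tg,
               context_score = -stats::rexp(deg[i], rate = 4),
               stringsAsFactors = FALSE)
  }))
  if (truth$planted) {
    others <- setdiff(genes, truth$planted_targets)
    extra <- sample(others, truth$planted_degree - length(truth$planted_targets))
    pp <- data.frame(
      family = truth$planted_family,
      gene = c(truth$planted_targets, extra),
      context_score = c(-(2 + stats::runif(length(truth$planted_targets),
                                           0, 0.5)),
                        -stats::rexp(length(extra), rate = 4)),
      stringsAsFactors = FALSE)
    pairs <- rbind(pairs, pp)
  }
  target_network(pairs)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression TSV, groups TSV, target-pair TSV and a JSON
#' description of the truth — the file set consumed by the command-line
#' `run` subcommand.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required to write the truth file")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_expression(truth)
  net <- generate_network(truth)
  em <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(em, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(study$matrix),
                                group = study$group),
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edge_list(net, file.path(dir, "targets.tsv"))
  tr <- unclass(truth)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
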