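#' Construct a two-group expression study
#'
#' @param matrix numeric gene x sample matrix with unique rownames (genes)
#'   and colnames (samples). Values are used as provided and are expected to
#'   be on a scale where per-gene t-tests are sensible (e.g. log intensities).
#' @param group character/factor per sample with levels `case` and `control`.
#' @param pairing optional per-sample pair identifier (same id on the case
#'   and control member of a pair) enabling paired t-tests.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(matrix, group, pairing = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("expression matrix needs unique gene rownames")
  if (is.null(colnames(matrix))) stop("expression matrix needs sample colnames")
  group <- as.character(group)
  if (length(group) != ncol(matrix)) stop("one group label per sample required")
  if (anyNA(group)) stop("missing group labels")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (any(table(factor(group, c("case", "control"))) < 2L))
    stop("need at least 2 samples per group")
  if (!is.null(pairing)) {
    pairing <- as.character(pairing)
    if (length(pairing) != ncol(matrix)) stop("one pairing id per sample")
  }
  structure(list(matrix = matrix, group = group, pairing = pairing),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%d case / %d control%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$group == "case"), sum(x$group == "control"),
              if (is.null(x$pairing)) "" else ", paired"))
  invisible(x)
}

#' Read an expression matrix and its sample annotation
#'
#' `read_expression` reads a TSV with genes in rows (first column = gene id,
#' header = sample names). `read_groups` reads a sample annotation TSV with
#' columns `sample`, `group` and optionally `pair`, and `expression_study_from_files`
#' combines the two, validating that every annotated sample is present.
#'
#' @param path TSV file.
#' @return `read_expression`: a numeric matrix; `read_groups`: a data.frame.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(d)
}

#' @rdname read_expression
#' @export
read_groups <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (col in c("sample", "group"))
    if (!col %in% names(d)) stop("groups file is missing column '", col, "'")
  d
}

#' @rdname read_expression
#' @param expression_path,groups_path paths to the two TSV files.
#' @export
expression_study_from_files <- function(expression_path, groups_path) {
  m <- read_expression(expression_path)
  g <- read_groups(groups_path)
  missing <- setdiff(g$sample, colnames(m))
  if (length(missing))
    stop("sample(s) in groups file absent from the matrix: ",
         paste(missing, collapse = ", "))
  m <- m[, g$sample, drop = FALSE]
  expression_study(m, g$group, if ("pair" %in% names(g)) g$pair else NULL)
}

#' Filter lowly expressed genes
#'
#' Keeps gene g when, in at least `ceiling(sample_fraction * n_samples)`
#' samples, g ranks within the `top_n` highest expression values of that
#' sample (ties at the boundary are all kept within a sample). This removes
#' genes that are near the noise floor in most samples before any testing.
#'
#' @param study an `expression_study`.
#' @param top_n rank cutoff within each sample (default 10000).
#' @param sample_fraction fraction of samples in which the rank cutoff must
#'   be met (default 0.3).
#' @return a reduced `expression_study`. When `top_n` is at least the number
#'   of genes the study is returned unchanged with a warning.
#' @export
filter_low_expression <- function(study, top_n = 10000L,
                                  sample_fraction = 0.3) {
  stopifnot(inherits(study, "expression_study"),
            top_n >= 1, sample_fraction > 0, sample_fraction <= 1)
  m <- study$matrix
  if (top_n >= nrow(m)) {
    warning("top_n >= number of genes; no filtering applied")
    return(study)
  }
  need <- ceiling(sample_fraction * ncol(m))
  in_top <- apply(m, 2L, function(x) rank(-x, ties.method = "min") <= top_n)
  keep <- rowSums(in_top) >= need
  study$matrix <- m[keep, , drop = FALSE]
  study
}

#' Per-gene differential expression by t-test
#'
#' Tests every gene for a case vs control mean difference with a two-sided
#' t-test — Welch's two-sample test by default, the paired test when
#' `paired = TRUE` and the study carries a pairing. Raw p-values are adjusted
#' by Benjamini-Hochberg across all tested genes, and the DE set is the genes
#' with adjusted p below `alpha`. A gene with zero standard error (constant
#' within both groups) gets t = 0, p = 1 and is reported in a message rather
#' than raised as an error.
#'
#' @param study an `expression_study` (normally after
#'   [filter_low_expression()]; the adjustment spans exactly the genes
#'   present).
#' @param paired use the paired t-test.
#' @param alpha adjusted-p threshold for the DE set (default 1e-4).
#' @return list with `table` (data.frame: gene, t_statistic, p_value,
#'   adjusted_p, log_fold_change) and `de_genes` (character vector).
#' @export
differential_expression <- function(study, paired = FALSE, alpha = 1e-4) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  grp <- study$group
  case <- m[, grp == "case", drop = FALSE]
  ctrl <- m[, grp == "control", drop = FALSE]
  if (paired) {
    if (is.null(study$pairing)) stop("paired = TRUE but study has no pairing")
    pc <- study$pairing[grp == "case"]
    pk <- study$pairing[grp == "control"]
    if (anyNA(match(pc, pk)) || length(pc) != length(pk))
      stop("pairing is incomplete")
    d <- case - ctrl[, match(pc, pk), drop = FALSE]
    n <- ncol(d)
    md <- rowMeans(d)
    sdd <- sqrt(rowSums((d - md)^2) / (n - 1L))
    se <- sdd / sqrt(n)
    df <- rep(n - 1, nrow(m))
    diff <- md
  } else {
    n1 <- ncol(case); n2 <- ncol(ctrl)
    m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
    v1 <- rowSums((case - m1)^2) / (n1 - 1L)
    v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    diff <- m1 - m2
  }
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- !is.finite(t)
  if (any(degenerate)) {
    message(sum(degenerate), " gene(s) with zero standard error: t set to 0, p to 1")
    t[degenerate] <- 0
    p[degenerate] <- 1
  }
  adj <- stats::p.adjust(p, method = "BH")
  lfc <- rowMeans(case) - rowMeans(ctrl)
  tab <- data.frame(gene = rownames(m), t_statistic = t, p_value = p,
                    adjusted_p = adj, log_fold_change = lfc,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, de_genes = tab$gene[tab$adjusted_p < alpha])
}

#' Write a differential-expression table
#' @param de result of [differential_expression()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
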