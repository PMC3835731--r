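write_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("TSV reader builds the network and dedups conflicting rows", {
  f <- write_tsv(data.frame(family = c("m1", "m1", "m2"),
                            gene = c("gA", "gB", "gA"),
                            context_score = c(-0.5, -0.1, -0.3)))
  net <- load_target_pairs(f)
  expect_equal(n_pairs(net), 3L)
  ts <- target_sets(net)
  expect_setequal(ts$m1, c("gA", "gB"))
  expect_equal(ts$m2, "gA")

  f2 <- write_tsv(data.frame(family = c("m1", "m1"), gene = c("gA", "gA"),
                             context_score = c(-0.5, -0.2)))
  expect_warning(net2 <- load_target_pairs(f2), "duplicate")
  expect_equal(n_pairs(net2), 1L)
  expect_equal(net2$pairs$context_score, -0.5)
})

test_that("reader errors name the offending column and reject empty files", {
  f <- write_tsv(data.frame(family = "m1", gene = "gA", other = 1))
  expect_error(load_target_pairs(f), "context_score")
  f3 <- write_tsv(data.frame(family = character(), gene = character(),
                             context_score = numeric()))
  expect_error(load_target_pairs(f3), "empty")
  # configurable column names accept a TargetScan-like header
  f4 <- write_tsv(data.frame(`miR Family` = "m1", `Gene Symbol` = "gA",
                             `Total context score` = -0.4,
                             check.names = FALSE))
  net <- load_target_pairs(f4, family_col = "miR Family",
                           gene_col = "Gene Symbol",
                           score_col = "Total context score")
  expect_equal(n_pairs(net), 1L)
})

test_that("family merging unions target sets and keeps the strongest score", {
  pairs <- data.frame(family = c("miR-200a", "miR-200b"),
                      gene = c("gA", "gA"),
                      context_score = c(-0.4, -0.6))
  net <- merge_families(target_network(pairs),
                        c("miR-200a" = "miR-200", "miR-200b" = "miR-200"))
  expect_equal(n_pairs(net), 1L)
  expect_equal(net$pairs$family, "miR-200")
  expect_equal(net$pairs$context_score, -0.6)

  # identity map leaves the pair table unchanged
  p2 <- data.frame(family = c("m1", "m2"), gene = c("gA", "gB"),
                   context_score = c(-0.2, -0.3))
  net2 <- merge_families(target_network(p2), c(m1 = "m1", m2 = "m2"))
  expect_equal(net2$pairs[c("family", "gene", "context_score")],
               target_network(p2)$pairs[c("family", "gene", "context_score")])

  # union across members
  p3 <- data.frame(family = c("miR-1", "miR-206"), gene = c("gA", "gB"),
                   context_score = c(-0.2, -0.3))
  net3 <- merge_families(target_network(p3),
                         c("miR-1" = "miR-1/206", "miR-206" = "miR-1/206"))
  expect_setequal(target_sets(net3)[["miR-1/206"]], c("gA", "gB"))
})

test_that("discretization matches the stated rank rule", {
  # N = 10, K = 5, b = 3: by decreasing score the levels read 1,1,4,4,...,13,13
  pairs <- data.frame(family = "m1", gene = sprintf("g%02d", 1:10),
                      context_score = -(1:10) / 10)
  net <- discretize_scores(target_network(pairs), K = 5, b = 3)
  p <- net$pairs[order(-net$pairs$context_score), ]
  expect_equal(p$discretized_score, c(1L, 1L, 4L, 4L, 7L, 7L, 10L, 10L, 13L, 13L))

  # K = 1: a single level
  net1 <- discretize_scores(target_network(pairs), K = 1, b = 3)
  expect_true(all(net1$pairs$discretized_score == 1L))

  # N = 7, K = 5: occupancies 2,1,2,1,1 over levels 1,4,7,10,13
  pairs7 <- pairs[1:7, ]
  net7 <- discretize_scores(target_network(pairs7), K = 5, b = 3)
  occ <- table(net7$pairs$discretized_score)
  expect_equal(as.integer(occ[as.character(c(1, 4, 7, 10, 13))]),
               c(2L, 1L, 2L, 1L, 1L))
})

test_that("discretization rejects invalid K and b", {
  pairs <- data.frame(family = "m1", gene = c("gA", "gB"),
                      context_score = c(-0.1, -0.2))
  net <- target_network(pairs)
  expect_error(discretize_scores(net, K = 3, b = 3), "exceeds")
  expect_error(discretize_scores(net, K = 0, b = 3), "positive")
  expect_error(discretize_scores(net, K = 2, b = 0), "positive")
})

test_that("discretization invariants hold on random networks", {
  for (seed in 1:5) {
    net <- discretize_scores(random_net(6, 40, 120, seed), K = 5, b = 3)
    s <- net$pairs$discretized_score
    # exactly min(K, N) levels, all of the form 1 + 3m
    expect_setequal(unique(s), c(1, 4, 7, 10, 13))
    # K divides N = 120: equal occupancy
    expect_true(all(table(s) == 24))
    # monotone: a strictly more negative context score never gets a lower
    # level (ties may straddle a level boundary)
    lo <- tapply(s, net$pairs$context_score, min)  # sorted by score ascending
    hi <- tapply(s, net$pairs$context_score, max)
    if (length(lo) > 1)
      expect_true(all(lo[-length(lo)] >= hi[-1]))
    # idempotent
    again <- discretize_scores(net, K = 5, b = 3)
    expect_identical(again$pairs, net$pairs)
  }
  # K does not divide N: occupancies differ by at most 1
  net <- discretize_scores(random_net(5, 40, 97, 9), K = 5, b = 3)
  expect_lte(diff(range(table(net$pairs$discretized_score))), 1)
})

test_that("GMT and edge-list writers round-trip the target sets", {
  net <- discretize_scores(random_net(4, 20, 30, 3), K = 5, b = 3)
  g <- tempfile(fileext = ".gmt")
  write_gmt(net, g)
  lines <- strsplit(readLines(g), "\t")
  got <- setNames(lapply(lines, function(x) sort(x[-(1:2)])),
                  vapply(lines, `[[`, "", 1))
  want <- lapply(target_sets(net), sort)
  expect_equal(got[names(want)], want)

  e <- tempfile(fileext = ".tsv")
  write_edge_list(net, e)
  back <- load_target_pairs(e)
  expect_equal(collapse_sorted <- back$pairs[order(back$pairs$family,
                                                   back$pairs$gene),
                                             c("family", "gene")],
               net$pairs[order(net$pairs$family, net$pairs$gene),
                         c("family", "gene")],
               ignore_attr = TRUE)
})
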