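test_that("enrichment scores sum discretized scores over the overlap", {
  net <- toy_net(family = rep("m1", 3), gene = c("gB", "gC", "gD"),
                 level = c(4, 13, 7))
  r <- enrichment_score(c("gA", "gB", "gC"), "m1", net)
  expect_setequal(r$overlap, c("gB", "gC"))
  expect_equal(r$es, 17)
  expect_equal(enrichment_score(c("gX", "gY"), "m1", net)$es, 0)
  expect_error(enrichment_score(c("gA"), "nope", net), "unknown")
})

test_that("vectorized scores equal a brute-force loop on random toys", {
  net <- discretize_scores(random_net(5, 20, 60, 21), K = 5, b = 3)
  sigs <- lapply(1:4, function(j) {
    set.seed(100 + j)
    g <- sample(sprintf("g%03d", 1:20), 8)
    list(id = paste0("C", j), genes = g, size = 8, level_correlation = NA)
  })
  cc <- generate_controls(net, R = 2, seed = 1)
  sp <- signature_pvalues(net, cc, sigs)
  for (f in unique(net$pairs$family)) {
    for (j in seq_along(sigs)) {
      brute <- 0
      for (k in seq_len(n_pairs(net)))
        if (net$pairs$family[k] == f &&
            net$pairs$gene[k] %in% sigs[[j]]$genes)
          brute <- brute + net$pairs$discretized_score[k]
      expect_equal(sp$es[f, sigs[[j]]$id], brute)
    }
  }
})

test_that("a frozen network gives p = 1 and p-values match their own tensor", {
  # disjoint single-gene targets at distinct levels: no permutation moves
  net <- toy_net(family = c("m1", "m2", "m3"), gene = c("g1", "g2", "g3"),
                 level = c(1, 7, 13))
  sigs <- list(list(id = "C1", genes = c("g1", "g2"), size = 2,
                    level_correlation = NA))
  sp <- signature_pvalues(net, generate_controls(net, R = 50, seed = 3), sigs)
  expect_true(all(sp$p == 1))  # every control equals the observation
  # contract: p is the right-tail proportion of the returned tensor
  net2 <- discretize_scores(random_net(4, 25, 70, 5), K = 5, b = 3)
  sp2 <- signature_pvalues(net2, generate_controls(net2, R = 40, seed = 9),
                           lapply(1:3, function(j) {
                             set.seed(j)
                             list(id = paste0("C", j),
                                  genes = sample(sprintf("g%03d", 1:25), 10))
                           }))
  recomputed <- rowSums(sweep(sp2$control_es, c(1, 2), sp2$es, ">="),
                        dims = 2) / 40
  expect_equal(sp2$p, recomputed)
})

test_that("the P-score is the row minimum", {
  expect_equal(p_score(c(0.4, 0.02, 0.6)), 0.02)
  expect_equal(p_score(c(0.7)), 0.7)
  expect_equal(p_score(c(1, 1, 1)), 1)
  m <- rbind(a = c(0.2, 0.5), b = c(0.9, 0.1))
  expect_equal(p_score(m), c(a = 0.2, b = 0.1))
  expect_error(p_score(numeric()), "empty")
})

test_that("empirical p-values collapse monotonically for a single signature", {
  net <- discretize_scores(random_net(10, 40, 150, 33), K = 5, b = 3)
  sigs <- list(list(id = "C1", genes = sprintf("g%03d", 1:15), size = 15,
                    level_correlation = NA))
  sp <- signature_pvalues(net, generate_controls(net, R = 200, seed = 4), sigs)
  P <- p_score(sp$p)
  pe <- empirical_pvalue(P, sp$control_es)
  expect_true(all(pe >= 0 & pe <= 1))
  # with one signature p_i is a monotone transform of p_i1
  expect_equal(cor(pe, sp$p[, 1], method = "spearman"), 1)
  # dominance: the P-score never exceeds any single p_ij
  sp3 <- signature_pvalues(net, generate_controls(net, R = 100, seed = 6),
                           list(sigs[[1]],
                                list(id = "C2", genes = sprintf("g%03d", 20:34))))
  expect_true(all(p_score(sp3$p) <= sp3$p))
})

test_that("null families draw uniform empirical p-values", {
  # few signatures keep the self-rank atom at p=0 negligible at this R
  net <- discretize_scores(random_net(20, 120, 600, 55), K = 5, b = 3)
  sigs <- list(list(id = "C1", genes = sprintf("g%03d", 1:30)),
               list(id = "C2", genes = sprintf("g%03d", 61:100)))
  cal <- calibrate_null(net, sigs, R = 500, n_sets = 50, seed = 17)
  ks <- suppressWarnings(ks.test(cal$empirical_p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(cal$empirical_p) - 0.5), 0.05)
})

test_that("empirical p on tiny graphs converges to exact enumeration", {
  net <- toy_net(family = c("m1", "m1", "m2", "m2", "m3", "m3"),
                 gene = c("g1", "g2", "g3", "g4", "g2", "g4"),
                 level = c(4, 4, 4, 4, 13, 13))
  states <- enumerate_stratified(net)
  sigs <- list(list(id = "C1", genes = c("g1", "g2")),
               list(id = "C2", genes = c("g3", "g4")))
  R <- 10000
  sp <- signature_pvalues(net, generate_controls(net, R = R, seed = 2), sigs)
  for (f in c("m1", "m2", "m3")) {
    for (sg in sigs) {
      es_enum <- vapply(states, function(q)
        sum(q$discretized_score[q$family == f & q$gene %in% sg$genes]), 0)
      obs <- sp$es[f, sg$id]
      p_exact <- mean(es_enum >= obs)
      se <- sqrt(p_exact * (1 - p_exact) / R)
      expect_lt(abs(sp$p[f, sg$id] - p_exact), 3 * se + 1e-6)
    }
  }
})

test_that("q-value arithmetic follows BH", {
  expect_equal(q_values(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(q_values(0.05), 0.05)
  expect_equal(q_values(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_error(q_values(c(0.5, 1.2)), "p")
})

test_that("full runs are deterministic and recover a planted regulator", {
  tr <- synthetic_truth(seed = 301)
  st <- generate_expression(tr)
  net <- generate_network(tr)
  cfg <- mirhic_config(R = 400, seed = 301)
  r1 <- suppressWarnings(suppressMessages(run_mirhic(st, net, cfg)))
  r2 <- suppressWarnings(suppressMessages(run_mirhic(st, net, cfg)))
  expect_identical(r1$table, r2$table)
  expect_identical(r1$network, r2$network)
  row <- r1$table[r1$table$mirna == tr$planted_family, ]
  expect_lt(row$q, 0.1)
  best <- r1$signatures[[match(row$best_signature,
                               vapply(r1$signatures, `[[`, "", "id"))]]
  jac <- length(intersect(best$genes, tr$blocks[[1]])) /
    length(union(best$genes, tr$blocks[[1]]))
  expect_gte(jac, 0.5)
  # the reported sub-network contains the planted family's overlap edges
  sub <- r1$network[r1$network$mirna == tr$planted_family, ]
  expect_true(all(sub$gene %in% best$genes))
  expect_true(all(sub$discretized_score >= 1))
})

test_that("false positives are rare on null networks", {
  # planted-free runs: families hitting q < 0.1 can only come from the
  # O(k_eff/R) atom of the nested economy; their count stays small
  fp <- 0
  for (s in 1:3) {
    tr <- synthetic_truth(planted = FALSE, seed = 400 + s)
    st <- generate_expression(tr)
    net <- generate_network(tr)
    cfg <- mirhic_config(R = 1000, seed = 400 + s)
    res <- suppressWarnings(suppressMessages(run_mirhic(st, net, cfg)))
    fp <- fp + sum(res$table$q < 0.1)
  }
  expect_lte(fp, 6)
})

test_that("the results writer renders exact zeros as a bound", {
  tr <- synthetic_truth(seed = 301)
  st <- generate_expression(tr)
  net <- generate_network(tr)
  res <- suppressWarnings(suppressMessages(
    run_mirhic(st, net, mirhic_config(R = 300, seed = 301))))
  f <- tempfile(fileext = ".tsv")
  write_results(res, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_true(any(grepl("^<", tab$empirical_p)))
})
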