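test_that("ks statistic matches the hand-computed worked examples", {
  inst <- toy_instance(paste0("g", 1:10))
  expect_equal(ks_statistic(c("g1", "g2"), inst), 0.8)    # top of the list
  expect_equal(ks_statistic(c("g9", "g10"), inst), -0.9)  # bottom of the list
})

test_that("ks statistic equals the exhaustive loop oracle for small lists", {
  for (n in 3:6) {
    subsets <- unlist(lapply(seq_len(n), function(t)
      utils::combn(n, t, simplify = FALSE)), recursive = FALSE)
    for (v in subsets) {
      expect_equal(ks_rank_stat(v, n), ks_oracle(v, n), tolerance = 1e-12,
                   info = paste("n =", n, "ranks:", paste(v, collapse = ",")))
    }
  }
})

test_that("absent tags are dropped; all-absent tags error with instance id", {
  inst <- toy_instance(paste0("g", 1:10), id = "inst_42")
  expect_message(ks <- ks_statistic(c("g1", "g2", "nope"), inst), "dropped 1")
  expect_equal(ks, 0.8)
  expect_error(suppressMessages(ks_statistic(c("x", "y"), inst)), "inst_42")
})

test_that("instance connectivity composes the two sides with the zero rule", {
  inst <- toy_instance(paste0("g", 1:10))
  q <- query_signature(up = c("g1", "g2"), down = c("g9", "g10"))
  sc <- instance_connectivity(q, inst)
  expect_equal(sc$s, 0.8 - (-0.9))
  # swapping up/down negates the raw score exactly
  q_swap <- query_signature(up = c("g9", "g10"), down = c("g1", "g2"))
  expect_equal(instance_connectivity(q_swap, inst)$s, -sc$s)
  # both tag sets at the top (same sign) => 0 by convention
  q_same <- query_signature(up = c("g1", "g2"), down = c("g3", "g4"))
  expect_equal(instance_connectivity(q_same, inst)$s, 0)
})

test_that("reversing a ranked list flips the sign of non-zero scores", {
  set.seed(7)
  genes <- paste0("g", 1:100)
  q <- query_signature(up = paste0("g", 1:10), down = paste0("g", 91:100))
  for (i in 1:25) {
    perm <- sample(genes)
    s_fwd <- instance_connectivity(q, toy_instance(perm))$s
    s_rev <- instance_connectivity(q, toy_instance(rev(perm)))$s
    expect_lte(s_fwd * s_rev, 0)
  }
  # strongly skewed case: strict sign flip
  inst <- toy_instance(genes)  # up tags on top, down tags at bottom
  s1 <- instance_connectivity(q, inst)$s
  s2 <- instance_connectivity(q, toy_instance(rev(genes)))$s
  expect_gt(s1, 0)
  expect_lt(s2, 0)
})

test_that("score scaling divides by the batch extremes", {
  expect_equal(scale_scores(c(1.7, -1.0, 0.85)), c(1.0, -1.0, 0.5))
  expect_equal(scale_scores(0.3), 1.0)
  expect_equal(scale_scores(c(-0.4, -0.4)), c(-1, -1))
  expect_warning(z <- scale_scores(c(0, 0)), "all raw scores are zero")
  expect_equal(z, c(0, 0))
})

test_that("scaled scores stay in [-1, 1] and attain an extreme", {
  set.seed(8)
  for (i in 1:20) {
    raw <- round(rnorm(30), 2)
    es <- scale_scores(raw)
    expect_true(all(es >= -1 & es <= 1))
    if (any(raw != 0)) expect_true(any(abs(es) == 1))
    expect_true(all(sign(es) == sign(raw)))
  }
})

test_that("perturbagen summaries aggregate by (drug, cell line)", {
  scores <- data.frame(instance_id = paste0("i", 1:5),
                       perturbagen = c("a", "a", "a", "b", "b"),
                       cell_line = c("HL60", "HL60", "MCF7", "HL60", "HL60"),
                       es = c(-0.6, -0.4, 0.2, 0.5, 0.7))
  summ <- summarize_perturbagen(scores, n_perm = 0)
  expect_equal(nrow(summ), 3)
  a_hl <- summ[summ$perturbagen == "a" & summ$cell_line == "HL60", ]
  expect_equal(a_hl$mean_es, -0.5)
  expect_equal(a_hl$n, 2)
  # singleton group
  a_mc <- summ[summ$perturbagen == "a" & summ$cell_line == "MCF7", ]
  expect_equal(a_mc$mean_es, 0.2)
  expect_equal(a_mc$n, 1)
  # determinism of the permutation p under a fixed seed
  s1 <- summarize_perturbagen(scores, n_perm = 500, seed = 3)
  s2 <- summarize_perturbagen(scores, n_perm = 500, seed = 3)
  expect_identical(s1, s2)
})

test_that("null permutation p is approximately uniform", {
  set.seed(9)
  reps <- 200
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    scores <- data.frame(instance_id = paste0("i", 1:60),
                         perturbagen = rep(sprintf("d%02d", 1:20), each = 3),
                         cell_line = "HL60",
                         es = rnorm(60) / 2)
    summ <- summarize_perturbagen(scores, n_perm = 200, seed = r)
    pvals[r] <- summ$perm_p[summ$perturbagen == "d01"]
  }
  # Kolmogorov bound at ~1% plus permutation discreteness
  d <- max(abs(sort(pvals) - (seq_len(reps) / reps)))
  expect_lt(d, 1.63 / sqrt(reps) + 1 / 200)
})

test_that("hit filtering applies cell line, n and sign thresholds in order", {
  summ <- data.frame(perturbagen = c("drugA", "drugB", "drugC"),
                     cell_line = c("HL60", "HL60", "MCF7"),
                     mean_es = c(-0.5, -0.9, -0.8),
                     n = c(3, 2, 5), perm_p = NA_real_)
  hits <- filter_hits(summ)  # defaults: HL60, min_n 3, negative
  expect_identical(hits$perturbagen, "drugA")
  all_in <- filter_hits(summ, cell_line = c("HL60", "MCF7"), min_n = 1,
                        direction = "both")
  expect_equal(nrow(all_in), 3)
  expect_identical(all_in$perturbagen[1], "drugB")  # sorted by |mean ES|
  expect_error(filter_hits(summ, cell_line = "K562"), "available")
  empty <- filter_hits(summ[0, ])
  expect_s3_class(empty, "hit_table")
  expect_equal(nrow(empty), 0)
})

test_that("query building ranks by human p, breaks ties by symbol, truncates", {
  tab <- data.frame(gene = c("A", "B", "C", "D", "E"),
                    direction = c("up", "up", "up", "down", "down"),
                    human_logfc = c(1, 2, 3, -1, -2),
                    mouse_logfc = c(1, 2, 3, -1, -2),
                    human_p = c(0.04, 0.01, 0.04, 0.02, 0.03))
  cdeg <- structure(list(overlap = tab$gene, up = c("A", "B", "C"),
                         down = c("D", "E"), discordant = character(0),
                         table = tab),
                    class = "conserved_signature")
  q <- build_query(cdeg, max_per_side = 1000)
  expect_identical(q$up, c("B", "A", "C"))  # p order, tie A before C
  expect_identical(q$down, c("D", "E"))
  q2 <- build_query(cdeg, max_per_side = 2)
  expect_identical(q2$up, c("B", "A"))
  # one empty side is refused
  cdeg0 <- structure(list(overlap = "A", up = "A", down = character(0),
                          discordant = character(0), table = tab),
                     class = "conserved_signature")
  expect_error(build_query(cdeg0), "both an up and a down side")
})
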