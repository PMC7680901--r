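test_that("config validation rejects out-of-domain values", {
  expect_error(sim_config(n_case = 0), "positive count")
  expect_error(sim_config(frac_de_shared = 0.6, frac_de_private = 0.5),
               "sum to at most 1")
  expect_error(sim_config(reversal_strength = 1.2), "reversal_strength")
  expect_error(sim_config(n_reversers = 40, n_mimickers = 20,
                          n_perturbagens = 50), "exceed")
})

test_that("expression pair is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 120, seed = 42)
  a <- simulate_expression_pair(cfg)
  b <- simulate_expression_pair(cfg)
  expect_identical(a$human$mat, b$human$mat)
  expect_identical(a$mouse$mat, b$mouse$mat)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ortholog_map, b$ortholog_map)
})

test_that("planted truth matches the configured fractions and structure", {
  cfg <- sim_config(n_genes = 1000, frac_de_shared = 0.1,
                    frac_de_private = 0.08, frac_discordant = 0.04,
                    ortholog_missing_frac = 0.1, seed = 3)
  sim <- simulate_expression_pair(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$status == "shared"), 100)
  expect_equal(sum(tr$status %in% c("private_human", "private_mouse")), 80)
  expect_equal(sum(tr$status == "discordant"), 40)
  expect_equal(nrow(sim$ortholog_map), 900)
  # shared genes same sign, discordant opposite, private one-sided
  sh <- tr[tr$status == "shared", ]
  expect_true(all(sign(sh$human_logfc) == sign(sh$mouse_logfc)))
  di <- tr[tr$status == "discordant", ]
  expect_true(all(sign(di$human_logfc) == -sign(di$mouse_logfc)))
  expect_true(all(tr$mouse_logfc[tr$status == "private_human"] == 0))
  expect_true(all(tr$human_logfc[tr$status == "private_mouse"] == 0))
  # mouse symbols are case-variants with a suffix, never string-identical
  expect_false(any(tr$mouse_symbol %in% tr$human_symbol))
  expect_identical(toupper(substr(tr$mouse_symbol, 1, 9)), tr$human_symbol)
})

test_that("noise-free expression reproduces planted logFC exactly", {
  cfg <- sim_config(n_genes = 60, noise_sd = 0, seed = 11)
  sim <- simulate_expression_pair(cfg)
  emp <- fit_two_groups(sim$human)
  expect_equal(emp$logfc, sim$truth$human_logfc, tolerance = 1e-12)
  emp_m <- fit_two_groups(sim$mouse)
  expect_equal(emp_m$logfc, sim$truth$mouse_logfc, tolerance = 1e-12)
})

test_that("null config (zero effect) yields ~alpha downstream DE calls", {
  cfg <- sim_config(n_genes = 1000, effect_logfc = 0, seed = 5)
  sim <- simulate_expression_pair(cfg)
  mod <- ebayes_moderate(fit_two_groups(sim$human))
  degs <- call_degs(mod$table, alpha = 0.05)
  n_called <- length(degs$up) + length(degs$down)
  # 99% binomial interval for Binomial(1000, 0.05)
  expect_gte(n_called, 31)
  expect_lte(n_called, 69)
})

test_that("perturbagen db has the configured shape and planted labels", {
  cfg <- sim_config(n_genes = 80, n_perturbagens = 5,
                    instances_per_perturbagen = 4, n_reversers = 1,
                    n_mimickers = 1, seed = 9)
  sim <- simulate_expression_pair(cfg)
  db <- simulate_perturbagen_db(cfg, sim$truth)
  expect_length(db$instances, 20)
  expect_equal(nrow(db$manifest), 20)
  expect_equal(sort(table(db$labels$label), decreasing = TRUE),
               sort(table(c("reverser", "mimicker", rep("neutral", 3))),
                    decreasing = TRUE))
  # every instance ranks the full universe exactly once
  for (inst in db$instances) {
    expect_setequal(inst$genes, db$universe)
    expect_false(anyDuplicated(inst$genes) > 0)
  }
  # all instances of one drug share a cell line; all lines populated
  expect_equal(nrow(unique(db$manifest[, c("perturbagen", "cell_line")])), 5)
  expect_setequal(unique(db$labels$cell_line), c("HL60", "MCF7", "PC3"))
})

test_that("perfect reverser with no noise is the exact reverse ordering", {
  # all genes planted DE so the disease ranking is tie-free
  cfg <- sim_config(n_genes = 50, frac_de_shared = 1, frac_de_private = 0,
                    frac_discordant = 0, noise_sd = 0, reversal_strength = 1,
                    n_perturbagens = 2, instances_per_perturbagen = 1,
                    n_reversers = 1, n_mimickers = 0, seed = 13)
  sim <- simulate_expression_pair(cfg)
  db <- simulate_perturbagen_db(cfg, sim$truth)
  disease_rank <- sim$truth$human_symbol[order(sim$truth$human_logfc,
                                               decreasing = TRUE)]
  rev_inst <- db$instances[[1]]
  expect_identical(db$labels$label[1], "reverser")
  expect_identical(rev_inst$genes, rev(disease_rank))
})

test_that("neutral drugs score near zero on average when strength is zero", {
  cfg <- sim_config(n_genes = 300, n_perturbagens = 70,
                    instances_per_perturbagen = 3, n_reversers = 0,
                    n_mimickers = 0, reversal_strength = 0, seed = 21)
  sim <- simulate_expression_pair(cfg)
  db <- simulate_perturbagen_db(cfg, sim$truth)
  tr <- sim$truth
  up <- tr$human_symbol[order(tr$human_logfc, decreasing = TRUE)][1:30]
  dn <- tr$human_symbol[order(tr$human_logfc)][1:30]
  scores <- connectivity_screen(query_signature(up, dn), db)
  expect_gte(nrow(scores), 200)
  se <- sd(scores$s) / sqrt(nrow(scores))
  expect_lt(abs(mean(scores$s)), 3 * se)
})

test_that("bibliometric simulation is deterministic with valid domains", {
  a <- simulate_bibliometrics(sprintf("m%02d", 1:50), seed = 4)
  b <- simulate_bibliometrics(sprintf("m%02d", 1:50), seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
  expect_true(all(a$impact_tier %in% 1:3))
  expect_true(all(a$trials >= 0) && all(a$publications >= 0))
  expect_error(simulate_bibliometrics(character(0)), "empty")
  zero <- simulate_bibliometrics(c("x", "y"), seed = 1, mean_trials = 0)
  expect_true(all(zero$trials == 0))
})
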