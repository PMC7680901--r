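test_that("bibliometric score matches the worked examples", {
  expect_equal(as.numeric(bibliometric_score(3, 5, 2, 2)), log10(60))
  expect_equal(as.numeric(bibliometric_score(3, 5, 2, 2)), 1.7782,
               tolerance = 1e-4)
  expect_equal(as.numeric(bibliometric_score(1, 1, 1, 2)), log10(2))
  expect_equal(as.numeric(bibliometric_score(1, 1, 1, 2)), 0.3010,
               tolerance = 1e-4)
})

test_that("zero-count molecules get the flagged sentinel minimum", {
  s <- bibliometric_score(c(0, 2, 3), c(7, 0, 1), c(3, 2, 1))
  expect_equal(as.numeric(s)[1:2], c(-Inf, -Inf))
  expect_identical(attr(s, "unstudied"), c(TRUE, TRUE, FALSE))
  expect_lt(s[1], min(s[3]))
})

test_that("score is strictly increasing in each count on the positive domain", {
  base <- as.numeric(bibliometric_score(2, 3, 2, 2))
  expect_gt(as.numeric(bibliometric_score(3, 3, 2, 2)), base)
  expect_gt(as.numeric(bibliometric_score(2, 4, 2, 2)), base)
  expect_gt(as.numeric(bibliometric_score(2, 3, 3, 2)), base)
  expect_gt(as.numeric(bibliometric_score(2, 3, 2, 3)), base)
  # identical records give identical scores
  expect_equal(as.numeric(bibliometric_score(c(2, 2), c(3, 3), c(2, 2))),
               rep(base, 2))
})

test_that("candidate ranking puts unstudied molecules first", {
  hits <- data.frame(perturbagen = c("A", "B", "C"),
                     cell_line = "HL60",
                     mean_es = c(-0.5, -0.7, -0.6), n = 3, perm_p = NA,
                     rank = 1:3)
  biblio <- data.frame(molecule = c("A", "B", "C"),
                       trials = c(5, 0, 1), publications = c(25, 9, 1),
                       impact_tier = c(3, 2, 1))
  out <- rank_candidates(hits, biblio)
  expect_identical(out$perturbagen, c("B", "C", "A"))  # sentinel, 0.3, 2.57
  expect_identical(out$triage_rank, 1:3)
  # tie on score: larger |mean ES| first
  biblio2 <- transform(biblio, trials = 1, publications = 1, impact_tier = 1)
  out2 <- rank_candidates(hits, biblio2)
  expect_identical(out2$perturbagen, c("B", "C", "A"))
  # missing record -> sentinel: A ties with zero-count B and both precede C;
  # the tie is broken by |mean ES|, so B (0.7) comes before A (0.5)
  out3 <- rank_candidates(hits, biblio[-1, ])
  expect_identical(out3$perturbagen, c("B", "A", "C"))
  expect_true(out3$unstudied[out3$perturbagen == "A"])
  expect_equal(out3$score[out3$perturbagen == "A"], -Inf)
  expect_equal(nrow(rank_candidates(hits[0, ], biblio)), 0)
})

test_that("bubble radii are inverse-monotone in score with degenerate rule", {
  tri <- data.frame(perturbagen = c("a", "b"), cell_line = "HL60",
                    mean_es = c(-0.4, -0.6), score = c(0.3, 1.7))
  tab <- render_bubble_plot(tri, seed = 1)
  expect_gt(tab$radius[tab$molecule == "a"], tab$radius[tab$molecule == "b"])
  # equal scores collapse to the midpoint radius
  tri_eq <- transform(tri, score = 1)
  tab_eq <- render_bubble_plot(tri_eq, seed = 1, r_min = 0.02, r_max = 0.12)
  expect_equal(tab_eq$radius, rep(0.07, 2))
  # sentinel is treated as the finite minimum (largest bubble)
  tri_s <- data.frame(perturbagen = c("a", "b", "c"), cell_line = "HL60",
                      mean_es = -0.5, score = c(-Inf, 0.5, 2))
  tab_s <- render_bubble_plot(tri_s, seed = 1, r_min = 0.02, r_max = 0.12)
  expect_equal(tab_s$radius[1], 0.12)
})

test_that("bubble table is deterministic, one row per summary, banded by line", {
  tri <- data.frame(perturbagen = sprintf("m%02d", 1:9),
                    cell_line = rep(c("HL60", "MCF7", "PC3"), 3),
                    mean_es = seq(-0.9, -0.1, length.out = 9),
                    score = c(1:8, -Inf))
  t1 <- render_bubble_plot(tri, seed = 42)
  t2 <- render_bubble_plot(tri, seed = 42)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 9)
  expect_equal(t1$y, abs(tri$mean_es))
  # jitter stays within each band (bands are 1, 2, 3 by sorted line name)
  band <- match(t1$cell_line, sort(unique(t1$cell_line)))
  expect_true(all(abs(t1$x - band) <= 0.30))
  # configured colors; unknown lines fall back to the palette cycle
  expect_identical(unique(t1$color[t1$cell_line == "HL60"]), "blue")
  tri_k <- transform(tri, cell_line = "K562")
  tk <- render_bubble_plot(tri_k, seed = 1)
  expect_true(all(nzchar(tk$color)))
})

test_that("bubble plot writes image files when asked", {
  tri <- data.frame(perturbagen = c("a", "b"), cell_line = c("HL60", "MCF7"),
                    mean_es = c(-0.4, -0.6), score = c(0.3, 1.7))
  png_f <- tempfile(fileext = ".png"); svg_f <- tempfile(fileext = ".svg")
  render_bubble_plot(tri, png_file = png_f, svg_file = svg_f, seed = 1)
  expect_true(file.exists(png_f) && file.size(png_f) > 0)
  expect_true(file.exists(svg_f) && file.size(svg_f) > 0)
})
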