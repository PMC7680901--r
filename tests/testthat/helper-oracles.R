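# Independent brute-force oracles. Deliberately naive: plain loops and
# exhaustive enumeration, no shared code with the package internals.

# KS connectivity statistic by full loop over the two max expressions.
ks_oracle <- function(ranks, n) {
  v <- sort(ranks)
  t <- length(v)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# Hypergeometric upper tail P(overlap >= k) by enumerating all C(N, n) draws
# of an n-subset from a universe of N containing a marked K-subset.
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# GSEA running sum computed step by step, independently of gsea_es().
gsea_oracle <- function(ranked, set, w = 1) {
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  r <- ranked[ord]
  ishit <- genes %in% set
  t <- sum(ishit); n <- length(r)
  if (t == n) return(1)
  nr <- sum(abs(r[ishit])^w)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (ishit[i]) run + abs(r[i])^w / nr else run - 1 / (n - t)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Small helpers to build study fixtures in code.
toy_study <- function(case, ctrl, genes = NULL, species = "human") {
  mat <- rbind(cbind(case, ctrl))
  if (is.null(dim(case))) mat <- matrix(c(case, ctrl), nrow = 1)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(mat)))
  rownames(mat) <- genes
  ncase <- if (is.null(dim(case))) length(case) else ncol(case)
  nctrl <- if (is.null(dim(ctrl))) length(ctrl) else ncol(ctrl)
  colnames(mat) <- c(sprintf("case%d", seq_len(ncase)),
                     sprintf("ctrl%d", seq_len(nctrl)))
  groups <- setNames(c(rep("case", ncase), rep("control", nctrl)), colnames(mat))
  expression_study(mat, groups, species = species)
}

toy_instance <- function(genes, id = "inst1", perturbagen = "drugX",
                         cell_line = "HL60") {
  ranked_instance(id = id, perturbagen = perturbagen, cell_line = cell_line,
                  genes = genes)
}
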