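#' Weighted-KS gene-set enrichment score on a preranked list
#'
#' The classic GSEA running-sum statistic on a ranked list of gene-level
#' scores: walking down the list sorted by decreasing score, hits (set
#' members) advance the running sum by `|r_i|^w / sum(|r_hits|^w)` and misses
#' retreat it by `1/(N - t)`; the enrichment score is the extremum of the
#' running sum with the largest magnitude. `w = 0` reduces to the classic
#' (unweighted) Kolmogorov-Smirnov form; `w = 1` (default) weights hits by
#' their scores.
#'
#' Degenerate cases: a set covering the whole list has no misses and gets
#' ES = 1 by convention; if all hit scores are zero under `w > 0` the hit
#' increments fall back to equal weights.
#'
#' @param ranked named numeric vector of gene-level ranking statistics
#'   (e.g. signed moderated t); sorted internally in decreasing order.
#' @param set character vector of member gene symbols.
#' @param weight_exponent exponent `w` on |score| for hit increments.
#' @return ES in \[-1, 1\], or `NA` (with a warning) when no member of the
#'   set is present in the ranked list.
#' @export
gsea_es <- function(ranked, set, weight_exponent = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)), all(is.finite(ranked)))
  if (anyDuplicated(names(ranked)))
    stop("gsea_es: duplicate genes in ranked list", call. = FALSE)
  r <- sort(ranked, decreasing = TRUE)
  hit <- names(r) %in% set
  t <- sum(hit)
  if (t == 0L) {
    warning("gsea_es: no set member present in the ranked list")
    return(NA_real_)
  }
  n <- length(r)
  if (t == n) return(1)  # no misses: ES = 1 by convention
  w <- abs(r)^weight_exponent
  nr <- sum(w[hit])
  if (nr == 0) { w <- rep(1, n); nr <- t }  # all-zero hit scores: equal weights
  step <- ifelse(hit, w / nr, -1 / (n - t))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Enrichment score with gene-label permutation NES and p-value
#'
#' Normalizes the observed ES by the mean |ES| of same-sign gene-label
#' permutations (random member sets of equal size drawn from the ranked
#' list), the preranked-GSEA convention, and reports a permutation p-value
#' `p = (1 + #{|ES_perm| >= |ES|, same sign}) / (1 + #same-sign perms)`.
#'
#' @param ranked named numeric vector of ranking statistics.
#' @param set character vector of member gene symbols.
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed integer seed.
#' @param weight_exponent passed to [gsea_es()].
#' @return list of class `enrichment_result`: `set_size` (members present),
#'   `es`, `nes`, `p`.
#' @export
gsea_nes <- function(ranked, set, n_perm = 1000L, seed = 1L,
                     weight_exponent = 1) {
  if (n_perm < 100L)
    stop("gsea_nes: need at least 100 permutations", call. = FALSE)
  es <- gsea_es(ranked, set, weight_exponent)
  if (is.na(es)) return(structure(list(set_size = 0L, es = NA_real_,
                                       nes = NA_real_, p = NA_real_),
                                  class = "enrichment_result"))
  t <- sum(names(ranked) %in% set)
  set.seed(stage_seed(seed, "perm_gsea"))
  perm_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es(ranked, sample(names(ranked), t), weight_exponent)
  }, numeric(1))
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same) == 0L) NA_real_ else es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(set_size = t, es = es, nes = nes, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: size=%d ES=%.3f NES=%.3f p=%.3g\n",
              x$set_size, x$es, x$nes, x$p))
  invisible(x)
}

#' Preranked GSEA over a gene-set collection
#'
#' Runs [gsea_nes()] for every set of a collection and collects a tidy
#' result table with Benjamini-Hochberg q-values across sets. Sets with no
#' member in the ranked list are reported with NA statistics.
#'
#' @param ranked named numeric vector of ranking statistics.
#' @param sets named list of character vectors (e.g. read from a GMT file
#'   with [read_gmt()]).
#' @param n_perm,seed,weight_exponent passed to [gsea_nes()].
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    res <- suppressWarnings(
      gsea_nes(ranked, sets[[nm]], n_perm = n_perm,
               seed = stage_seed(seed, paste0("gsea_", nm)),
               weight_exponent = weight_exponent))
    data.frame(set = nm, size = res$set_size, es = res$es, nes = res$nes,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Over-representation (hypergeometric) test of a gene list in gene sets
#'
#' For each set, the one-sided hypergeometric enrichment tail of the overlap
#' between `gene_list` and the set within a background universe — the same
#' tail statistic as [overlap_significance()] (one shared implementation) —
#' with Benjamini-Hochberg q-values across all sets tested.
#'
#' @param gene_list character vector of genes of interest.
#' @param sets named list of character vectors.
#' @param universe either a character vector of background genes (sets and
#'   list are intersected with it) or a single integer universe size (list
#'   and sets are then taken as given).
#' @return data.frame: `set`, `size` (set size in universe), `overlap`, `p`,
#'   `q`, sorted by ascending p (ties by set name).
#' @export
ora_test <- function(gene_list, sets, universe) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  gene_list <- unique(toupper(gene_list))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.character(universe)) {
    universe <- unique(toupper(universe))
    N <- length(universe)
    gene_list <- intersect(gene_list, universe)
    sets <- lapply(sets, intersect, universe)
  } else {
    stopifnot(is.numeric(universe), length(universe) == 1L)
    N <- as.integer(universe)
  }
  if (N < length(gene_list))
    stop("ora_test: universe smaller than the gene list", call. = FALSE)
  if (all(lengths(sets) == 0L))
    stop("ora_test: no set intersects the universe", call. = FALSE)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(gene_list, sets[[nm]]))
    p <- if (K == 0L) NA_real_ else hyper_tail_p(k, K, n, N)
    data.frame(set = nm, size = K, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}

#' Top-k report of enrichment results
#'
#' For GSEA-style results (column `nes`) the top `k` sets by |NES|, optionally
#' split by NES sign; for ORA-style results (no `nes` column) the top `k` by
#' ascending p. Ties are broken by set name so the report is stable.
#'
#' @param results data.frame from [gsea_preranked()] or [ora_test()].
#' @param k number of sets to keep (per direction when `per_direction`).
#' @param per_direction report the top k separately for positive and negative
#'   NES (GSEA results only).
#' @return data.frame of the selected rows, with a `report_direction` column
#'   when `per_direction` is set.
#' @export
top_k_report <- function(results, k = 10L, per_direction = FALSE) {
  stopifnot(is.data.frame(results), k >= 1L)
  if ("nes" %in% names(results)) {
    res <- results[!is.na(results$nes), , drop = FALSE]
    if (per_direction) {
      take <- function(rows, dirname) {
        rows <- rows[order(-abs(rows$nes), rows$set), , drop = FALSE]
        rows <- utils::head(rows, k)
        if (nrow(rows) > 0L) rows$report_direction <- dirname
        rows
      }
      out <- rbind(take(res[res$nes > 0, , drop = FALSE], "positive"),
                   take(res[res$nes < 0, , drop = FALSE], "negative"))
    } else {
      out <- utils::head(res[order(-abs(res$nes), res$set), , drop = FALSE], k)
    }
  } else {
    out <- utils::head(results[order(results$p, results$set), , drop = FALSE], k)
  }
  rownames(out) <- NULL
  out
}
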