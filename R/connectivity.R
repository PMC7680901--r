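#' Ranked reference instance
#'
#' One profiling instance of a perturbagen: the complete reference gene list
#' ordered by the perturbagen's effect, rank 1 = most up-regulated.
#'
#' @param id instance identifier.
#' @param perturbagen perturbagen (molecule) name.
#' @param cell_line cell line name.
#' @param genes character vector: the reference genes in rank order.
#' @param scores optional numeric vector of the underlying effect scores
#'   (same order as `genes`), kept for export to RNK files.
#' @return list of class `ranked_instance`.
#' @export
ranked_instance <- function(id, perturbagen, cell_line, genes, scores = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("ranked_instance: duplicate genes in ranked list for '", id, "'",
         call. = FALSE)
  if (!is.null(scores) && length(scores) != length(genes))
    stop("ranked_instance: scores and genes differ in length", call. = FALSE)
  structure(list(id = id, perturbagen = perturbagen, cell_line = cell_line,
                 genes = genes, scores = scores),
            class = "ranked_instance")
}

#' Query signature for the connectivity screen
#'
#' @param up,down disjoint, non-empty character vectors of gene symbols
#'   (the up- and down-regulated tags of the disease signature).
#' @return list of class `query_signature`.
#' @export
query_signature <- function(up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) == 0L || length(down) == 0L)
    stop("query_signature: both tag sets must be non-empty", call. = FALSE)
  if (length(intersect(up, down)) > 0L)
    stop("query_signature: up and down tags must be disjoint", call. = FALSE)
  structure(list(up = up, down = down), class = "query_signature")
}

#' Core rank-based KS statistic from tag ranks
#'
#' The bare statistic behind [ks_statistic()], taking tag ranks directly:
#' with sorted ranks \eqn{V(1)<\dots<V(t)} in a list of \eqn{n} genes,
#' `a = max_j [j/t - V(j)/n]`, `b = max_j [V(j)/n - (j-1)/t]`, and
#' `ks = a` if `a > b` else `-b`.
#'
#' @param ranks integer vector of tag positions (1 = top of the list).
#' @param n length of the ranked reference list.
#' @return ks statistic in \[-1, 1\].
#' @export
ks_rank_stat <- function(ranks, n) {
  t <- length(ranks)
  stopifnot(t >= 1L, n >= t, all(ranks >= 1), all(ranks <= n))
  v <- sort(as.numeric(ranks))
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Rank-based Kolmogorov-Smirnov connectivity statistic for one tag set
#'
#' Measures whether the tag genes skew toward the top (`ks > 0`) or the bottom
#' (`ks < 0`) of an instance's ranked list. With tag ranks
#' \eqn{V(1) < \dots < V(t)} in a list of \eqn{n} genes,
#' \deqn{a = \max_j\left[\frac{j}{t} - \frac{V(j)}{n}\right],\qquad
#'       b = \max_j\left[\frac{V(j)}{n} - \frac{j-1}{t}\right],}
#' and \eqn{ks = a} if \eqn{a > b}, else \eqn{-b}.
#'
#' Tags absent from the reference list are dropped (with a message) and `t`
#' recomputed; if no tag is present the instance is named in an error.
#'
#' @param tags character vector of tag gene symbols.
#' @param instance a [ranked_instance].
#' @return ks statistic in \[-1, 1\].
#' @export
ks_statistic <- function(tags, instance) {
  stopifnot(inherits(instance, "ranked_instance"))
  ranks <- match(tags, instance$genes)
  absent <- sum(is.na(ranks))
  if (absent == length(tags))
    stop("ks_statistic: no query tag present in ranked list of instance '",
         instance$id, "'", call. = FALSE)
  if (absent > 0L)
    message("ks_statistic: dropped ", absent, " tag(s) absent from instance '",
            instance$id, "'")
  ks_rank_stat(ranks[!is.na(ranks)], length(instance$genes))
}

#' Raw connectivity score of one instance against a query signature
#'
#' Combines the KS statistics of the up- and down-tag sets: a perturbagen that
#' pushes the disease's up-genes down and its down-genes up gets a strongly
#' negative score (a reverser). When both tag sets skew the same way the
#' evidence is self-contradictory and the score is 0 by convention:
#' `s = ks_up - ks_down` if the two statistics have opposite signs or one is
#' zero, else `s = 0`.
#'
#' @param query a [query_signature].
#' @param instance a [ranked_instance].
#' @return list: `instance_id`, `perturbagen`, `cell_line`, `ks_up`,
#'   `ks_down`, `s` (raw combined score in \[-2, 2\]).
#' @export
instance_connectivity <- function(query, instance) {
  stopifnot(inherits(query, "query_signature"))
  ks_up <- ks_statistic(query$up, instance)
  ks_down <- ks_statistic(query$down, instance)
  s <- if (sign(ks_up) == sign(ks_down) && ks_up != 0 && ks_down != 0) 0
  else ks_up - ks_down
  list(instance_id = instance$id, perturbagen = instance$perturbagen,
       cell_line = instance$cell_line, ks_up = ks_up, ks_down = ks_down, s = s)
}

#' Scale raw connectivity scores to \[-1, 1\] within a screen
#'
#' Positive raw scores are divided by the maximum positive score, negative
#' ones by the absolute value of the most negative score, zeros stay zero.
#' At least one instance attains +1 or -1 whenever any score is non-zero.
#'
#' @param s numeric vector of raw combined scores (one screen = one scaling
#'   batch).
#' @return numeric vector of scaled enrichment scores (ES) in \[-1, 1\].
#' @export
scale_scores <- function(s) {
  out <- numeric(length(s))
  pos <- s > 0; neg <- s < 0
  if (!any(pos) && !any(neg)) {
    warning("scale_scores: all raw scores are zero; scaled scores are all zero")
    return(out)
  }
  if (any(pos)) out[pos] <- s[pos] / max(s[pos])
  if (any(neg)) out[neg] <- s[neg] / abs(min(s[neg]))
  out
}

#' Score every instance of a reference database against a query
#'
#' Runs [instance_connectivity()] over all instances and scales the raw
#' scores per screen with [scale_scores()].
#'
#' @param query a [query_signature].
#' @param db a `perturbagen_db` (or any list with an `instances` element of
#'   [ranked_instance]s).
#' @return data.frame with one row per instance: `instance_id`, `perturbagen`,
#'   `cell_line`, `ks_up`, `ks_down`, `s` (raw), `es` (scaled).
#' @export
connectivity_screen <- function(query, db) {
  instances <- if (inherits(db, "perturbagen_db")) db$instances else db
  stopifnot(length(instances) >= 1L)
  rows <- lapply(instances, function(inst) {
    as.data.frame(instance_connectivity(query, inst), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$es <- scale_scores(out$s)
  out
}

#' Summarize instance scores per (perturbagen, cell line)
#'
#' Mean scaled ES and instance count per group, plus a permutation p-value:
#' the fraction of `n_perm` random same-size instance groups, resampled
#' without replacement from the whole screen, whose absolute mean ES is at
#' least the observed one. The permutation p-value is this package's
#' addition to the classic connectivity output (which reports only n and ES)
#' and is labelled `perm_p` to keep that distinction visible.
#'
#' @param scores instance score table from [connectivity_screen()].
#' @param n_perm number of permutations (default 10000); 0 skips the
#'   permutation test (`perm_p` = NA).
#' @param seed integer seed for the permutation draws.
#' @return data.frame with one row per (perturbagen, cell_line): `perturbagen`,
#'   `cell_line`, `mean_es`, `n`, `perm_p`.
#' @export
summarize_perturbagen <- function(scores, n_perm = 10000L, seed = 1L) {
  stopifnot(is.data.frame(scores),
            all(c("perturbagen", "cell_line", "es") %in% names(scores)))
  key <- interaction(scores$perturbagen, scores$cell_line, drop = TRUE)
  groups <- split(scores, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(perturbagen = g$perturbagen[1L], cell_line = g$cell_line[1L],
               mean_es = mean(g$es), n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$perm_p <- NA_real_
  if (n_perm > 0L) {
    set.seed(stage_seed(seed, "perm_connectivity"))
    pool <- scores$es
    # the null distribution of a group mean depends only on group size
    null_means <- lapply(sort(unique(out$n)), function(sz) {
      vapply(seq_len(n_perm),
             function(i) mean(pool[sample.int(length(pool), sz)]),
             numeric(1))
    })
    names(null_means) <- as.character(sort(unique(out$n)))
    out$perm_p <- vapply(seq_len(nrow(out)), function(i) {
      nm <- null_means[[as.character(out$n[i])]]
      mean(abs(nm) >= abs(out$mean_es[i]))
    }, numeric(1))
  }
  out[order(out$perturbagen, out$cell_line), , drop = FALSE]
}

#' Filter perturbagen summaries to screening hits
#'
#' Applies the screening thresholds: keep summaries on the requested cell
#' line(s), with at least `min_n` instances, and a mean ES of the requested
#' sign (negative mean ES = signature reversal, the default). Results are
#' sorted by |mean ES| descending and ranked.
#'
#' @param summaries output of [summarize_perturbagen()].
#' @param cell_line character vector of cell lines to keep (default "HL60").
#' @param min_n minimum instance count per summary (default 3).
#' @param direction `"negative"` (reversers, default), `"positive"`
#'   (mimickers) or `"both"`.
#' @return data.frame of class `hit_table` with columns `perturbagen`,
#'   `cell_line`, `mean_es`, `n`, `perm_p`, `rank`.
#' @export
filter_hits <- function(summaries, cell_line = "HL60", min_n = 3L,
                        direction = c("negative", "positive", "both")) {
  direction <- match.arg(direction)
  stopifnot(min_n >= 1L)
  if (nrow(summaries) == 0L) {
    empty <- cbind(summaries, rank = integer(0))
    class(empty) <- c("hit_table", "data.frame")
    return(empty)
  }
  available <- unique(summaries$cell_line)
  if (!any(cell_line %in% available))
    stop("filter_hits: unknown cell line(s) ", paste(cell_line, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  keep <- summaries$cell_line %in% cell_line & summaries$n >= min_n
  keep <- keep & switch(direction,
                        negative = summaries$mean_es < 0,
                        positive = summaries$mean_es > 0,
                        both = rep(TRUE, nrow(summaries)))
  hits <- summaries[keep, , drop = FALSE]
  hits <- hits[order(-abs(hits$mean_es), hits$perturbagen), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Build the query signature from a conserved signature
#'
#' Takes the up/down cDEG genes, orders each side by ascending human p-value
#' (ties broken by gene symbol, lexicographic) and truncates to
#' `max_per_side` tags per side, emulating a "top N probes per side" query.
#'
#' @param cdeg a [conserved_signature] whose `table` carries `human_p`.
#' @param human_degs optional full moderated DEG table used to look up
#'   p-values when `cdeg$table` lacks them.
#' @param max_per_side maximum tags per side (default 1000).
#' @return a [query_signature].
#' @export
build_query <- function(cdeg, human_degs = NULL, max_per_side = 1000L) {
  stopifnot(inherits(cdeg, "conserved_signature"), max_per_side >= 1L)
  if (length(cdeg$up) == 0L || length(cdeg$down) == 0L)
    stop("build_query: query needs both an up and a down side; cDEG has ",
         length(cdeg$up), " up / ", length(cdeg$down), " down", call. = FALSE)
  pvals <- NULL
  if (!is.null(cdeg$table) && "human_p" %in% names(cdeg$table))
    pvals <- stats::setNames(cdeg$table$human_p, cdeg$table$gene)
  else if (!is.null(human_degs))
    pvals <- stats::setNames(human_degs$p, toupper(human_degs$gene))
  take <- function(genes) {
    if (is.null(pvals)) {
      sel <- sort(genes)
    } else {
      p <- pvals[genes]
      p[is.na(p)] <- 1
      sel <- genes[order(p, genes)]
    }
    utils::head(sel, max_per_side)
  }
  query_signature(up = take(cdeg$up), down = take(cdeg$down))
}
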