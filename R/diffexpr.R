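#' Per-gene two-group fit
#'
#' Ordinary least-squares two-group summaries per gene: the log2 fold change
#' (case minus control), the pooled within-group sample variance and its
#' residual degrees of freedom. This is the input to empirical-Bayes variance
#' moderation ([ebayes_moderate()]).
#'
#' @param study an [expression_study].
#' @return data.frame with columns `gene`, `logfc`, `s2` (pooled variance),
#'   `df` (residual degrees of freedom), plus attributes `n_case`,
#'   `n_control`, `species`.
#' @export
fit_two_groups <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  case <- study$mat[, study$groups == "case", drop = FALSE]
  ctrl <- study$mat[, study$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("fit_two_groups: each group needs at least 2 samples", call. = FALSE)
  logfc <- rowMeans(case) - rowMeans(ctrl)
  ss1 <- rowSums((case - rowMeans(case))^2)
  ss2 <- rowSums((ctrl - rowMeans(ctrl))^2)
  df <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(study$mat),
                    logfc = unname(logfc),
                    s2 = unname((ss1 + ss2) / df),
                    df = df,
                    stringsAsFactors = FALSE)
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  attr(out, "species") <- study$species
  out
}

# Inverse of trigamma() by Newton iteration on 1/trigamma, which is nearly
# linear; converges in a handful of steps for any y > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Moment-matching estimate of the variance prior (d0, s0^2) on the log scale.
# Under the hierarchical model s2_g ~ s0^2 * F(d_g, d0), log(s2_g) has mean
# log(s0^2) + digamma(d_g/2) - digamma(d0/2) - log(d_g/d0) and variance
# trigamma(d_g/2) + trigamma(d0/2); matching the empirical mean and variance
# of log(s2_g) yields d0 via the inverse trigamma and then s0^2.
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok))
    stop("ebayes_moderate: all gene variances are zero; ",
         "add noise to the data (degenerate, noise-free input)", call. = FALSE)
  z <- log(s2[ok])
  dfok <- rep_len(df, length(s2))[ok]
  e <- z - digamma(dfok / 2) + log(dfok / 2)
  evar <- stats::var(e) - mean(trigamma(dfok / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-gene variances toward a prior estimated from all genes and
#' forms moderated t-statistics: the posterior variance is
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g),}
#' the moderated t is `logfc / (s_tilde * sqrt(1/n_case + 1/n_control))`, and
#' two-sided p-values use a t distribution on `d0 + d_g` degrees of freedom.
#' The prior `(d0, s0^2)` is estimated by moment matching of the scaled-F
#' distribution of the sample variances on the log scale (see
#' `estimate_variance_prior` in the source); exact equality with other
#' moderated-t implementations is not claimed, though agreement is close.
#'
#' @param fit output of [fit_two_groups()].
#' @param prior optional list `list(d0 =, s02 =)` overriding estimation
#'   (useful for studying the ordinary-t limit `d0 -> 0` and the fully
#'   pooled limit `d0 -> Inf`).
#' @return list with `params` (`d0`, `s02`) and `table`, a data.frame with
#'   columns `gene`, `logfc`, `s2`, `s2_post`, `t`, `p`, `fdr`, `direction`
#'   (`fdr` is Benjamini-Hochberg, emitted for convenience; the default
#'   calling threshold uses raw p).
#' @export
ebayes_moderate <- function(fit, prior = NULL) {
  stopifnot(is.data.frame(fit), all(c("gene", "logfc", "s2", "df") %in% names(fit)))
  if (is.null(prior)) {
    if (nrow(fit) < 10L)
      stop("ebayes_moderate: need at least 10 genes to estimate the variance prior",
           call. = FALSE)
    prior <- estimate_variance_prior(fit$s2, fit$df)
  }
  d0 <- prior$d0; s02 <- prior$s02
  stopifnot(d0 > 0, s02 > 0)
  n1 <- attr(fit, "n_case"); n2 <- attr(fit, "n_control")
  if (is.null(n1) || is.null(n2))
    stop("ebayes_moderate: fit lacks n_case/n_control attributes", call. = FALSE)
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(fit)) else
    (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- fit$logfc / se
  df_total <- d0 + fit$df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  tab <- data.frame(gene = fit$gene,
                    logfc = fit$logfc,
                    s2 = fit$s2,
                    s2_post = s2_post,
                    t = tstat,
                    p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    direction = ifelse(fit$logfc < 0, "down", "up"),
                    stringsAsFactors = FALSE)
  attr(tab, "n_case") <- n1
  attr(tab, "n_control") <- n2
  attr(tab, "species") <- attr(fit, "species")
  list(params = list(d0 = d0, s02 = s02), table = tab)
}

#' Call differentially expressed genes at a raw p-value threshold
#'
#' Genes with `p < alpha` (strict inequality, matching thresholds written as
#' "p < 0.05") are split by direction of change. No multiple-testing
#' correction is applied by default; pass the `fdr` column yourself if you
#' want an adjusted threshold.
#'
#' @param table a moderated DEG table ([ebayes_moderate()]`$table`).
#' @param alpha raw p-value threshold in (0, 1); default 0.05.
#' @return list of class `deg_list`: `up`, `down` (character vectors of gene
#'   symbols) and `table`, the retained rows.
#' @export
call_degs <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("gene", "p", "direction") %in% names(table)))
  if (alpha <= 0 || alpha > 1)
    stop("call_degs: alpha must lie in (0, 1]", call. = FALSE)
  keep <- table$p < alpha
  tab <- table[keep, , drop = FALSE]
  deg_list(up = tab$gene[tab$direction == "up"],
           down = tab$gene[tab$direction == "down"],
           table = tab)
}

#' Construct a DEG list
#'
#' @param up,down disjoint character vectors of gene symbols.
#' @param table optional data.frame with at least `gene`, `logfc`, `p`,
#'   `direction` rows backing the calls.
#' @return list of class `deg_list`.
#' @export
deg_list <- function(up, down, table = NULL) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)) > 0L)
    stop("deg_list: up and down sets must be disjoint", call. = FALSE)
  structure(list(up = up, down = down, table = table), class = "deg_list")
}

#' @export
print.deg_list <- function(x, ...) {
  cat(sprintf("deg_list: %d up, %d down\n", length(x$up), length(x$down)))
  invisible(x)
}
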