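#' Bibliometric triage score
#'
#' `score = log10(c * p * i * w)` for a molecule with `c` disease-related
#' clinical trials, `p` publications, impact tier `i` in 1..3 and a fixed
#' weight `w` (default 2). A LOW score marks a molecule scarcely studied in
#' the disease area — the candidates the triage is designed to surface.
#' When `c * p = 0` the molecule has no literature footprint at all and gets
#' the sentinel score `-Inf`, guaranteed below any finite score and flagged
#' `unstudied`; a pseudocount is deliberately avoided because it would
#' silently reorder exactly those most interesting molecules.
#'
#' The log base (10) only shifts the scale; every downstream use (ranking,
#' bubble radius) is invariant to it.
#'
#' @param trials,publications non-negative integer counts (vectorized).
#' @param impact_tier impact tier in `{1, 2, 3}`.
#' @param weight positive weight `w`, default 2.
#' @return numeric vector of scores; `-Inf` for zero-count molecules, with
#'   attribute `unstudied` (logical vector).
#' @export
bibliometric_score <- function(trials, publications, impact_tier, weight = 2) {
  stopifnot(all(trials >= 0), all(publications >= 0), weight > 0,
            all(impact_tier %in% 1:3))
  prod <- trials * publications * impact_tier * weight
  unstudied <- trials * publications == 0
  score <- ifelse(unstudied, -Inf, log10(prod))
  attr(score, "unstudied") <- unstudied
  score
}

#' Score a bibliometric record table
#'
#' @param biblio data.frame with columns `molecule`, `trials`, `publications`,
#'   `impact_tier` (as produced by [simulate_bibliometrics()] or read with
#'   [read_biblio()]).
#' @param weight weight `w` passed to [bibliometric_score()].
#' @return the input with `score` and `unstudied` columns appended.
#' @export
biblio_scores <- function(biblio, weight = 2) {
  stopifnot(is.data.frame(biblio),
            all(c("molecule", "trials", "publications", "impact_tier") %in% names(biblio)))
  sc <- bibliometric_score(biblio$trials, biblio$publications,
                           biblio$impact_tier, weight)
  biblio$score <- as.numeric(sc)
  biblio$unstudied <- attr(sc, "unstudied")
  biblio
}

#' Triage screening hits by bibliometric score
#'
#' Joins hits with bibliometric scores and sorts ascending by score, so the
#' least-studied molecules come first; missing bibliometric records get the
#' sentinel `-Inf` (treated as entirely unstudied). Ties are broken by
#' |mean ES| descending, then molecule name.
#'
#' @param hits a `hit_table` from [filter_hits()] (columns `perturbagen`,
#'   `mean_es`, ...).
#' @param biblio a scored bibliometric table ([biblio_scores()]) or a raw
#'   record table (scored internally with default weight).
#' @param top_k optionally keep only the first `top_k` rows.
#' @return data.frame: hit columns plus `score`, `unstudied`,
#'   `triage_rank`.
#' @export
rank_candidates <- function(hits, biblio, top_k = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    out <- cbind(hits, score = numeric(0), unstudied = logical(0),
                 triage_rank = integer(0))
    return(out)
  }
  if (!"score" %in% names(biblio)) biblio <- biblio_scores(biblio)
  idx <- match(hits$perturbagen, biblio$molecule)
  hits$score <- biblio$score[idx]
  hits$unstudied <- biblio$unstudied[idx]
  hits$score[is.na(idx)] <- -Inf
  hits$unstudied[is.na(idx)] <- TRUE
  ord <- order(hits$score, -abs(hits$mean_es), hits$perturbagen)
  out <- hits[ord, , drop = FALSE]
  out$triage_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

# Inverse-linear radius mapping: the largest score gets r_min, the smallest
# (sentinels included, treated as the finite minimum) gets r_max; zero score
# range collapses to the midpoint.
bubble_radius <- function(score, r_min, r_max) {
  s <- score
  finite <- is.finite(s)
  if (!any(finite)) return(rep((r_min + r_max) / 2, length(s)))
  s[!finite] <- min(s[finite])
  rng <- range(s)
  if (diff(rng) == 0) return(rep((r_min + r_max) / 2, length(s)))
  r_min + (r_max - r_min) * (rng[2] - s) / (rng[2] - rng[1])
}

#' Render the cell-line bubble plot of screening hits
#'
#' One horizontal band per cell line (default colors blue = HL60,
#' yellow = MCF7, orange = PC3), vertical position = |mean ES|, seeded
#' uniform horizontal jitter within the band to avoid overplotting, and
#' bubble radius inversely proportional (inverse-linear, bounded
#' \[r_min, r_max\]) to the bibliometric score — big bubbles are the
#' scarcely studied molecules. Cell lines without a configured color fall
#' back to the standard palette cycle.
#'
#' Alongside (optionally) drawing the figure, the function always returns the
#' tidy table of plotted coordinates so the layout is testable without pixel
#' comparison.
#'
#' @param triaged a triaged hit table ([rank_candidates()]) with columns
#'   `perturbagen`, `cell_line`, `mean_es`, `score`.
#' @param png_file,svg_file optional output paths; when `NULL` nothing is
#'   drawn to that device.
#' @param draw also draw on the active device (default FALSE).
#' @param seed seed for the horizontal jitter.
#' @param r_min,r_max bubble radius bounds (plot units).
#' @param jitter_width half-width of the uniform jitter within a band.
#' @param colors named vector of band colors per cell line.
#' @return data.frame (invisibly when drawing): `molecule`, `cell_line`,
#'   `x` (jittered position), `y` (|mean ES|), `es` (signed), `score`,
#'   `radius`, `color`.
#' @export
render_bubble_plot <- function(triaged, png_file = NULL, svg_file = NULL,
                               draw = FALSE, seed = 1L,
                               r_min = 0.02, r_max = 0.12,
                               jitter_width = 0.30,
                               colors = c(HL60 = "blue", MCF7 = "gold",
                                          PC3 = "orange")) {
  stopifnot(is.data.frame(triaged), nrow(triaged) >= 1L,
            all(c("perturbagen", "cell_line", "mean_es", "score") %in% names(triaged)))
  lines <- sort(unique(triaged$cell_line))
  band <- match(triaged$cell_line, lines)
  set.seed(stage_seed(seed, "jitter"))
  x <- band + stats::runif(nrow(triaged), -jitter_width, jitter_width)
  col <- colors[triaged$cell_line]
  fallback <- grDevices::palette()
  miss <- is.na(col)
  if (any(miss))
    col[miss] <- fallback[(band[miss] - 1L) %% length(fallback) + 1L]
  tab <- data.frame(molecule = triaged$perturbagen,
                    cell_line = triaged$cell_line,
                    x = x,
                    y = abs(triaged$mean_es),
                    es = triaged$mean_es,
                    score = triaged$score,
                    radius = bubble_radius(triaged$score, r_min, r_max),
                    color = unname(col),
                    stringsAsFactors = FALSE)

  draw_it <- function() {
    graphics::plot(NA, xlim = c(0.5, length(lines) + 0.5),
                   ylim = c(0, max(tab$y) * 1.15 + 1e-9),
                   xaxt = "n", xlab = "cell line", ylab = "|mean ES|",
                   main = "Connectivity screen hits")
    graphics::axis(1, at = seq_along(lines), labels = lines)
    graphics::symbols(tab$x, tab$y, circles = tab$radius, inches = FALSE,
                      add = TRUE, bg = grDevices::adjustcolor(tab$color, 0.6),
                      fg = tab$color)
    graphics::text(tab$x, tab$y, labels = tab$molecule, cex = 0.55, pos = 3)
  }
  if (!is.null(png_file)) {
    grDevices::png(png_file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_it()
  }
  if (!is.null(svg_file)) {
    grDevices::svg(svg_file, width = 7.5, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_it()
  }
  if (draw) draw_it()
  if (draw || !is.null(png_file) || !is.null(svg_file)) invisible(tab) else tab
}
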