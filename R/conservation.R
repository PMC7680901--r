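#' Map a mouse DEG list into human symbol space
#'
#' Renames each mouse gene through the ortholog map. Lookup is
#' case-normalized (mouse/human symbol casing conventions differ). Genes with
#' no map entry are dropped; genes involved in one-to-many or many-to-one
#' pairs are dropped under the default strict policy (or resolved to the
#' first human symbol in alphabetical order under `policy = "first"`).
#' Fold changes, p-values and directions are carried over unchanged.
#'
#' @param deg_mouse a [deg_list] in mouse symbols.
#' @param map data.frame with columns `mouse_symbol`, `human_symbol`.
#' @param policy `"drop"` (default, strict one-to-one) or `"first"`
#'   (first-alphabetical human symbol for ambiguous pairs).
#' @return A [deg_list] in human symbols; attributes `n_unmapped` and
#'   `n_ambiguous` count dropped genes.
#' @export
map_orthologs <- function(deg_mouse, map, policy = c("drop", "first")) {
  policy <- match.arg(policy)
  stopifnot(inherits(deg_mouse, "deg_list"))
  if (!is.data.frame(map) || nrow(map) == 0L ||
      !all(c("mouse_symbol", "human_symbol") %in% names(map)))
    stop("map_orthologs: ortholog map is empty or malformed", call. = FALSE)

  map <- unique(data.frame(mouse_symbol = toupper(map$mouse_symbol),
                           human_symbol = toupper(map$human_symbol),
                           stringsAsFactors = FALSE))
  multi_m <- map$mouse_symbol[duplicated(map$mouse_symbol)]
  multi_h <- map$human_symbol[duplicated(map$human_symbol)]
  ambiguous <- map$mouse_symbol %in% multi_m | map$human_symbol %in% multi_h
  if (policy == "drop") {
    map_use <- map[!ambiguous, , drop = FALSE]
  } else {
    map_use <- map[order(map$mouse_symbol, map$human_symbol), , drop = FALSE]
    map_use <- map_use[!duplicated(map_use$mouse_symbol), , drop = FALSE]
  }
  lut <- stats::setNames(map_use$human_symbol, map_use$mouse_symbol)

  rename_set <- function(genes) {
    hit <- lut[toupper(genes)]
    unname(hit[!is.na(hit)])
  }
  all_genes <- c(deg_mouse$up, deg_mouse$down)
  n_ambiguous <- sum(toupper(all_genes) %in% map$mouse_symbol[ambiguous] &
                       !(toupper(all_genes) %in% names(lut)))
  n_unmapped <- sum(!(toupper(all_genes) %in% map$mouse_symbol))

  tab <- deg_mouse$table
  if (!is.null(tab)) {
    hit <- lut[toupper(tab$gene)]
    tab <- tab[!is.na(hit), , drop = FALSE]
    tab$gene <- unname(hit[!is.na(hit)])
  }
  out <- deg_list(up = rename_set(deg_mouse$up),
                  down = rename_set(deg_mouse$down),
                  table = tab)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Extract the conserved, direction-concordant signature (cDEG)
#'
#' Intersects two DEG lists in the same (human) symbol space and keeps the
#' genes whose direction of change agrees — the conserved differentially
#' expressed genes. Concordance is judged on sign only, not magnitude.
#' Symbols are compared case-insensitively (upper-cased).
#'
#' @param deg_human,deg_mouse_mapped [deg_list]s in human symbol space.
#' @return list of class `conserved_signature`: `overlap` (all symbols DE in
#'   both), `up`, `down` (the concordant cDEG split by direction),
#'   `discordant` (DE in both, opposite directions), and `table` with per-gene
#'   human/mouse fold changes and the human p-value when the input lists carry
#'   backing tables.
#' @export
conserved_signature <- function(deg_human, deg_mouse_mapped) {
  stopifnot(inherits(deg_human, "deg_list"), inherits(deg_mouse_mapped, "deg_list"))
  hu_up <- toupper(deg_human$up); hu_dn <- toupper(deg_human$down)
  mo_up <- toupper(deg_mouse_mapped$up); mo_dn <- toupper(deg_mouse_mapped$down)
  overlap <- intersect(c(hu_up, hu_dn), c(mo_up, mo_dn))
  up <- intersect(hu_up, mo_up)
  down <- intersect(hu_dn, mo_dn)
  discordant <- setdiff(overlap, c(up, down))

  tab <- NULL
  if (!is.null(deg_human$table) && !is.null(deg_mouse_mapped$table)) {
    ht <- deg_human$table; mt <- deg_mouse_mapped$table
    ht$gene <- toupper(ht$gene); mt$gene <- toupper(mt$gene)
    cdeg <- c(up, down)
    ht <- ht[match(cdeg, ht$gene), , drop = FALSE]
    mt <- mt[match(cdeg, mt$gene), , drop = FALSE]
    tab <- data.frame(gene = cdeg,
                      direction = c(rep("up", length(up)), rep("down", length(down))),
                      human_logfc = ht$logfc,
                      mouse_logfc = mt$logfc,
                      human_p = ht$p,
                      stringsAsFactors = FALSE)
  }
  structure(list(overlap = overlap, up = up, down = down,
                 discordant = discordant, table = tab),
            class = "conserved_signature")
}

#' @export
print.conserved_signature <- function(x, ...) {
  cat(sprintf("conserved_signature: overlap %d, cDEG %d (%d up / %d down), discordant %d\n",
              length(x$overlap), length(x$up) + length(x$down),
              length(x$up), length(x$down), length(x$discordant)))
  invisible(x)
}

# Shared one-sided hypergeometric enrichment tail P(X >= k) for
# X ~ Hypergeometric(N, K, n); also backs the over-representation test.
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Significance of the overlap between two gene lists
#'
#' One-sided enrichment p-value for observing at least `k` genes in common
#' between a list of `K` and a list of `n` genes drawn from a background
#' universe of `N` genes: the upper hypergeometric tail, equivalent to the
#' one-sided Fisher exact test on the 2x2 table. The background universe size
#' is an explicit, consequential parameter — there is no silent default
#' inside the computation; pipeline callers use a configurable value
#' (20,000 protein-coding genes unless overridden).
#'
#' @param K,n sizes of the two gene lists.
#' @param k observed overlap.
#' @param N background universe size.
#' @return list of class `overlap_test`: `N`, `K`, `n`, `k`, `p` (one-sided
#'   enrichment, floored at the smallest positive double), `log_p` (natural
#'   log of the tail, exact even where `p` underflows) and `odds_ratio`
#'   (sample odds ratio of the 2x2 table).
#' @export
overlap_significance <- function(K, n, k, N) {
  stopifnot(length(K) == 1L, length(n) == 1L, length(k) == 1L, length(N) == 1L)
  if (k > min(K, n))
    stop("overlap_significance: overlap k exceeds the smaller list", call. = FALSE)
  if (max(K, n) > N)
    stop("overlap_significance: list sizes exceed the background N", call. = FALSE)
  if (min(K, n, k, N) < 0)
    stop("overlap_significance: counts must be non-negative", call. = FALSE)
  p <- hyper_tail_p(k, K, n, N)
  # log-scale tail survives underflow for extreme overlaps
  log_p <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                         lower.tail = FALSE, log.p = TRUE)
  a <- k; b <- K - k; c <- n - k; d <- N - K - n + k
  or <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  structure(list(N = N, K = K, n = n, k = k,
                 p = min(max(p, .Machine$double.xmin), 1),
                 log_p = min(log_p, 0),
                 odds_ratio = or),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap_test: k=%d of K=%d vs n=%d (background N=%d); p=%.3g, OR=%.3g\n",
              x$k, x$K, x$n, x$N, x$p, x$odds_ratio))
  invisible(x)
}
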