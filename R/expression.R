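#' Two-group expression study
#'
#' A normalized genes-by-samples expression matrix with a two-group sample
#' annotation (case/control) and a species label. Values are assumed already
#' normalized on the log2 scale, as for processed microarray series.
#'
#' @param mat numeric matrix, genes in rows (unique rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param groups named character vector mapping every sample ID to `"case"` or
#'   `"control"`.
#' @param species species label, e.g. `"human"` or `"mouse"`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(mat, groups, species = "unspecified") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression_study: 'mat' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("expression_study: gene symbols (rownames) must be present and unique",
         call. = FALSE)
  if (is.null(colnames(mat)))
    stop("expression_study: sample IDs (colnames) required", call. = FALSE)
  groups <- groups[colnames(mat)]
  if (anyNA(groups))
    stop("expression_study: every sample needs a group label", call. = FALSE)
  if (!all(groups %in% c("case", "control")))
    stop("expression_study: groups must be 'case' or 'control'", call. = FALSE)
  tab <- table(factor(groups, levels = c("case", "control")))
  if (any(tab < 2L))
    stop("expression_study: each group needs at least 2 samples (got ",
         tab[["case"]], " case / ", tab[["control"]], " control)", call. = FALSE)
  structure(list(mat = mat, groups = groups, species = species),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("expression_study (%s): %d genes x %d samples (%d case / %d control)\n",
              x$species, nrow(x$mat), ncol(x$mat),
              tab[["case"]], tab[["control"]]))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$mat)
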