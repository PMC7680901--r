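# Plain-text interchange formats. Everything is tab-delimited or line-based
# so fixtures and outputs stay diffable.

#' Write / read an expression matrix as TSV
#'
#' First column `gene`, remaining columns one per sample (header = sample
#' IDs).
#'
#' @param study an [expression_study] (writer) or a path (reader).
#' @param path output file.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$mat), study$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @param groups_path path of the two-column sample/group TSV.
#' @param species species label attached to the study.
#' @export
read_expression <- function(path, groups_path, species = "unspecified") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_study(mat, stats::setNames(g$group, g$sample), species = species)
}

#' @rdname expression_io
#' @export
write_groups <- function(study, path) {
  utils::write.table(data.frame(sample = names(study$groups),
                                group = unname(study$groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an ortholog map TSV (`mouse_symbol`, `human_symbol`)
#' @param map data.frame with the two symbol columns.
#' @param path file path.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[, c("mouse_symbol", "human_symbol")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a moderated DEG table TSV
#' @param table DEG table (columns `gene`, `logfc`, `t`, `p`, `direction`, ...).
#' @param path file path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read RNK files (gene, score; no header; rank 1 first)
#' @param x named numeric vector (names = genes), written in decreasing order.
#' @param path file path.
#' @export
write_rnk <- function(x, path) {
  x <- sort(x, decreasing = TRUE)
  utils::write.table(data.frame(gene = names(x), score = unname(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Write a perturbagen database as one RNK file per instance plus a manifest
#'
#' The manifest TSV has columns `instance_id`, `perturbagen`, `cell_line`,
#' `path` (RNK paths relative to the manifest's directory).
#'
#' @param db a `perturbagen_db`.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_perturbagen_db <- function(db, dir) {
  stopifnot(inherits(db, "perturbagen_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- vapply(db$instances, function(inst) {
    f <- paste0(inst$id, ".rnk")
    scores <- inst$scores
    if (is.null(scores)) scores <- rev(seq_along(inst$genes))
    write_rnk(stats::setNames(scores, inst$genes), file.path(dir, f))
    f
  }, character(1))
  man <- db$manifest
  man$path <- rel
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man_path)
}

#' Read a perturbagen database from a manifest TSV and its RNK files
#' @param manifest_path path of the manifest TSV.
#' @return a `perturbagen_db`.
#' @export
read_perturbagen_db <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  instances <- lapply(seq_len(nrow(man)), function(i) {
    x <- read_rnk(file.path(base, man$path[i]))
    x <- sort(x, decreasing = TRUE)
    ranked_instance(id = man$instance_id[i], perturbagen = man$perturbagen[i],
                    cell_line = man$cell_line[i], genes = names(x),
                    scores = unname(x))
  })
  labels <- unique(man[, c("perturbagen", "cell_line")])
  structure(list(instances = instances,
                 manifest = man[, c("instance_id", "perturbagen", "cell_line")],
                 labels = labels,
                 universe = instances[[1]]$genes),
            class = "perturbagen_db")
}

#' Read / write GMT gene-set collections
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-section GRP-style query signature file
#'
#' Format: a `> up` header line followed by the up tags (one per line), then
#' a `> down` header and the down tags.
#'
#' @param query a [query_signature] (writer) / file path (reader).
#' @param path output file.
#' @export
write_query <- function(query, path) {
  stopifnot(inherits(query, "query_signature"))
  writeLines(c("> up", query$up, "> down", query$down), path)
  invisible(path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) != 2L)
    stop("read_query: expected exactly two '>' section headers", call. = FALSE)
  labs <- tolower(sub("^>\\s*", "", lines[heads]))
  if (!setequal(labs, c("up", "down")))
    stop("read_query: sections must be 'up' and 'down'", call. = FALSE)
  sec1 <- lines[(heads[1] + 1):(heads[2] - 1)]
  sec2 <- lines[(heads[2] + 1):length(lines)]
  if (labs[1] == "up") query_signature(sec1, sec2) else query_signature(sec2, sec1)
}

#' Read / write bibliometric record TSVs
#' (`molecule`, `trials`, `publications`, `impact_tier`)
#' @param biblio data.frame of records.
#' @param path file path.
#' @export
write_biblio <- function(biblio, path) {
  utils::write.table(biblio, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biblio
#' @export
read_biblio <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
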