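#' Pipeline run configuration
#'
#' All thresholds and paths for an end-to-end run. Defaults mirror the
#' screening conventions used throughout the package: raw p < 0.05 DEG
#' threshold, a 20,000-gene background universe for overlap tests, up to
#' 1000 query tags per side, and hits filtered to negative mean ES with at
#' least 3 instances on the HL60 line.
#'
#' @param outdir output directory for all stage artifacts.
#' @param alpha raw p-value threshold for DEG calling.
#' @param background_n background universe size for the overlap test.
#' @param max_per_side maximum query tags per side.
#' @param hit_cell_line cell line(s) kept by the hit filter.
#' @param hit_min_n minimum instances per (perturbagen, cell line) summary.
#' @param hit_direction `"negative"`, `"positive"` or `"both"`.
#' @param n_perm_connectivity permutations for the perturbagen summaries.
#' @param n_perm_gsea gene-label permutations per gene set.
#' @param n_random_sets random gene sets added to the synthetic GMT.
#' @param top_k sets per direction in the enrichment report.
#' @param seed root seed; stage substreams derive from it.
#' @param sim a [sim_config()] for the simulate stage (its seed is forced to
#'   the root seed so one `--seed` controls the whole run).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir,
                       alpha = 0.05,
                       background_n = 20000L,
                       max_per_side = 1000L,
                       hit_cell_line = "HL60",
                       hit_min_n = 3L,
                       hit_direction = "negative",
                       n_perm_connectivity = 10000L,
                       n_perm_gsea = 1000L,
                       n_random_sets = 10L,
                       top_k = 10L,
                       seed = 1L,
                       sim = sim_config(seed = seed)) {
  stopifnot(alpha > 0, alpha <= 1, background_n > 0, max_per_side >= 1)
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(outdir = outdir, alpha = alpha,
                 background_n = as.integer(background_n),
                 max_per_side = as.integer(max_per_side),
                 hit_cell_line = hit_cell_line,
                 hit_min_n = as.integer(hit_min_n),
                 hit_direction = hit_direction,
                 n_perm_connectivity = as.integer(n_perm_connectivity),
                 n_perm_gsea = as.integer(n_perm_gsea),
                 n_random_sets = as.integer(n_random_sets),
                 top_k = as.integer(top_k),
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(run_config, c(x, list(sim = sim)))
}

pipe_paths <- function(outdir) {
  list(human_expr = file.path(outdir, "human_expression.tsv"),
       human_groups = file.path(outdir, "human_groups.tsv"),
       mouse_expr = file.path(outdir, "mouse_expression.tsv"),
       mouse_groups = file.path(outdir, "mouse_groups.tsv"),
       ortholog_map = file.path(outdir, "ortholog_map.tsv"),
       truth = file.path(outdir, "truth.json"),
       db_dir = file.path(outdir, "perturbagen_db"),
       db_manifest = file.path(outdir, "perturbagen_db", "manifest.tsv"),
       labels = file.path(outdir, "perturbagen_labels.tsv"),
       gmt = file.path(outdir, "gene_sets.gmt"),
       biblio = file.path(outdir, "bibliometrics.tsv"),
       human_degs = file.path(outdir, "human_degs.tsv"),
       mouse_degs = file.path(outdir, "mouse_degs.tsv"),
       human_rnk = file.path(outdir, "human_ranked.rnk"),
       cdeg = file.path(outdir, "cdeg.tsv"),
       overlap = file.path(outdir, "overlap_test.json"),
       query = file.path(outdir, "query.grp"),
       instance_scores = file.path(outdir, "instance_scores.tsv"),
       summaries = file.path(outdir, "perturbagen_summaries.tsv"),
       hits = file.path(outdir, "hits.tsv"),
       gsea = file.path(outdir, "gsea_results.tsv"),
       gsea_top = file.path(outdir, "gsea_top.tsv"),
       ora = file.path(outdir, "ora_results.tsv"),
       triage = file.path(outdir, "triage.tsv"),
       bubble_table = file.path(outdir, "bubble_table.tsv"),
       bubble_png = file.path(outdir, "bubble_plot.png"),
       bubble_svg = file.path(outdir, "bubble_plot.svg"),
       manifest = file.path(outdir, "run_manifest.json"))
}

#' Individual pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs to, fixed file
#' names under `config$outdir`, so any stage can be re-run standalone from
#' the persisted artifacts of the previous ones.
#'
#' @param config a [run_config()].
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  p <- pipe_paths(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression_pair(config$sim)
  write_expression(sim$human, p$human_expr)
  write_groups(sim$human, p$human_groups)
  write_expression(sim$mouse, p$mouse_expr)
  write_groups(sim$mouse, p$mouse_groups)
  write_ortholog_map(sim$ortholog_map, p$ortholog_map)
  jsonlite::write_json(sim$truth, p$truth, digits = NA)

  db <- simulate_perturbagen_db(config$sim, sim$truth)
  write_perturbagen_db(db, p$db_dir)
  utils::write.table(db$labels, p$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # synthetic gene sets: the planted up/down cores plus random sets, so the
  # enrichment stage has signal and null sets to work on
  tr <- sim$truth
  sets <- list(PLANTED_SHARED_UP = tr$human_symbol[tr$status == "shared" & tr$human_logfc > 0],
               PLANTED_SHARED_DOWN = tr$human_symbol[tr$status == "shared" & tr$human_logfc < 0])
  set.seed(stage_seed(config$seed, "gene_sets"))
  for (i in seq_len(config$n_random_sets)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(tr$human_symbol, min(50L, config$sim$n_genes))
  }
  sets <- Filter(length, sets)
  write_gmt(sets, p$gmt)

  write_biblio(simulate_bibliometrics(db$labels$perturbagen, seed = config$seed),
               p$biblio)
  invisible(sim)
}

# Moderated table, with an exact-call fallback for noise-free input where
# every within-group variance is 0: |logFC| > 0 is then infinite evidence
# (p = smallest positive double) and logFC = 0 is none (p = 1).
moderate_or_exact <- function(fit) {
  if (all(fit$s2 == 0)) {
    warning("noise-free input (all gene variances zero): emitting exact calls")
    tab <- data.frame(gene = fit$gene, logfc = fit$logfc, s2 = fit$s2,
                      s2_post = 0,
                      t = sign(fit$logfc) * Inf,
                      p = ifelse(fit$logfc == 0, 1, .Machine$double.xmin),
                      fdr = ifelse(fit$logfc == 0, 1, .Machine$double.xmin),
                      direction = ifelse(fit$logfc < 0, "down", "up"),
                      stringsAsFactors = FALSE)
    return(list(params = list(d0 = NA_real_, s02 = NA_real_), table = tab))
  }
  ebayes_moderate(fit)
}

#' @rdname pipeline_stages
#' @export
stage_de <- function(config) {
  p <- pipe_paths(config$outdir)
  human <- read_expression(p$human_expr, p$human_groups, species = "human")
  mouse <- read_expression(p$mouse_expr, p$mouse_groups, species = "mouse")
  mod_h <- moderate_or_exact(fit_two_groups(human))
  mod_m <- moderate_or_exact(fit_two_groups(mouse))
  write_deg_table(mod_h$table, p$human_degs)
  write_deg_table(mod_m$table, p$mouse_degs)
  rnk <- stats::setNames(mod_h$table$t, mod_h$table$gene)
  rnk[!is.finite(rnk)] <- sign(rnk[!is.finite(rnk)]) * 1e6  # RNK needs finite scores
  write_rnk(rnk, p$human_rnk)
  invisible(list(human = mod_h, mouse = mod_m))
}

#' @rdname pipeline_stages
#' @export
stage_conserve <- function(config) {
  p <- pipe_paths(config$outdir)
  deg_h <- call_degs(read_deg_table(p$human_degs), config$alpha)
  deg_m <- call_degs(read_deg_table(p$mouse_degs), config$alpha)
  map <- read_ortholog_map(p$ortholog_map)
  deg_m_mapped <- map_orthologs(deg_m, map)
  cdeg <- conserved_signature(deg_h, deg_m_mapped)
  ov <- overlap_significance(K = length(deg_h$up) + length(deg_h$down),
                             n = length(deg_m_mapped$up) + length(deg_m_mapped$down),
                             k = length(cdeg$overlap),
                             N = config$background_n)
  out <- if (!is.null(cdeg$table)) cdeg$table else
    data.frame(gene = c(cdeg$up, cdeg$down),
               direction = c(rep("up", length(cdeg$up)),
                             rep("down", length(cdeg$down))),
               stringsAsFactors = FALSE)
  utils::write.table(out, p$cdeg, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(ov), p$overlap, auto_unbox = TRUE, digits = NA)
  invisible(list(cdeg = cdeg, overlap = ov,
                 deg_human = deg_h, deg_mouse_mapped = deg_m_mapped))
}

read_cdeg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(overlap = tab$gene,
                 up = tab$gene[tab$direction == "up"],
                 down = tab$gene[tab$direction == "down"],
                 discordant = character(0), table = tab),
            class = "conserved_signature")
}

#' @rdname pipeline_stages
#' @export
stage_connect <- function(config) {
  p <- pipe_paths(config$outdir)
  cdeg <- read_cdeg(p$cdeg)
  query <- build_query(cdeg, read_deg_table(p$human_degs),
                       max_per_side = config$max_per_side)
  write_query(query, p$query)
  db <- read_perturbagen_db(p$db_manifest)
  scores <- connectivity_screen(query, db)
  summaries <- summarize_perturbagen(scores, n_perm = config$n_perm_connectivity,
                                     seed = config$seed)
  hits <- filter_hits(summaries, cell_line = config$hit_cell_line,
                      min_n = config$hit_min_n, direction = config$hit_direction)
  utils::write.table(scores, p$instance_scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summaries, p$summaries, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hits, p$hits, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(query = query, scores = scores, summaries = summaries,
                 hits = hits))
}

#' @rdname pipeline_stages
#' @export
stage_enrich <- function(config) {
  p <- pipe_paths(config$outdir)
  ranked <- read_rnk(p$human_rnk)
  sets <- read_gmt(p$gmt)
  gsea <- gsea_preranked(ranked, sets, n_perm = config$n_perm_gsea,
                         seed = config$seed)
  utils::write.table(gsea, p$gsea, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(top_k_report(gsea, k = config$top_k, per_direction = TRUE),
                     p$gsea_top, sep = "\t", quote = FALSE, row.names = FALSE)
  cdeg <- read_cdeg(p$cdeg)
  ora <- ora_test(cdeg$overlap, sets, universe = names(ranked))
  utils::write.table(ora, p$ora, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(gsea = gsea, ora = ora))
}

#' @rdname pipeline_stages
#' @export
stage_bibscore <- function(config) {
  p <- pipe_paths(config$outdir)
  hits <- utils::read.delim(p$hits, stringsAsFactors = FALSE)
  biblio <- biblio_scores(read_biblio(p$biblio))
  triaged <- rank_candidates(hits, biblio)
  utils::write.table(triaged, p$triage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(triaged)
}

#' @rdname pipeline_stages
#' @export
stage_viz <- function(config) {
  p <- pipe_paths(config$outdir)
  triaged <- utils::read.delim(p$triage, stringsAsFactors = FALSE)
  if (nrow(triaged) == 0L) {
    warning("stage_viz: no triaged hits to plot")
    utils::write.table(triaged, p$bubble_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(NULL))
  }
  tab <- render_bubble_plot(triaged, png_file = p$bubble_png,
                            svg_file = p$bubble_svg, seed = config$seed)
  utils::write.table(tab, p$bubble_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Run the whole pipeline end to end
#'
#' Executes simulate -> differential expression (both species) -> conserved
#' signature -> query -> connectivity screen -> enrichment -> bibliometric
#' triage -> bubble plot, each stage persisting its artifacts under
#' `config$outdir`. A stage failure halts the run with the failing stage
#' named; artifacts of completed stages are retained. With a fixed
#' config and seed the run is fully deterministic.
#'
#' @param config a [run_config()].
#' @param simulate run the simulate stage first (set `FALSE` to run on
#'   pre-existing conforming input files in `outdir`).
#' @return The run manifest (invisibly): config snapshot, stage-by-stage
#'   record counts, seed, timestamps, package version. Also written to
#'   `run_manifest.json`.
#' @export
run_all <- function(config, simulate = TRUE) {
  stopifnot(inherits(config, "run_config"))
  p <- pipe_paths(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  run_stage <- function(name, fun) {
    tryCatch(fun(config),
             error = function(e) {
               man <- list(config = unclass_config(config), counts = counts,
                           failed_stage = name, error = conditionMessage(e),
                           started = t0, version = pkg_version())
               jsonlite::write_json(man, p$manifest, auto_unbox = TRUE, digits = NA)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }

  if (simulate) run_stage("simulate", stage_simulate)
  de <- run_stage("de", stage_de)
  counts$genes_in <- nrow(de$human$table)
  cons <- run_stage("conserve", stage_conserve)
  counts$degs_human <- length(cons$deg_human$up) + length(cons$deg_human$down)
  counts$degs_mouse_mapped <- length(cons$deg_mouse_mapped$up) +
    length(cons$deg_mouse_mapped$down)
  counts$overlap <- length(cons$cdeg$overlap)
  counts$cdeg <- length(cons$cdeg$up) + length(cons$cdeg$down)
  counts$overlap_p <- cons$overlap$p
  conn <- run_stage("connect", stage_connect)
  counts$instances_scored <- nrow(conn$scores)
  counts$hits <- nrow(conn$hits)
  enr <- run_stage("enrich", stage_enrich)
  counts$gene_sets_tested <- nrow(enr$gsea)
  tri <- run_stage("bibscore", stage_bibscore)
  counts$triaged <- nrow(tri)
  run_stage("viz", stage_viz)

  man <- list(config = unclass_config(config), counts = counts,
              seed = config$seed, started = t0,
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              version = pkg_version())
  jsonlite::write_json(man, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x
}

pkg_version <- function() {
  as.character(utils::packageVersion("cdegscreen"))
}
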