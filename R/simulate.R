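#' Simulate a two-species case/control expression pair with planted truth
#'
#' Generates one human-labelled and one mouse-labelled expression study sharing
#' a planted orthologous differential-expression structure:
#' `frac_de_shared` of genes are DE in both species with the same sign (the
#' conserved core a downstream analysis should recover), `frac_de_private` in
#' one species only, `frac_discordant` in both with opposite signs, and the
#' rest are null. Expression is Gaussian on the log2 scale around group means
#' (control mean = per-gene baseline, case mean = baseline + planted logFC).
#' Mouse symbols are case-variants of the human symbols with an `"m"` suffix,
#' linked through the emitted ortholog map; a fraction of genes is deliberately
#' missing from the map to exercise the mapping step.
#'
#' Per-gene planted |logFC| is drawn from Gamma(shape = 10) with mean
#' `effect_logfc`, independently per species, so planted effects are
#' continuous (tie-free) and vary around the configured mean.
#'
#' @param config a [sim_config()].
#' @return A list with elements `human` and `mouse` ([expression_study]s),
#'   `ortholog_map` (data.frame `mouse_symbol`, `human_symbol`) and `truth`
#'   (data.frame with per-gene `human_symbol`, `mouse_symbol`, `status` in
#'   `{shared, private_human, private_mouse, discordant, null}`,
#'   `human_logfc`, `mouse_logfc`, `has_ortholog`).
#' @export
simulate_expression_pair <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  set.seed(stage_seed(config$seed, "expression"))

  human_symbols <- sprintf("TALG%05d", seq_len(n))
  mouse_symbols <- paste0(substr(human_symbols, 1L, 1L),
                          tolower(substr(human_symbols, 2L, nchar(human_symbols))),
                          "m")

  n_shared <- round(config$frac_de_shared * n)
  n_private <- round(config$frac_de_private * n)
  n_disc <- round(config$frac_discordant * n)
  status <- rep("null", n)
  idx <- sample.int(n)  # random placement of planted genes
  shared_idx <- idx[seq_len(n_shared)]
  private_idx <- idx[n_shared + seq_len(n_private)]
  disc_idx <- idx[n_shared + n_private + seq_len(n_disc)]
  status[shared_idx] <- "shared"
  if (n_private > 0L) {
    half <- sample(c(TRUE, FALSE), n_private, replace = TRUE)
    status[private_idx[half]] <- "private_human"
    status[private_idx[!half]] <- "private_mouse"
  }
  status[disc_idx] <- "discordant"

  draw_mag <- function(m) {
    if (config$effect_logfc == 0) return(rep(0, m))
    stats::rgamma(m, shape = 10, rate = 10 / config$effect_logfc)
  }
  sign_h <- sample(c(-1, 1), n, replace = TRUE)
  human_logfc <- mouse_logfc <- rep(0, n)
  de_h <- status %in% c("shared", "private_human", "discordant")
  de_m <- status %in% c("shared", "private_mouse", "discordant")
  human_logfc[de_h] <- sign_h[de_h] * draw_mag(sum(de_h))
  sign_m <- ifelse(status == "discordant", -sign_h, sign_h)
  mouse_logfc[de_m] <- sign_m[de_m] * draw_mag(sum(de_m))

  ns <- config$n_case + config$n_control
  grp <- c(rep("case", config$n_case), rep("control", config$n_control))
  make_study <- function(logfc, symbols, species, prefix) {
    baseline <- stats::rnorm(n, mean = 7, sd = 1.5)
    mu <- outer(logfc, as.numeric(grp == "case")) + baseline
    mat <- mu + matrix(stats::rnorm(n * ns, sd = config$noise_sd), n, ns)
    samples <- sprintf("%s_%s_%02d", prefix, ifelse(grp == "case", "case", "ctrl"),
                       stats::ave(seq_len(ns), grp, FUN = seq_along))
    dimnames(mat) <- list(symbols, samples)
    expression_study(mat, stats::setNames(grp, samples), species = species)
  }
  human <- make_study(human_logfc, human_symbols, "human", "hs")
  mouse <- make_study(mouse_logfc, mouse_symbols, "mouse", "mm")

  n_missing <- round(config$ortholog_missing_frac * n)
  missing_idx <- sample.int(n, n_missing)
  has_ortholog <- !(seq_len(n) %in% missing_idx)
  ortholog_map <- data.frame(mouse_symbol = mouse_symbols[has_ortholog],
                             human_symbol = human_symbols[has_ortholog],
                             stringsAsFactors = FALSE)

  truth <- data.frame(human_symbol = human_symbols,
                      mouse_symbol = mouse_symbols,
                      status = status,
                      human_logfc = human_logfc,
                      mouse_logfc = mouse_logfc,
                      has_ortholog = has_ortholog,
                      stringsAsFactors = FALSE)
  list(human = human, mouse = mouse, ortholog_map = ortholog_map, truth = truth)
}

#' Simulate a ranked perturbagen reference database
#'
#' Builds a small Connectivity-Map-like reference: each perturbagen has a
#' latent genome-wide effect vector, each profiling instance ranks all genes by
#' that vector plus instance-level noise (rank 1 = most up-regulated by the
#' perturbagen). Planted reversers' latent vectors correlate
#' `-reversal_strength` with the disease log-fold-change signature (the human
#' planted logFC in `truth`), mimickers `+reversal_strength`, and neutral
#' drugs 0. Cell lines are assigned round-robin at the perturbagen level over
#' `cell_lines`, so all instances of one drug share a line and every line is
#' populated.
#'
#' @param config a [sim_config()].
#' @param truth the per-gene truth table from [simulate_expression_pair()].
#' @param cell_lines names to cycle over; defaults to the three classic lines.
#' @return A list of class `perturbagen_db` with `instances` (list of
#'   [ranked_instance] objects), `manifest` (data.frame `instance_id`,
#'   `perturbagen`, `cell_line`), `labels` (data.frame `perturbagen`,
#'   `label` in `{reverser, mimicker, neutral}`, `cell_line`) and `universe`
#'   (the reference gene symbols).
#' @export
simulate_perturbagen_db <- function(config, truth,
                                    cell_lines = c("HL60", "MCF7", "PC3")) {
  validate_sim_config(config)
  stopifnot(is.data.frame(truth), all(c("human_symbol", "human_logfc") %in% names(truth)))
  if (all(truth$human_logfc == 0))
    stop("simulate_perturbagen_db: truth contains no disease signature ",
         "(all planted logFC are zero)", call. = FALSE)
  set.seed(stage_seed(config$seed, "perturbagens"))

  genes <- truth$human_symbol
  n <- length(genes)
  sig <- truth$human_logfc
  sig_unit <- sig / stats::sd(sig)

  n_drug <- config$n_perturbagens
  drugs <- sprintf("drug_%03d", seq_len(n_drug))
  label <- rep("neutral", n_drug)
  label[seq_len(config$n_reversers)] <- "reverser"
  if (config$n_mimickers > 0L)
    label[config$n_reversers + seq_len(config$n_mimickers)] <- "mimicker"
  line_of <- cell_lines[(seq_len(n_drug) - 1L) %% length(cell_lines) + 1L]

  rho <- config$reversal_strength
  dir_of <- c(reverser = -1, mimicker = 1, neutral = 0)[label]
  instances <- vector("list", n_drug * config$instances_per_perturbagen)
  man <- vector("list", length(instances))
  k <- 0L
  for (d in seq_len(n_drug)) {
    rho_d <- if (dir_of[d] == 0) 0 else rho
    latent <- dir_of[d] * rho_d * sig_unit +
      sqrt(1 - rho_d^2) * stats::rnorm(n)
    for (i in seq_len(config$instances_per_perturbagen)) {
      k <- k + 1L
      eff <- latent + config$noise_sd * stats::rnorm(n)
      ord <- order(eff, decreasing = TRUE)
      id <- sprintf("%s_inst%02d", drugs[d], i)
      instances[[k]] <- ranked_instance(id = id, perturbagen = drugs[d],
                                        cell_line = line_of[d],
                                        genes = genes[ord],
                                        scores = eff[ord])
      man[[k]] <- data.frame(instance_id = id, perturbagen = drugs[d],
                             cell_line = line_of[d], stringsAsFactors = FALSE)
    }
  }
  structure(list(instances = instances,
                 manifest = do.call(rbind, man),
                 labels = data.frame(perturbagen = drugs, label = label,
                                     cell_line = line_of, stringsAsFactors = FALSE),
                 universe = genes),
            class = "perturbagen_db")
}

#' @export
print.perturbagen_db <- function(x, ...) {
  cat(sprintf("perturbagen_db: %d instances, %d perturbagens, %d reference genes\n",
              length(x$instances), nrow(x$labels), length(x$universe)))
  print(table(x$labels$label))
  invisible(x)
}

#' Simulate bibliometric count records for a set of molecules
#'
#' Emulates triage inputs: per molecule, a leukemia-related clinical-trial
#' count, a publication count, and an impact tier in 1..3 (higher = better
#' journals for the association). Counts are Poisson draws; a sizeable share
#' of molecules ends up scarcely studied, which is exactly the regime the
#' triage score is designed to surface.
#'
#' @param molecules character vector of molecule names.
#' @param seed integer seed.
#' @param mean_trials,mean_publications Poisson means for the two counts.
#' @return data.frame with columns `molecule`, `trials`, `publications`,
#'   `impact_tier`.
#' @export
simulate_bibliometrics <- function(molecules, seed = 1L,
                                   mean_trials = 2, mean_publications = 8) {
  if (length(molecules) == 0L)
    stop("simulate_bibliometrics: empty molecule list", call. = FALSE)
  set.seed(stage_seed(seed, "bibliometrics"))
  data.frame(molecule = as.character(molecules),
             trials = stats::rpois(length(molecules), mean_trials),
             publications = stats::rpois(length(molecules), mean_publications),
             impact_tier = sample(1:3, length(molecules), replace = TRUE),
             stringsAsFactors = FALSE)
}
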