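#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' two-species leukemia comparison (two case/control cohorts sharing a planted
#' orthologous, direction-concordant differential-expression core) together
#' with a small ranked-perturbagen reference containing planted
#' signature-reversing and signature-mimicking drugs.
#'
#' @param n_genes number of genes simulated per species (shared universe).
#' @param n_case,n_control samples per group, per species.
#' @param frac_de_shared fraction of genes planted DE in both species with the
#'   same sign (the conserved core).
#' @param frac_de_private fraction DE in exactly one species.
#' @param frac_discordant fraction DE in both species with opposite signs.
#' @param effect_logfc mean planted log2 fold-change magnitude. Per-gene
#'   magnitudes are drawn from a Gamma distribution with this mean (shape 10),
#'   so planted effects vary around it without ties.
#' @param noise_sd residual Gaussian standard deviation on the log2 scale.
#' @param ortholog_missing_frac fraction of genes absent from the ortholog map.
#' @param n_perturbagens number of perturbagens in the reference database.
#' @param instances_per_perturbagen profiling replicates per perturbagen.
#' @param n_reversers,n_mimickers planted drug counts whose effect vectors
#'   anti-correlate / correlate with the disease signature.
#' @param reversal_strength correlation magnitude in \[0,1\] between a planted
#'   drug's latent effect vector and the disease log-fold-change signature.
#' @param seed root integer seed; every stage derives its own substream from it
#'   (see [stage_seed()]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_case = 10L,
                       n_control = 10L,
                       frac_de_shared = 0.10,
                       frac_de_private = 0.10,
                       frac_discordant = 0.05,
                       effect_logfc = 2,
                       noise_sd = 0.5,
                       ortholog_missing_frac = 0.10,
                       n_perturbagens = 50L,
                       instances_per_perturbagen = 3L,
                       n_reversers = 3L,
                       n_mimickers = 2L,
                       reversal_strength = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_case = as.integer(n_case),
    n_control = as.integer(n_control),
    frac_de_shared = frac_de_shared,
    frac_de_private = frac_de_private,
    frac_discordant = frac_discordant,
    effect_logfc = effect_logfc,
    noise_sd = noise_sd,
    ortholog_missing_frac = ortholog_missing_frac,
    n_perturbagens = as.integer(n_perturbagens),
    instances_per_perturbagen = as.integer(instances_per_perturbagen),
    n_reversers = as.integer(n_reversers),
    n_mimickers = as.integer(n_mimickers),
    reversal_strength = reversal_strength,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_genes", "n_case", "n_control", "n_perturbagens",
              "instances_per_perturbagen")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a positive count", call. = FALSE)
  }
  fracs <- c("frac_de_shared", "frac_de_private", "frac_discordant",
             "ortholog_missing_frac")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_de_shared + cfg$frac_de_private + cfg$frac_discordant > 1)
    stop("sim_config: DE fractions must sum to at most 1", call. = FALSE)
  if (cfg$reversal_strength < 0 || cfg$reversal_strength > 1)
    stop("sim_config: 'reversal_strength' must lie in [0, 1]", call. = FALSE)
  if (cfg$n_reversers < 0 || cfg$n_mimickers < 0 ||
      cfg$n_reversers + cfg$n_mimickers > cfg$n_perturbagens)
    stop("sim_config: n_reversers + n_mimickers must not exceed n_perturbagens",
         call. = FALSE)
  if (cfg$noise_sd < 0) stop("sim_config: 'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$effect_logfc < 0)
    stop("sim_config: 'effect_logfc' must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Derive a named substream seed from a root seed
#'
#' Every stochastic stage of the pipeline draws its seed from the root seed and
#' a stage label, so stages are reproducible when re-run standalone. The
#' derived value is kept inside the 32-bit integer range.
#'
#' @param seed root integer seed.
#' @param stage stage label, e.g. `"expression"`, `"perturbagens"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genes: %d; samples/group: %d case, %d control (per species)\n",
              x$n_genes, x$n_case, x$n_control))
  cat(sprintf("  planted DE: %.0f%% shared, %.0f%% private, %.0f%% discordant; mean |logFC| %.2f; noise sd %.2f\n",
              100 * x$frac_de_shared, 100 * x$frac_de_private,
              100 * x$frac_discordant, x$effect_logfc, x$noise_sd))
  cat(sprintf("  reference: %d perturbagens x %d instances (%d reversers, %d mimickers, strength %.2f)\n",
              x$n_perturbagens, x$instances_per_perturbagen, x$n_reversers,
              x$n_mimickers, x$reversal_strength))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
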