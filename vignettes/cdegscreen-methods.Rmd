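---
title: "Methods: conserved signatures, connectivity screening and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved signatures, connectivity screening and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdegscreen)
```

This vignette documents the statistical model behind each pipeline stage,
the parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Differential expression model

Expression values are assumed normalized on the log2 scale (as for
processed microarray series), approximately Gaussian per gene within each
group, with a two-group design (case vs control) per species. For gene $g$,
`fit_two_groups()` computes $\mathrm{logFC}_g$ (case minus control), the
pooled within-group variance $s^2_g$ and its residual degrees of freedom
$d_g = n_1 + n_2 - 2$.

`ebayes_moderate()` assumes the hierarchical variance model
$s^2_g \mid \sigma^2_g \sim \sigma^2_g \chi^2_{d_g}/d_g$ with
$1/\sigma^2_g \sim \chi^2_{d_0} / (d_0 s_0^2)$, i.e. $s^2_g$ follows a
scaled F distribution. The prior $(d_0, s_0^2)$ is estimated by moment
matching on the log scale: with
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$, the excess of
$\operatorname{var}(e_g)$ over $\psi'(d_g/2)$ identifies $d_0$ through the
inverse trigamma function (solved by Newton iteration, relative tolerance
$10^{-10}$), and the mean of $e_g$ then identifies $s_0^2$. A
non-positive excess yields $d_0 = \infty$ (complete pooling). Genes with
$s^2_g = 0$ are excluded from prior estimation but still get defined
moderated statistics as long as some genes carry noise. The posterior
variance is $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ — always
between $s^2_g$ and $s_0^2$ — and the moderated $t$ uses $d_0 + d_g$
degrees of freedom. This moment-matching recipe is standard for
moderated-t analyses; the test suite cross-checks it against an independent
implementation of the same estimator.

Design choices:

* **Raw p-values, strict threshold.** DEG calling uses raw $p < \alpha$
  (default $\alpha = 0.05$, strict inequality). A BH-FDR column is emitted
  for convenience but takes no part in the default pipeline. Conserved
  two-species signatures tolerate the inflated per-species false-positive
  rate because spurious calls rarely replicate with matching direction
  across species; the conservation stage is the real filter.
* **Noise-free degenerate rule.** When *every* gene has zero within-group
  variance the prior is unidentifiable and `ebayes_moderate()` refuses with
  an instruction to add noise. The pipeline's DE stage instead recognizes
  this case and emits exact calls — $p$ equal to the smallest positive
  double where $|\mathrm{logFC}| > 0$, $p = 1$ otherwise — since a
  noise-free difference is infinite evidence. This keeps fully
  deterministic simulations usable end to end.

## Conservation stage

Mouse DEGs enter human symbol space through an explicit ortholog table.
Lookup is case-normalized (upper-cased on both sides) because mouse and
human symbol casing conventions differ. One-to-many and many-to-one pairs
are dropped by default (strict one-to-one) — reproducible and conservative —
with an optional `"first"` policy that resolves ambiguity to the
alphabetically first human symbol. Unmapped and ambiguous genes are counted
on the returned object.

The cDEG is the direction-concordant intersection: concordance is judged on
the *sign* of logFC only, never its magnitude, since effect sizes are not
comparable across platforms and species. Discordant overlap genes are
reported separately.

Overlap significance is the one-sided hypergeometric enrichment tail
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, computed by
`phyper`. The background $N$ is a consequential, *explicit* parameter: the
default of 20,000 approximates the protein-coding gene count, but any
analysis should set it to the actual assayed universe. The tail is also
returned on the natural-log scale (`log_p`), which stays exact where the
linear-scale p underflows (overlaps of a few hundred genes in a
20,000-gene universe routinely have $p < 10^{-308}$). The p-value
decreases in the overlap $k$ and also decreases in $N$ — the same overlap
inside a larger universe is more surprising — and is symmetric in the two
list sizes.

## Connectivity screen

The query carries up to `max_per_side` (default 1000) up and down tags.
Sides are ordered by ascending human p-value — the natural "strongest
evidence first" order for a truncated query; ordering by |logFC| is the
plausible alternative, and the choice only matters when the cDEG exceeds
the cap. Ties in p are broken by symbol so queries are reproducible.

Each instance ranks the full reference universe (ties are forbidden at the
format level; the simulator emits continuous scores). Per tag set the
rank-based KS statistic is

$$a = \max_j\left[\tfrac{j}{t} - \tfrac{V(j)}{n}\right],\quad
  b = \max_j\left[\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right],\quad
  ks = \begin{cases} a & a > b\\ -b & \text{otherwise,}\end{cases}$$

positive when tags crowd the top. Tags absent from a reference list are
dropped per instance with $t$ recomputed (reference universes are
restricted); only a fully absent tag set is an error. The combined raw
score is $s = ks_{up} - ks_{down}$ unless both share a sign (contradictory
evidence), in which case $s = 0$. Swapping the tag sets negates $s$
exactly; reversing a ranked list flips the sign of a non-zero $s$ (the
discrete $1/n$ asymmetry of the KS maxima means the magnitude may shift by
up to $2/n$, and near-zero scores can land on the same-sign zero rule).

Scaling is per screen (one batch per query): positive scores divide by the
maximum positive, negatives by |minimum negative|, so $ES \in [-1, 1]$ with
at least one extreme attained. Summaries average scaled ES per
(perturbagen, cell line); the permutation p — the fraction of `n_perm`
(default 10,000) random same-size instance groups resampled from the screen
with |mean ES| at least the observed — is this package's addition to the
classic output and is labelled as such (`perm_p`).

Hit filtering mirrors the classic screen: requested cell line(s), $n \ge 3$
instances, negative mean ES, sorted by |mean ES|. `cell_line` accepts a
vector: since the simulator assigns each drug's instances to one line,
panel-wide screens pass all lines and the per-line filter semantics are
preserved.

## Enrichment

`gsea_es()` is the weighted-KS running sum: hits advance by
$|r_i|^w / \sum_{hits}|r|^w$ (default $w = 1$), misses retreat by
$1/(N - t)$, and the ES is the extremum of largest magnitude. Conventions:
a set spanning the whole list (no misses) has ES = 1; all-zero hit weights
under $w > 0$ fall back to equal weights. NES normalizes by the mean |ES|
of sign-matched gene-label permutations — gene-label (not sample)
permutation because only ranked statistics are available in preranked
use — with $p = (1 + \#\{|ES_{perm}| \ge |ES|,\ \text{same sign}\}) /
(1 + \#\text{same-sign})$. Default 1000 permutations per set in the
pipeline configuration (10,000 is preferable when p-values near $10^{-3}$
matter; the floor is $1/(1+\#\text{same-sign})$).

The over-representation test reuses the identical hypergeometric tail as
the overlap test (single shared implementation) with BH q-values across
sets; the conventional reporting cutoff is $p < 0.001$.

## Bibliometric triage and bubble plot

$\mathrm{score}_m = \log_{10}(c_m\, p_m\, i_m\, w)$ with clinical-trial
count $c$, publication count $p$, impact tier $i \in \{1,2,3\}$ (taken as
given input) and weight $w = 2$ inside the logarithm, following the
multiplicative form; the base (10) and $w$ only shift/scale the score and
every downstream use is rank-based, hence invariant to both. Zero-count
molecules ($c\,p = 0$) get a $-\infty$ sentinel flagged `unstudied` rather
than a pseudocount: the whole point of the triage is to surface scarcely
described molecules, and a pseudocount would silently reorder exactly
those. Triage sorts ascending by score, ties broken by |mean ES|
descending, then name.

The bubble plot bands hits by cell line (blue HL60, yellow MCF7, orange
PC3; unknown lines cycle the standard palette), places them at
$y = |\text{mean ES}|$ with seeded uniform horizontal jitter
(half-width 0.30 band units), and maps scores to radii inverse-linearly on
$[r_{min}, r_{max}]$, sentinels pinned to the finite minimum; a zero score
range degenerates to the midpoint radius. The tidy coordinate table is
always returned (and persisted) so the layout is testable without pixel
comparison.

## Synthetic data: what it emulates, and what it does not

`simulate_expression_pair()` emulates the statistical skeleton of a
two-species case/control comparison: per-gene Gaussian log2 expression
around group means (baseline $\mathcal N(7, 1.5)$), a planted DE structure
with a shared direction-concordant core (default 10% of genes), private
per-species DE (10%) and discordant genes (5%), per-gene |logFC| drawn from
Gamma(shape 10) with configurable mean (default 2 — a strong but realistic
microarray effect) so planted effects are continuous and tie-free, residual
sd 0.5, and 10 samples per group — in the range of the public cohorts such
analyses use. Mouse symbols are case-variants of the human ones with a
suffix and an explicit ortholog map (10% of genes deliberately missing), so
the pipeline must actually exercise the mapping step rather than rely on
string identity.

`simulate_perturbagen_db()` gives each drug a latent genome-wide effect
vector correlated $-\rho$ (reversers), $+\rho$ (mimickers) or $0$
(neutral) with the standardized disease logFC vector
($\rho$ = `reversal_strength`, default 0.8); instances add
$\mathcal N(0, \texttt{noise\_sd})$ perturbations before ranking, reusing
the expression noise scale since instance-to-instance variability has no
separate knob. Cell lines are assigned round-robin at the *perturbagen*
level: all instances of one drug share a line and every line is populated.
Assigning lines within drugs would make the $n \ge 3$-per-(drug, line)
filter unsatisfiable at the default 3 instances per drug, and real
reference batches are per-line anyway. Defaults: 50 perturbagens × 3
instances, 3 reversers, 2 mimickers. `simulate_bibliometrics()` draws
Poisson counts (means 2 trials, 8 publications) and uniform tiers.

All randomness flows from one root seed through `stage_seed()`, which
derives a fixed 32-bit substream seed per named stage, so any stage re-run
standalone reproduces the one-shot run and fixed-seed runs are
byte-identical.

Not emulated: probe-level array structure, batch effects, correlated genes
(noise is independent across genes, so variance moderation faces a milder
task than on real arrays), dose–response structure within perturbagens,
restricted reference gene universes, and the long-tailed instance counts of
real reference databases. Passing tests therefore demonstrate correctness
of the algorithms and recovery under the planted model — not performance on
real GEO/CMAP data.

## Problem sizes and verification

The test-suite property checks use exhaustive enumeration where feasible
(every tag subset of lists up to $n = 8$ for the KS statistic; all
hypergeometric configurations up to $N = 12$ against a draw-enumeration
oracle) and Monte-Carlo calibration elsewhere (200-replicate uniformity
checks for permutation p-values at a Kolmogorov bound; 1000-gene null
simulations for type-I error, expected in the 99% binomial band
[0.031, 0.069] at $\alpha = 0.05$). Planted-reverser recovery runs 50
replicates of a 2000-gene, 50-drug × 3-instance screen at $\rho = 0.8$ with
a 100+100-tag query — sizes chosen to keep the full suite under a minute of
compute while leaving the recovery criterion statistically meaningful.
End-to-end reproducibility and noise-free exact-recovery runs use a
400–500-gene configuration, where every stage's behavior is already fully
exercised.

## Known limitations

* Two-group designs only; no covariates, pairing or multi-factor models.
* The moderated-t prior estimator assumes a common scaled-F variance model
  across genes; heavy tails or variance–mean dependence in real data would
  call for robust variants.
* The screen implements the classic unweighted-combination KS connectivity
  score; the newer weighted (WTCS) variant is out of scope.
* Impact tiers are inputs, not derived from impact-factor data.
* The GSEA p floor is permutation-limited; no adaptive/multilevel
  refinement is implemented.
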