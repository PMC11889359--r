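---
title: "Site-centric competitive ABPP: models, parameters and validation"
author: "abppsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-centric competitive ABPP: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abppsites)
```

## The experiment this package analyzes

Covalent pan-kinase probes carrying a sulfonyl-fluoride warhead label
ATP-pocket lysines (and, less often, tyrosines) in live cells. When cells
are pre-treated with a kinase inhibitor, probe labeling at the sites the
inhibitor occupies drops with dose, while unengaged sites stay flat. After
enrichment and LC-MS, a search engine reports probe-modified peptidoforms
with label-free intensities across samples. Because proteolysis is done in
parallel with trypsin (specific, cleaving after K/R) and pepsin (effectively
nonspecific), the same binding-site residue is usually covered by several
distinct peptides per protease.

`abppsites` takes those per-protease modified-peptide tables plus a sample
annotation and produces, per (site, protease): an apparent IC50 with an
asymmetric 95% confidence interval and a competed/stable/ambiguous call.
"Apparent" matters: the number depends on probe/drug incubation times and
target abundance, and is not an equilibrium constant.

## From peptides to sites

Peptides are localized by exact substring search against the proteome
(`locate_peptide()`), which handles nonspecific peptic peptides that a
rule-based digest could never enumerate; tryptic peptides are additionally
validated by the specific digest model (`digest()`: cleavage after K/R, up
to two missed cleavages, length 5–30). Coordinates are 1-based residue
numbers on the canonical sequence. The probe residue is
`match_start + position_in_peptide - 1`, and the residue letter is checked
on every mapping.

Design choices that were genuinely open:

* **I/L ambiguity.** Matching treats I and L as distinct, because the
  search engine reports the database-resolved sequence; an `il_equivalent`
  flag exists for localization-robustness checks.
* **Shared peptides.** A peptide matching several (typically homologous)
  proteins becomes a single multi-protein *site group* keyed by the full
  sorted member set, rather than being apportioned — apportionment would
  invent evidence, and joint reporting mirrors how nonunique ATP-pocket
  peptides are interpreted in practice.
* **Doubly probe-labeled peptides** (rare) contribute their full intensity
  to both site groups and are flagged; splitting the intensity would be
  arbitrary, and full assignment is conservative for competition detection
  (it can only dilute, never fabricate, a dose response).
* **Engine/localization conflicts.** When the search engine's protein
  assignment is absent from the localization result, localization wins and
  the conflict is logged.

## Filtering and aggregation

A peptidoform is kept if it has signal in at least two DMSO replicates of
its own protease (`filter_dmso_presence()`); presence means any positive
intensity, since label-free intensities carry no natural floor. The filter
acts per peptidoform, so a site survives when any member peptide does.
Surviving intensities are summed per site and sample
(`aggregate_to_sites()`). Missing is never zero: a site-sample with no
surviving evidence is excluded from downstream fits, not imputed, and a
conservation identity (matrix totals equal retained peptide totals per
sample) is asserted on every run. Intensities are consumed as the engine
normalized them; an optional per-sample median centering is deliberately
not applied by default, to avoid double normalization.

## The dose-response model

Competition acts multiplicatively on intensity. With plateaus
$T$ (uninhibited) and $B$ (fully competed), the site intensity follows

$$ I(c) \;=\; B + \frac{T - B}{1 + (c/\mathrm{IC50})^{h}} . $$

The plotted and fitted responses are log2 intensities, whose noise is
approximately additive Gaussian when intensity noise is multiplicative
log-normal. The fitted mean function is therefore the intensity-scale
four-parameter logistic *viewed through log2*:

$$ y(c) \;=\; \log_2\!\bigl( 2^{\text{bottom}} + (2^{\text{top}} -
2^{\text{bottom}})\,/\,(1 + (c/\mathrm{IC50})^{h}) \bigr), $$

with $\text{top} = \log_2 T$, $\text{bottom} = \log_2 B$. Fitting a plain
logistic directly in log2 space is tempting (it is what generic curve-fit
software does when handed log-scale values) but subtly shifts the
inflection: its midpoint sits where the *log* signal is halfway down, which
for a site with a $\Delta$ log2-unit dynamic range overestimates the
half-intensity concentration by a factor $2^{\Delta/(2h)}$ — about 2.8-fold
for a typical 3-unit drop. Keeping the model on the intensity scale
preserves the standard meaning of IC50 (the concentration halving the
background-subtracted signal) and removes that bias.

Numerical details:

* The model is evaluated in concentration space, so the DMSO control
  (dose 0) participates directly and evaluates to `top` exactly — no
  pseudo-dose for zero is needed.
* IC50 is parameterized as $\log_{10}$ IC50; the Wald interval on that
  scale, scaled by residual variance with $n-4$ degrees of freedom, is
  back-transformed to nM, which is why intervals are asymmetric (e.g. a
  17 nM estimate with a 10–28 nM interval).
* Hill slope is free within [0.1, 10], matching the variable-slope
  convention of standard dose-response software.
* Optimization is Levenberg–Marquardt with box bounds and a deterministic
  multi-start: plateau starts from the mean responses at the extreme doses,
  $\log_{10}$ IC50 started at every tested positive dose. Near-flat series
  make the Jacobian singular when both plateau starts coincide, so each
  start is retried with a separated bottom; if every start fails, a
  derivative-free Nelder–Mead fallback runs and the fit is flagged
  `covariance unavailable` instead of being silently accepted.
* At least 4 distinct dose levels with data are required; perfectly flat
  series are called stable outright with IC50 undefined.

## The competed / stable / ambiguous call

The published analyses report which sites are competed without printing a
numeric rule, so the rule here is this package's own definition: a site is
**competed** when (i) the 4PL beats a constant model in an
extra-sum-of-squares F-test at p < 0.05, (ii) the fitted dynamic range is
at least 1 log2 unit, and (iii) the IC50 lies within
[min positive dose / 10, max dose × 10]. It is **stable** when the F-test
is not significant, and **ambiguous** otherwise (significant but shallow,
or out of range). IC50s outside the tested ladder are reported but flagged
extrapolated. The 1-log2 floor keeps twofold-scale wobble from being called
engagement; the F-test threshold makes the stable-call specificity
approximately its nominal 95%.

## What the synthetic generator emulates — and what it does not

`generate_proteome()`, `plant_labeled_sites()` and
`simulate_quant_tables()` build a fully known ground truth:

* design: 7 inhibitor doses on a half-log ladder (1, 3.16, 10, 31.6, 100,
  316, 1000 nM) plus DMSO, triplicates, trypsin and pepsin in parallel —
  the published design, with the exact ladder a configurable stand-in
  since only its shape is public;
* 100 planted K/Y sites by default, some proteins carrying several sites,
  two host proteins duplicated into homolog copies so their peptides are
  shared and exercise multi-protein grouping;
* each site covered by rule-valid tryptic and arbitrary-boundary peptic
  peptides; peptidoform base intensities log-uniform over three orders of
  magnitude (1e6–1e9);
* competed sites (10% by default) with IC50 log-uniform over 3.16–316 nM
  (the interior of the ladder), Hill slopes 0.8–1.5, and true dynamic
  ranges of 2–4 log2 units; competition applied multiplicatively on
  intensity;
* noise: multiplicative log-normal at 20% CV
  ($\sigma = \sqrt{\ln(1+\mathrm{CV}^2)}$), per-sample run-effect scale
  factors (sd 0.05, natural log), and 5% missing-at-random entries written
  as zeros, the convention the parser maps back to missing.

These defaults are what a triplicate label-free competition experiment
plausibly looks like after engine-level normalization. The generator does
*not* emulate: intensity-dependent missingness (available as an option but
off by default), interference/co-isolation artifacts, retention-time drift,
mis-localized probe positions, or FDR-level identification errors — the
search itself is upstream of this package. Passing recovery tests therefore
demonstrates the pipeline's correctness and statistical calibration under a
faithful noise model, not robustness to pathologies the simulator does not
contain.

## Validation results the package computes about itself

The test suite and `scripts/acceptance.R` recompute, at run time: exact
agreement of localization and digestion with naive brute-force oracles;
mass conservation of the site matrix; exact brute-force agreement of the
DMSO-presence rule; noise-free 4PL recovery to 1e-6 relative on all four
parameters; and, at the triplicate 20% CV design with 100 sites (10
competed), median $|\Delta\log_{10}\mathrm{IC50}|$ around 0.1, competed
sensitivity ≥ 0.9, stable specificity ≥ 0.95, and empirical 95%-CI coverage
around 0.93 over 1,000 Monte-Carlo fits. Problem sizes (50-protein
proteomes, 100 sites, 500–1,000 resampling draws) were chosen so the whole
suite runs in a few minutes on a laptop while keeping the binomial error of
the estimated rates small relative to their acceptance margins.

Two checks require inputs that are not distributed with the package: the
worked-example residue mappings need the canonical UniProt sequences
(`inst/extdata/uniprot/README.txt`), and the full-scale IC50 benchmark
needs the deposited study's processed tables
(`inst/extdata/external/README.txt`). The corresponding acceptance tests
fail until those files are supplied, by design — they are external-data
checks, not simulations.

## Known limitations

* Residue numbering assumes the canonical isoform of each protein; sites
  on unrepresented isoforms are not defined.
* Semi-specific tryptic peptides are not modeled: a peptide either passes
  the fully specific rule or is handled by the nonspecific substring path.
* No probabilistic localization scoring: the probe position is taken from
  the search output as given.
* Fits are independent per site and protease; no shared-plateau or global
  model, and no pooling across proteases (parallel digests are treated as
  independent replications of the measurement, which is also what makes
  their agreement informative).
* With triplicates and a free Hill slope, sites whose true IC50 sits at
  the edge of the dose ladder carry wide intervals, and occasionally the
  global least-squares optimum is a steep step between adjacent doses
  (Hill at its bound). These fits are flagged, and their intervals are
  honest about the uncertainty.

## A minimal session

```{r example, eval = FALSE}
proteome <- generate_proteome(50, seed = 1)
manifest <- plant_labeled_sites(proteome, n_sites = 100,
                                competed_fraction = 0.1, seed = 2)
sim <- simulate_quant_tables(manifest, seed = 3)
res <- run_pipeline(manifest$index, sim$tables, sim$annotation)

head(res$fits[res$fits$call == "competed",
              c("site_id", "protease", "ic50_nM", "ci_low_nM",
                "ci_high_nM", "hill")])
recovery_report(res$fits, res$groups, manifest)
```
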