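# abppsites

Site-centric analysis of **competitive activity-based protein profiling
(ABPP)** experiments for kinase-inhibitor target engagement.

Covalent pan-kinase probes label ATP-pocket lysines (and tyrosines) in live
cells; pre-treatment with an inhibitor suppresses labeling at the sites the
inhibitor engages, in a dose-dependent way. After enrichment, LC-MS and a
database search, the evidence arrives as per-protease tables of
probe-modified peptidoforms with label-free intensities across samples
(seven inhibitor doses plus a DMSO control, in triplicate, digested in
parallel with trypsin and with pepsin). `abppsites` turns those tables into
residue-resolved pharmacology:

1. **Localization** — peptides are matched to exact positions in the
   proteome (`locate_peptide()`, exact substring search, so nonspecific
   peptic peptides work; `digest()` models the specific tryptic rule:
   cleavage after K/R, ≤ 2 missed cleavages, length 5–30), and the probe
   position inside the peptide becomes a protein residue number.
2. **Site grouping** — peptidoforms sharing a modified (protein, residue)
   form one binding-site group; a peptide matching several homologous
   proteins forms a single multi-protein group (`cluster_to_sites()`).
3. **Filtering & aggregation** — peptidoforms must be present in ≥ 2 DMSO
   replicates of their protease (`filter_dmso_presence()`); survivors are
   summed into a site × sample matrix (`aggregate_to_sites()`).
4. **Dose-response** — per site and protease, a four-parameter logistic
   competition model is fitted to the log2 intensities
   (`fit_4pl()`, `fit_all_sites()`):

   `I(c) = B + (T − B) / (1 + (c / IC50)^h)`

   fitted on the log2 scale as
   `y(c) = log2(2^bottom + (2^top − 2^bottom) / (1 + (c/IC50)^h))`,
   with IC50 parameterized as log10(IC50), a free Hill slope `h` in
   [0.1, 10], and dose 0 (DMSO) anchoring the `top` plateau exactly. The
   95% CI on log10(IC50) is back-transformed, giving the familiar
   asymmetric intervals in nM. Sites are called **competed** (4PL beats a
   constant model at p < 0.05, fitted drop ≥ 1 log2 unit, IC50 in range),
   **stable**, or **ambiguous**.

A synthetic-data module (`generate_proteome()`, `plant_labeled_sites()`,
`simulate_quant_tables()`, `recovery_report()`) builds complete experiments
with known ground truth, so every stage is testable without any download.

## Worked example

```r
library(abppsites)

proteome <- generate_proteome(50, seed = 1)
manifest <- plant_labeled_sites(proteome, n_sites = 100,
                                competed_fraction = 0.1, seed = 2)
sim <- simulate_quant_tables(manifest, seed = 3)

res <- run_pipeline(manifest$index, sim$tables, sim$annotation)
subset(res$fits, call == "competed",
       c(site_id, protease, ic50_nM, ci_low_nM, ci_high_nM, hill))[4:6, ]
```

```
        site_id protease ic50_nM ci_low_nM ci_high_nM  hill
35 SYNG0008;K47   pepsin  368.63      0.00        Inf 10.00
39 SYNG0008;K52   pepsin    8.99      5.63       14.3  1.77
40 SYNG0008;K52  trypsin   12.80      8.39       19.5  1.50
```

`SYNG0008;K52` was planted with a true IC50 of 8.5 nM: both proteases
recover it independently (9.0 and 12.8 nM) with overlapping intervals —
the dual-protease agreement that makes site-level calls trustworthy.
`SYNG0008;K47` is a planted *stable* site that slips past the F-test at
p = 0.048; its unbounded interval and Hill slope at the bound are the
flags that give such calls away. Against the full truth manifest:

```r
recovery_report(res$fits, res$groups, manifest)
```

```
$mapping_precision      1
$mapping_recall         1
$ic50_median_abs_dlog10 0.127
$sensitivity            0.9
$specificity            0.972
$ci_coverage            0.9
```

Every planted (protein, residue) site is recovered exactly; IC50s of truly
competed sites are estimated to about 0.13 log10 units (≈ 1.3-fold) at the
triplicate 20% CV design, with 18 of 20 site × protease calls sensitive and
97% of stable sites correctly left uncalled.

The per-protease complementarity view (`res$overlap`) and the heatmap-style
per-condition mean table (`export_heatmap_table()`) reproduce the standard
reporting formats of dual-protease site-profiling studies.

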