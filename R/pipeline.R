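## End-to-end convenience wrapper: quantification tables -> site groups ->
## filtered site matrix -> condition means -> per-site competition fits.

#' Run the site-centric competitive ABPP pipeline
#'
#' Chains the full analysis for one experiment: parse each per-protease
#' modified-peptide table, localize probe sites and cluster peptides into
#' binding-site groups, apply the DMSO replicate-presence filter, sum
#' intensities to the site-by-sample matrix, compute per-condition means,
#' and fit a four-parameter competition curve per site and protease.
#'
#' @param index A `ProteomeIndex`.
#' @param tables Named list (names = protease labels) of quantification
#'   tables: paths or data.frames in the modified-peptide dialect.
#' @param annotation Sample annotation (path or data.frame, see
#'   [read_sample_annotation()]).
#' @param mod Probe [modification_spec()].
#' @param kinases Optional `KinaseAnnotation`.
#' @param min_present DMSO replicate-presence threshold.
#' @param p_threshold,min_drop Competed-call thresholds, see
#'   [classify_site()].
#' @return list with `pset` (combined, unfiltered), `pset_filtered`,
#'   `groups`, `sqm`, `cond_means`, `fits`, `merged` (site table with
#'   per-protease detection flags), `overlap`, and `kinase_summary` when a
#'   kinase annotation is supplied.
#' @export
run_pipeline <- function(index, tables, annotation,
                         mod = modification_spec(), kinases = NULL,
                         min_present = 2L, p_threshold = 0.05,
                         min_drop = 1) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  if (is.character(annotation) || is.data.frame(annotation)) {
    annotation <- read_sample_annotation(annotation)
  }
  psets <- lapply(names(tables), function(p)
    parse_quant_table(tables[[p]], annotation, protease = p, mod = mod))
  pset <- combine_peptide_sets(psets)
  groups <- cluster_to_sites(pset, index)
  pset_f <- filter_dmso_presence(pset, annotation, min_present = min_present)
  sqm <- aggregate_to_sites(pset_f, groups, annotation)
  cond_means <- summarize_condition_means(sqm)
  fits <- fit_all_sites(sqm, p_threshold = p_threshold, min_drop = min_drop)

  ## per-protease detection flags + complementarity counts
  merged <- sqm$sites
  prot_names <- sort(names(tables), method = "radix")
  site_sets <- list()
  for (p in prot_names) {
    asg <- groups$assignment[groups$assignment$protease == p &
                               groups$assignment$pep_id %in%
                                 pset_f$peptides$pep_id, , drop = FALSE]
    detected <- merged$site_key %in% asg$site_key
    merged[[paste0("detected_", p)]] <- detected
    site_sets[[p]] <- merged$site_key[detected]
  }
  overlap <- if (length(site_sets) >= 2L) overlap_counts(site_sets) else NULL

  out <- list(pset = pset, pset_filtered = pset_f, groups = groups,
              sqm = sqm, cond_means = cond_means, fits = fits,
              merged = merged, overlap = overlap)
  if (!is.null(kinases)) {
    ann_k <- annotate_kinases(merged, groups$members, kinases)
    out$merged <- ann_k$sites
    out$kinase_summary <- ann_k$summary
  }
  out
}
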