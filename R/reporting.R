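## Reporting: protease complementarity counts, kinase annotation, and the
## heatmap-style condition-mean export.

#' Read a kinase annotation table
#'
#' TSV with columns `accession`, `gene` and optionally `group` (kinase family
#' label). Any accession absent from the table is treated as not a kinase.
#'
#' @param x Path to a TSV file, or a data.frame.
#' @return A `KinaseAnnotation` data.frame.
#' @export
read_kinase_annotation <- function(x) {
  ann <- if (is.character(x)) {
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  if (!"accession" %in% names(ann)) {
    stop("kinase annotation needs an 'accession' column")
  }
  if (!"group" %in% names(ann)) ann$group <- ""
  if (!"gene" %in% names(ann)) ann$gene <- ""
  class(ann) <- c("KinaseAnnotation", "data.frame")
  ann
}

#' Is an accession a protein kinase?
#' @param accession Character vector of accessions.
#' @param kinases A `KinaseAnnotation` (or NULL: everything is not-kinase).
#' @return Logical vector.
#' @export
is_kinase <- function(accession, kinases) {
  if (is.null(kinases)) return(rep(FALSE, length(accession)))
  accession %in% kinases$accession
}

#' Per-protease site overlap counts
#'
#' Given one site-key set per protease, tabulates per-protease totals,
#' exclusive counts, the pairwise intersection, and the union — the
#' complementarity summary behind dual-protease Venn counts. The identity
#' |A| + |B| - |A n B| = |A u B| is asserted.
#'
#' @param site_sets Named list of character vectors of site keys (typically
#'   2 proteases; any number is accepted).
#' @return For two sets, a one-row data.frame with `n_<name>`,
#'   `excl_<name>`, `overlap`, `union`; for more, the pairwise table.
#' @export
overlap_counts <- function(site_sets) {
  stopifnot(is.list(site_sets), length(site_sets) >= 1L,
            !is.null(names(site_sets)))
  site_sets <- lapply(site_sets, unique)
  nm <- names(site_sets)
  pairs <- if (length(nm) == 1L) {
    data.frame(a = nm, b = nm, stringsAsFactors = FALSE)
  } else {
    idx <- utils::combn(length(nm), 2)
    data.frame(a = nm[idx[1, ]], b = nm[idx[2, ]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    A <- site_sets[[pairs$a[i]]]; B <- site_sets[[pairs$b[i]]]
    ov <- length(intersect(A, B)); un <- length(union(A, B))
    stopifnot(length(A) + length(B) - ov == un ||
                pairs$a[i] == pairs$b[i])
    data.frame(set_a = pairs$a[i], set_b = pairs$b[i],
               n_a = length(A), n_b = length(B),
               excl_a = length(setdiff(A, B)), excl_b = length(setdiff(B, A)),
               overlap = ov, union = un, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate sites with kinase membership and count distinct proteins
#'
#' Adds an `is_kinase` flag to the merged site table (a shared site is
#' kinase-flagged when any member accession is a kinase). Shared sites count
#' once in site tallies but expand to all their member accessions for the
#' distinct-protein tallies, each accession counted once.
#'
#' @param merged Merged site table from [merge_protease_runs()].
#' @param members Member table (`SiteGroups$members`, or row-bound members
#'   from several runs).
#' @param kinases A `KinaseAnnotation` or NULL.
#' @return list with `sites` (annotated table) and `summary` (n_sites,
#'   n_kinase_sites, n_distinct_proteins, n_distinct_kinases).
#' @export
annotate_kinases <- function(merged, members, kinases = NULL) {
  members <- members[members$site_key %in% merged$site_key, , drop = FALSE]
  kin_by_site <- vapply(merged$site_key, function(k) {
    any(is_kinase(members$accession[members$site_key == k], kinases))
  }, logical(1))
  merged$is_kinase <- unname(kin_by_site)
  accs <- unique(members$accession)
  kin_accs <- accs[is_kinase(accs, kinases)]
  list(
    sites = merged,
    summary = list(
      n_sites = nrow(merged),
      n_kinase_sites = sum(merged$is_kinase),
      n_distinct_proteins = length(accs),
      n_distinct_kinases = length(kin_accs)
    )
  )
}

#' Export the condition-mean heatmap table
#'
#' Pivots the per-condition mean log2 intensities of one protease into a
#' sites x conditions table (DMSO first, then ascending dose), with `"ND"`
#' for cells without signal. Row order is deterministic: kinase sites first,
#' then alphabetical by site id.
#'
#' @param cond_means Output of [summarize_condition_means()].
#' @param protease Which protease's columns to export.
#' @param sites Site table carrying `site_key`, `site_id` and (optionally)
#'   `is_kinase`.
#' @param path Optional TSV output path.
#' @return The exported data.frame (invisibly when `path` is given).
#' @export
export_heatmap_table <- function(cond_means, protease, sites, path = NULL) {
  cm <- cond_means[cond_means$protease == protease, , drop = FALSE]
  if (nrow(cm) == 0L) stop("no condition means for protease '", protease, "'")
  doses <- sort(unique(cm$dose))
  labels <- vapply(doses, function(d) {
    if (d == 0) "DMSO" else format(d, trim = TRUE, scientific = FALSE)
  }, character(1))
  keys <- unique(cm$site_key)
  info <- sites[match(keys, sites$site_key), , drop = FALSE]
  kin <- if ("is_kinase" %in% names(info)) info$is_kinase else
    rep(FALSE, length(keys))
  kin[is.na(kin)] <- FALSE
  ids <- ifelse(is.na(info$site_id), keys, info$site_id)
  o <- order(!kin, ids, method = "radix")
  keys <- keys[o]; ids <- ids[o]; kin <- kin[o]
  wide <- matrix("ND", length(keys), length(doses),
                 dimnames = list(NULL, labels))
  for (j in seq_along(doses)) {
    sub <- cm[cm$dose == doses[j], , drop = FALSE]
    v <- sub$mean_log2[match(keys, sub$site_key)]
    has <- !is.na(v)
    wide[has, j] <- format(round(v[has], 4), trim = TRUE, scientific = FALSE)
  }
  out <- data.frame(site_id = ids, site_key = keys, is_kinase = kin,
                    wide, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export the per-site fit results table
#'
#' @param fits Results from [fit_all_sites()].
#' @param path TSV output path.
#' @return `fits`, invisibly.
#' @export
export_results_table <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fits)
}
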