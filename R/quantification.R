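## Quantification: parse per-protease modified-peptide tables, apply the
## DMSO replicate-presence filter, and sum peptide intensities into the
## site-by-sample matrix.

#' Read and validate a sample annotation table
#'
#' The annotation maps quantification columns to experimental conditions.
#' Expected TSV columns: `sample_id`, `condition` (a dose in nM, or the token
#' `DMSO` for the vehicle control), `replicate`, `protease`. A numeric `dose`
#' column is derived (DMSO = 0 nM).
#'
#' @param x Path to a TSV file, or a data.frame with those columns.
#' @return Validated annotation data.frame with an added `dose` column.
#' @export
read_sample_annotation <- function(x) {
  ann <- if (is.character(x)) {
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "replicate", "protease")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0L) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  }
  ann$sample_id <- as.character(ann$sample_id)
  ann$condition <- as.character(ann$condition)
  ann$protease <- as.character(ann$protease)
  ann$replicate <- as.integer(ann$replicate)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  key <- paste(ann$condition, ann$replicate, ann$protease)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, replicate, protease) in annotation")
  }
  dose <- ifelse(toupper(ann$condition) == "DMSO", 0,
                 suppressWarnings(as.numeric(ann$condition)))
  if (anyNA(dose)) {
    stop("condition must be a dose in nM or 'DMSO'; offending value(s): ",
         paste(unique(ann$condition[is.na(dose)]), collapse = ", "))
  }
  ann$dose <- dose
  ann
}

#' Construct a PeptideSet from parsed components
#' @keywords internal
.peptide_set <- function(peptides, intensity) {
  stopifnot(nrow(peptides) == nrow(intensity))
  rownames(intensity) <- NULL
  structure(list(peptides = peptides, intensity = intensity),
            class = "PeptideSet")
}

#' @export
print.PeptideSet <- function(x, ...) {
  cat("PeptideSet:", nrow(x$peptides), "peptidoforms x",
      ncol(x$intensity), "samples (",
      length(unique(x$peptides$protease)), "protease(s) )\n")
  invisible(x)
}

#' Parse a modified-peptide quantification table
#'
#' Reads one per-protease quantification TSV in the combined modified-peptide
#' dialect: one row per peptidoform with a peptide sequence, an assigned
#' modifications string such as `"7K(754.2532)"`, a protein accession, and
#' one intensity column per sample. Probe positions are taken from
#' modification entries whose mass matches `mod$delta_mass` within `mass_tol`
#' and whose residue is in `mod$residues`; other modifications (fixed
#' carbamidomethyl, oxidation, N-terminal acetyl) are carried but ignored for
#' site mapping. Zero intensities are recorded as missing; negative
#' intensities are rejected.
#'
#' @param x Path to a TSV file, or a data.frame.
#' @param annotation Sample annotation (see [read_sample_annotation()]).
#' @param protease Protease label of this run; its samples are selected from
#'   the annotation.
#' @param mod A [modification_spec()] describing the probe adduct.
#' @param mass_tol Mass tolerance in Da when matching the probe delta mass.
#' @param cols Optional named list overriding the column names
#'   (`peptide`, `mods`, `protein`).
#' @return A `PeptideSet`: `peptides` data.frame (`pep_id`, `peptide`,
#'   `probe_positions`, `assigned_accession`, `protease`) plus an `intensity`
#'   matrix (peptidoforms x samples of this protease). Rows whose
#'   modification string could not be parsed are dropped and reported in
#'   `attr(, "row_errors")`.
#' @export
parse_quant_table <- function(x, annotation, protease,
                              mod = modification_spec(),
                              mass_tol = 0.001, cols = NULL) {
  tab <- if (is.character(x)) {
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- list(peptide = "Peptide", mods = "Assigned Modifications",
             protein = "Protein")
  cn[names(cols)] <- cols
  miss <- setdiff(unlist(cn), names(tab))
  if (length(miss) > 0L) {
    stop("quantification table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  ann <- annotation[annotation$protease == protease, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated samples for protease '", protease, "'")
  int_cols <- vapply(ann$sample_id, function(sid) {
    if (sid %in% names(tab)) sid
    else if (paste(sid, "Intensity") %in% names(tab)) paste(sid, "Intensity")
    else NA_character_
  }, character(1))
  if (anyNA(int_cols)) {
    stop("no intensity column for annotated sample(s): ",
         paste(ann$sample_id[is.na(int_cols)], collapse = ", "))
  }
  extra <- setdiff(names(tab),
                   c(unlist(cn), int_cols, "Gene", "site", "Site"))
  ## unknown numeric columns are suspicious: likely unannotated samples
  extra_num <- extra[vapply(tab[extra], is.numeric, logical(1))]
  if (length(extra_num) > 0L) {
    stop("intensity column(s) without sample annotation: ",
         paste(extra_num, collapse = ", "))
  }
  intensity <- as.matrix(tab[, int_cols, drop = FALSE])
  colnames(intensity) <- ann$sample_id
  storage.mode(intensity) <- "double"
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("negative intensity values are not allowed")
  }
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_

  parsed <- lapply(as.character(tab[[cn$mods]]), .parse_mod_string,
                   mod = mod, mass_tol = mass_tol)
  bad <- vapply(parsed, function(p) !is.null(p$error), logical(1))
  row_errors <- if (any(bad)) {
    data.frame(row = which(bad),
               message = vapply(parsed[bad], function(p) p$error, character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(row = integer(0), message = character(0))
  peptides <- data.frame(
    pep_id = seq_len(nrow(tab)),
    peptide = toupper(as.character(tab[[cn$peptide]])),
    probe_positions = vapply(parsed, function(p)
      if (is.null(p$error)) paste(p$probe, collapse = ";") else NA_character_,
      character(1)),
    assigned_accession = as.character(tab[[cn$protein]]),
    protease = protease,
    stringsAsFactors = FALSE
  )
  ## residue-letter sanity: probe positions must sit on allowed residues
  for (i in which(!bad)) {
    for (pos in .parse_positions(peptides$probe_positions[i])) {
      if (pos < 1L || pos > nchar(peptides$peptide[i]) ||
          !(substring(peptides$peptide[i], pos, pos) %in% mod$residues)) {
        bad[i] <- TRUE
        row_errors <- rbind(row_errors, data.frame(
          row = i, message = paste0("probe position ", pos,
            " not on an allowed residue (", paste(mod$residues, collapse = "/"),
            ")"), stringsAsFactors = FALSE))
      }
    }
  }
  keep <- !bad
  out <- .peptide_set(peptides[keep, , drop = FALSE],
                      intensity[keep, , drop = FALSE])
  out$peptides$pep_id <- seq_len(nrow(out$peptides))
  attr(out, "row_errors") <- row_errors
  out
}

## parse "7K(754.2532), 3C(57.0215)" -> probe positions matching the spec
.parse_mod_string <- function(s, mod, mass_tol) {
  if (is.na(s) || !nzchar(trimws(s))) return(list(probe = integer(0)))
  entries <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  probe <- integer(0)
  for (e in entries) {
    if (grepl("^N-term\\(", e, ignore.case = TRUE)) next
    m <- regmatches(e, regexec("^([0-9]+)([A-Z])\\(([-0-9.]+)\\)$", e))[[1]]
    if (length(m) != 4L) {
      return(list(error = paste0("malformed modification entry '", e, "'")))
    }
    pos <- as.integer(m[2]); letter <- m[3]; mass <- as.numeric(m[4])
    if (is.na(mass)) {
      return(list(error = paste0("unparseable mass in '", e, "'")))
    }
    if (abs(mass - mod$delta_mass) <= mass_tol && letter %in% mod$residues) {
      probe <- c(probe, pos)
    }
  }
  list(probe = sort(unique(probe)))
}

#' Combine per-protease PeptideSets into one set
#'
#' Peptide rows are stacked; the intensity matrix is the block union of the
#' per-run matrices (a peptide observed only in the trypsin run is missing in
#' all pepsin samples, and vice versa).
#'
#' @param ... `PeptideSet` objects.
#' @return A combined `PeptideSet` with renumbered `pep_id`.
#' @export
combine_peptide_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "PeptideSet")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "PeptideSet")))
  all_samples <- unique(unlist(lapply(sets, function(s) colnames(s$intensity))))
  if (anyDuplicated(unlist(lapply(sets, function(s) colnames(s$intensity))))) {
    stop("sample ids overlap between the combined PeptideSets")
  }
  peptides <- do.call(rbind, lapply(sets, function(s) s$peptides))
  intensity <- do.call(rbind, lapply(sets, function(s) {
    m <- matrix(NA_real_, nrow(s$intensity), length(all_samples),
                dimnames = list(NULL, all_samples))
    m[, colnames(s$intensity)] <- s$intensity
    m
  }))
  peptides$pep_id <- seq_len(nrow(peptides))
  rownames(peptides) <- NULL
  .peptide_set(peptides, intensity)
}

#' Filter peptidoforms by presence in DMSO replicates
#'
#' A peptidoform is retained iff it has a non-missing (positive) intensity in
#' at least `min_present` DMSO replicates of its own protease. Presence means
#' any positive intensity; no minimum level is imposed. The filter is applied
#' per peptidoform, so a site survives when at least one member peptidoform
#' survives. Idempotent.
#'
#' @param pset A `PeptideSet`.
#' @param annotation Sample annotation.
#' @param min_present Minimum number of DMSO replicates with signal.
#' @return The filtered `PeptideSet` (pep_id values preserved).
#' @export
filter_dmso_presence <- function(pset, annotation, min_present = 2L) {
  stopifnot(inherits(pset, "PeptideSet"))
  proteases <- unique(pset$peptides$protease)
  dmso <- lapply(proteases, function(p) {
    ids <- annotation$sample_id[annotation$protease == p &
                                  annotation$dose == 0]
    ids <- intersect(ids, colnames(pset$intensity))
    if (length(ids) < 2L) {
      stop("fewer than 2 DMSO samples for protease '", p,
           "'; the replicate-presence filter requires at least 2")
    }
    ids
  })
  names(dmso) <- proteases
  keep <- vapply(seq_len(nrow(pset$peptides)), function(i) {
    ids <- dmso[[pset$peptides$protease[i]]]
    sum(!is.na(pset$intensity[i, ids])) >= min_present
  }, logical(1))
  .peptide_set(pset$peptides[keep, , drop = FALSE],
               pset$intensity[keep, , drop = FALSE])
}

#' Sum filtered peptide intensities into the site-by-sample matrix
#'
#' For every binding-site group, the intensities of its surviving member
#' peptidoforms are summed per sample (missing peptide terms contribute
#' nothing; a site-sample with no surviving evidence stays missing — missing
#' is never treated as zero downstream). A log2 layer is derived on positive
#' sums. Mass conservation — per sample, the matrix total equals the total
#' intensity of the retained assigned peptides — is asserted on every run.
#'
#' @param pset Filtered `PeptideSet`.
#' @param groups `SiteGroups` computed on the (unfiltered) parent set.
#' @param annotation Sample annotation.
#' @return A `SiteQuantMatrix`: list with `intensity` and `log2` matrices
#'   (sites x samples), `sites` (site table restricted to surviving sites)
#'   and `annotation`.
#' @export
aggregate_to_sites <- function(pset, groups, annotation) {
  stopifnot(inherits(pset, "PeptideSet"), inherits(groups, "SiteGroups"))
  asg <- groups$assignment[groups$assignment$pep_id %in% pset$peptides$pep_id, ,
                           drop = FALSE]
  site_keys <- sort(unique(asg$site_key), method = "radix")
  samples <- colnames(pset$intensity)
  intensity <- matrix(NA_real_, length(site_keys), length(samples),
                      dimnames = list(site_keys, samples))
  row_of <- match(asg$pep_id, pset$peptides$pep_id)
  for (k in seq_along(site_keys)) {
    rows <- row_of[asg$site_key == site_keys[k]]
    sub <- pset$intensity[rows, , drop = FALSE]
    sums <- colSums(sub, na.rm = TRUE)
    sums[colSums(!is.na(sub)) == 0L] <- NA_real_
    intensity[k, ] <- sums
  }
  ## conservation: per sample, matrix total == total of assigned peptide
  ## intensities (each peptide counted once per group it feeds)
  lhs <- colSums(intensity, na.rm = TRUE)
  rhs <- colSums(pset$intensity[row_of, , drop = FALSE], na.rm = TRUE)
  if (any(abs(lhs - rhs) > 1e-9 * pmax(1, abs(rhs)))) {
    stop("internal error: site-matrix mass not conserved")
  }
  log2_layer <- intensity
  log2_layer[!is.na(log2_layer) & log2_layer <= 0] <- NA_real_
  log2_layer <- log2(log2_layer)
  structure(
    list(intensity = intensity, log2 = log2_layer,
         sites = groups$sites[groups$sites$site_key %in% site_keys, ,
                              drop = FALSE],
         annotation = annotation[annotation$sample_id %in% samples, ,
                                 drop = FALSE]),
    class = "SiteQuantMatrix"
  )
}

#' @export
print.SiteQuantMatrix <- function(x, ...) {
  cat("SiteQuantMatrix:", nrow(x$intensity), "sites x",
      ncol(x$intensity), "samples\n")
  invisible(x)
}

#' Per-condition mean log2 intensities
#'
#' Averages the log2 site intensities over replicates within each
#' (site, protease, dose) cell, excluding missing values — the quantity shown
#' in dose-response heatmaps. Conditions are ordered DMSO first, then
#' ascending dose.
#'
#' @param sqm A `SiteQuantMatrix`.
#' @return Long data.frame: `site_key`, `protease`, `dose`, `condition`
#'   (display label, `"DMSO"` for dose 0), `mean_log2`, `n_obs`; `mean_log2`
#'   is `NA` when no replicate has signal.
#' @export
summarize_condition_means <- function(sqm) {
  stopifnot(inherits(sqm, "SiteQuantMatrix"))
  ann <- sqm$annotation
  combos <- unique(ann[, c("protease", "dose")])
  combos <- combos[order(combos$protease, combos$dose, method = "radix"), ,
                   drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(combos))) {
    ids <- ann$sample_id[ann$protease == combos$protease[j] &
                           ann$dose == combos$dose[j]]
    sub <- sqm$log2[, ids, drop = FALSE]
    out[[j]] <- data.frame(
      site_key = rownames(sqm$log2),
      protease = combos$protease[j],
      dose = combos$dose[j],
      condition = if (combos$dose[j] == 0) "DMSO"
                  else format(combos$dose[j], trim = TRUE, scientific = FALSE),
      mean_log2 = rowMeans(sub, na.rm = TRUE),
      n_obs = rowSums(!is.na(sub)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$mean_log2[is.nan(res$mean_log2)] <- NA_real_
  res <- res[order(res$site_key, res$protease, res$dose, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
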