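## Probe-modification site mapping: convert modified-peptide records into
## protein-residue binding-site groups and merge evidence across proteases.

#' Probe / modification specification
#'
#' Describes a variable modification by name, delta mass and the residues it
#' may occupy. The default is the pan-kinase probe phosphonate adduct
#' (754.2532 Da) on lysine and tyrosine; restrict to lysine with
#' `residues = "K"`.
#'
#' @param name Modification name.
#' @param delta_mass Monoisotopic delta mass in Da.
#' @param residues Residues the modification is allowed on.
#' @return A `ModificationSpec` list.
#' @export
modification_spec <- function(name = "probe-phosphonate",
                              delta_mass = 754.2532,
                              residues = c("K", "Y")) {
  stopifnot(delta_mass > 0, length(residues) >= 1L)
  structure(list(name = name, delta_mass = delta_mass,
                 residues = toupper(residues)),
            class = "ModificationSpec")
}

#' Map one probe-modified peptide to protein residues
#'
#' Localizes the peptide by exact substring search and translates the
#' within-peptide modification index to 1-based protein residue coordinates:
#' `residue = match_start + mod_pos - 1`. The residue letter in the protein
#' must equal the modified residue letter in the peptide; a mismatch
#' indicates an index/peptide inconsistency and is an error.
#'
#' @param peptide Peptide sequence.
#' @param mod_pos 1-based modification position within the peptide.
#' @param index A `ProteomeIndex`.
#' @param il_equivalent Treat I/L as equivalent during localization.
#' @return data.frame with columns `accession`, `residue`, `letter`
#'   (zero rows when the peptide is not found).
#' @export
map_modification_site <- function(peptide, mod_pos, index,
                                  il_equivalent = FALSE) {
  stopifnot(mod_pos >= 1L, mod_pos <= nchar(peptide))
  matches <- locate_peptide(peptide, index, il_equivalent = il_equivalent)
  if (nrow(matches) == 0L) {
    return(data.frame(accession = character(0), residue = integer(0),
                      letter = character(0), stringsAsFactors = FALSE))
  }
  residue <- matches$start + as.integer(mod_pos) - 1L
  letter <- substring(index$sequence[match(matches$accession, index$accession)],
                      residue, residue)
  pep_letter <- toupper(substring(peptide, mod_pos, mod_pos))
  if (!isTRUE(il_equivalent) && any(letter != pep_letter)) {
    stop("residue letter mismatch while mapping '", peptide, "' at position ",
         mod_pos, ": index/peptide inconsistency")
  }
  data.frame(accession = matches$accession, residue = residue,
             letter = letter, stringsAsFactors = FALSE)
}

.site_key <- function(accession, residue) {
  paste(sort(paste0(accession, ":", residue), method = "radix"),
        collapse = "+")
}

.site_label <- function(accession, residue, letter, index) {
  gene <- index$gene[match(accession, index$accession)]
  gene[is.na(gene) | !nzchar(gene)] <- accession[is.na(gene) | !nzchar(gene)]
  o <- order(accession, method = "radix")
  paste(paste0(gene[o], ";", letter[o], residue[o]), collapse = "|")
}

#' Cluster probe-modified peptides into binding-site groups
#'
#' Peptides whose modified residue resolves to the same (accession, residue)
#' form one group. A shared peptide (matching several homologous proteins)
#' forms a single multi-protein group keyed by its full sorted member set,
#' mirroring joint reporting of homologous ATP-pocket sites. Each
#' peptidoform/probe-position pair belongs to exactly one group; a peptide
#' carrying two probe modifications contributes its full intensity to both
#' sites' groups and is flagged.
#'
#' Peptides that cannot be localized are returned in the `unmapped` report,
#' never silently dropped. When the search engine's assigned accession is
#' absent from the localization result, localization wins and the conflict is
#' logged in `conflicts`.
#'
#' @param pset A `PeptideSet` (see [parse_quant_table()]).
#' @param index A `ProteomeIndex`.
#' @param il_equivalent Treat I/L as equivalent during localization.
#' @return A `SiteGroups` object: list with `sites`, `members`, `assignment`,
#'   `unmapped` and `conflicts` data.frames.
#' @export
cluster_to_sites <- function(pset, index, il_equivalent = FALSE) {
  stopifnot(inherits(pset, "PeptideSet"), inherits(index, "ProteomeIndex"))
  pep <- pset$peptides
  assign_rows <- list(); member_rows <- list()
  unmapped <- list(); conflicts <- list()
  ## localization cache: identical peptidoform sequences map identically
  loc_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pep))) {
    positions <- .parse_positions(pep$probe_positions[i])
    if (length(positions) == 0L) next
    multi <- length(positions) > 1L
    for (pos in positions) {
      key <- paste0(pep$peptide[i], "@", pos)
      mem <- if (!is.null(loc_cache[[key]])) loc_cache[[key]] else {
        m <- map_modification_site(pep$peptide[i], pos, index,
                                   il_equivalent = il_equivalent)
        loc_cache[[key]] <- m
        m
      }
      if (nrow(mem) == 0L) {
        unmapped[[length(unmapped) + 1L]] <- data.frame(
          pep_id = pep$pep_id[i], peptide = pep$peptide[i], mod_pos = pos,
          reason = "no exact match in proteome", stringsAsFactors = FALSE)
        next
      }
      sk <- .site_key(mem$accession, mem$residue)
      assigned <- pep$assigned_accession[i]
      if (nzchar(assigned) && !(assigned %in% mem$accession)) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          pep_id = pep$pep_id[i], peptide = pep$peptide[i],
          assigned_accession = assigned,
          localized_accessions = paste(mem$accession, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        pep_id = pep$pep_id[i], site_key = sk, protease = pep$protease[i],
        multi_mod = multi, stringsAsFactors = FALSE)
      member_rows[[sk]] <- mem
    }
  }
  assignment <- .bind_or_empty(assign_rows,
    data.frame(pep_id = integer(0), site_key = character(0),
               protease = character(0), multi_mod = logical(0)))
  members <- .members_table(member_rows, index)
  sites <- .sites_table(members, assignment, index)
  structure(
    list(sites = sites, members = members, assignment = assignment,
         unmapped = .bind_or_empty(unmapped,
           data.frame(pep_id = integer(0), peptide = character(0),
                      mod_pos = integer(0), reason = character(0))),
         conflicts = .bind_or_empty(conflicts,
           data.frame(pep_id = integer(0), peptide = character(0),
                      assigned_accession = character(0),
                      localized_accessions = character(0)))),
    class = "SiteGroups"
  )
}

.parse_positions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

.bind_or_empty <- function(rows, empty) {
  if (length(rows) == 0L) empty else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
}

.members_table <- function(member_rows, index) {
  if (length(member_rows) == 0L) {
    return(data.frame(site_key = character(0), accession = character(0),
                      residue = integer(0), letter = character(0),
                      stringsAsFactors = FALSE))
  }
  keys <- sort(names(member_rows), method = "radix")
  out <- do.call(rbind, lapply(keys, function(k) {
    mem <- member_rows[[k]]
    o <- order(mem$accession, mem$residue, method = "radix")
    data.frame(site_key = k, accession = mem$accession[o],
               residue = mem$residue[o], letter = mem$letter[o],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.sites_table <- function(members, assignment, index) {
  keys <- unique(members$site_key)
  if (length(keys) == 0L) {
    return(data.frame(site_key = character(0), site_id = character(0),
                      unique = logical(0), n_members = integer(0),
                      n_peptides = integer(0), proteases = character(0),
                      multi_mod = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(keys, function(k) {
    mem <- members[members$site_key == k, , drop = FALSE]
    asg <- assignment[assignment$site_key == k, , drop = FALSE]
    data.frame(
      site_key = k,
      site_id = .site_label(mem$accession, mem$residue, mem$letter, index),
      unique = length(unique(mem$accession)) == 1L,
      n_members = nrow(mem),
      n_peptides = length(unique(asg$pep_id)),
      proteases = paste(sort(unique(asg$protease), method = "radix"),
                        collapse = ";"),
      multi_mod = any(asg$multi_mod),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site_key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.SiteGroups <- function(x, ...) {
  cat("SiteGroups:", nrow(x$sites), "sites (",
      sum(!x$sites$unique), "shared ),",
      nrow(x$assignment), "peptide assignments,",
      nrow(x$unmapped), "unmapped\n")
  invisible(x)
}

#' Merge site groups detected by different proteases
#'
#' Takes one `SiteGroups` per protease run and returns the union of site
#' keys with per-protease detection flags. Quantification stays per protease
#' (curve fits are never pooled across proteases); merging is used for
#' complementarity reporting.
#'
#' @param group_list Named list of `SiteGroups` objects; names are the
#'   protease labels.
#' @return data.frame with `site_key`, `site_id`, `unique`, `n_members` and
#'   one logical `detected_<protease>` column per run.
#' @export
merge_protease_runs <- function(group_list) {
  stopifnot(is.list(group_list), length(group_list) >= 1L,
            !is.null(names(group_list)), all(nzchar(names(group_list))))
  all_sites <- do.call(rbind, lapply(group_list, function(g)
    g$sites[, c("site_key", "site_id", "unique", "n_members")]))
  merged <- all_sites[!duplicated(all_sites$site_key), , drop = FALSE]
  merged <- merged[order(merged$site_key, method = "radix"), , drop = FALSE]
  for (prot in names(group_list)) {
    merged[[paste0("detected_", prot)]] <-
      merged$site_key %in% group_list[[prot]]$sites$site_key
  }
  rownames(merged) <- NULL
  merged
}
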