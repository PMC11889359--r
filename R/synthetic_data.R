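## Synthetic competitive-ABPP experiments with known ground truth: toy
## proteomes, planted probe-labeled sites, and simulated per-protease
## quantification tables. Used for end-to-end validation and the
## parameter-recovery benchmark.

## approximate vertebrate proteome residue frequencies; every residue class
## needed by the tryptic (K/R) and chymotryptic (F/L/Y/W) rules is abundant
.AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
  W = 0.012, Y = 0.027)

#' Generate a random toy proteome
#'
#' Sequences are drawn i.i.d. from realistic residue frequencies, so both
#' tryptic (K/R) and chymotryptic/peptic-relevant residues occur at natural
#' densities. Fully reproducible from the seed.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (residues).
#' @param kinase_fraction Fraction of proteins flagged as kinases in the
#'   manifest (used by the reporting tests).
#' @param seed RNG seed.
#' @return A `SyntheticProteome`: list with `proteins` (data.frame:
#'   `accession`, `gene`, `sequence`, `is_kinase`) and `seed`.
#' @export
generate_proteome <- function(n_proteins = 50, length_range = c(150, 400),
                              kinase_fraction = 0.3, seed = 1) {
  stopifnot(n_proteins >= 1)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(.AA_FREQ), L, replace = TRUE, prob = .AA_FREQ),
          collapse = "")
  }, character(1))
  kin <- rep(FALSE, n_proteins)
  kin[sample.int(n_proteins, round(n_proteins * kinase_fraction))] <- TRUE
  structure(
    list(proteins = data.frame(
           accession = sprintf("SYNP%04d", seq_len(n_proteins)),
           gene = sprintf("SYNG%04d", seq_len(n_proteins)),
           sequence = seqs, is_kinase = kin, stringsAsFactors = FALSE),
         seed = seed),
    class = "SyntheticProteome")
}

#' Write a synthetic proteome as FASTA
#'
#' UniProt-style headers (`>sp|ACC|ACC_SYN GN=GENE`), 60-column wrapping,
#' byte-deterministic.
#'
#' @param proteome A `SyntheticProteome` (or its `proteins` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  df <- if (inherits(proteome, "SyntheticProteome")) proteome$proteins
        else proteome
  lines <- unlist(lapply(seq_len(nrow(df)), function(i) {
    s <- df$sequence[i]
    chunks <- substring(s, seq(1, nchar(s), 60),
                        pmin(seq(1, nchar(s), 60) + 59, nchar(s)))
    c(sprintf(">sp|%s|%s_SYN GN=%s", df$accession[i], df$accession[i],
              df$gene[i]), chunks)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Proteome index of a synthetic proteome
#' @param proteome A `SyntheticProteome`.
#' @return A `ProteomeIndex`.
#' @export
proteome_index <- function(proteome) {
  df <- if (inherits(proteome, "SyntheticProteome")) proteome$proteins
        else proteome
  build_proteome_index(df$accession, df$sequence, df$gene)
}

#' Plant probe-labeled binding sites with known competition truth
#'
#' Chooses lysine (mostly) and tyrosine residues across the proteome as
#' probe-binding sites; some proteins receive two or more sites, and
#' `n_homolog_pairs` host proteins are duplicated into homolog copies so
#' their peptides become shared (nonunique) and exercise multi-protein site
#' groups. Every site gets at least one rule-valid tryptic peptide and at
#' least one arbitrary-boundary peptic peptide covering the residue. A
#' `competed_fraction` of the sites receive a finite true IC50 (log-uniform
#' over `ic50_range`), a Hill slope and a log2 dynamic range; the rest are
#' stable.
#'
#' @param proteome A `SyntheticProteome` from [generate_proteome()].
#' @param n_sites Number of planted sites.
#' @param competed_fraction Fraction of sites with true competition.
#' @param ic50_range True IC50 range in nM (log-uniform sampling).
#' @param hill_range True Hill-slope range.
#' @param drop_range_log2 True log2 dynamic-range (top minus bottom) range.
#' @param tyrosine_fraction Fraction of sites planted on Y instead of K.
#' @param n_homolog_pairs Host proteins duplicated to create shared peptides.
#' @param seed RNG seed.
#' @return A `TruthManifest`: list with `index` (ProteomeIndex including
#'   homolog copies), `proteins`, `sites`, `peptides` (the per-protease
#'   peptide plan), `design` and `noise` defaults.
#' @export
plant_labeled_sites <- function(proteome, n_sites = 100,
                                competed_fraction = 0.1,
                                ic50_range = c(3.16, 316),
                                hill_range = c(0.8, 1.5),
                                drop_range_log2 = c(2, 4),
                                tyrosine_fraction = 0.2,
                                n_homolog_pairs = 2,
                                seed = 1) {
  stopifnot(inherits(proteome, "SyntheticProteome"), n_sites >= 1)
  set.seed(seed)
  prot <- proteome$proteins
  rule <- digest_rule("trypsin")
  digests <- lapply(seq_len(nrow(prot)), function(i)
    digest(prot$sequence[i], rule, accession = prot$accession[i]))
  names(digests) <- prot$accession

  ## candidate residues per protein: K/Y positions covered by >=1 valid
  ## tryptic peptide
  candidates <- lapply(seq_len(nrow(prot)), function(i) {
    chars <- strsplit(prot$sequence[i], "")[[1]]
    pos <- which(chars %in% c("K", "Y"))
    dg <- digests[[i]]
    covered <- pos[vapply(pos, function(p)
      any(dg$start <= p & dg$end >= p), logical(1))]
    covered
  })
  avail <- vapply(candidates, length, integer(1))
  if (sum(avail) < n_sites) {
    stop("insufficient K/Y residues with tryptic coverage to plant ",
         n_sites, " sites")
  }

  ## allocate sites to host proteins (cap 3 per protein so several proteins
  ## carry multiple sites, like multiply-labeled kinases)
  hosts <- integer(0)
  pool <- rep(seq_len(nrow(prot)), pmin(avail, 3L))
  hosts <- sample(pool, n_sites)
  site_rows <- list()
  used <- vector("list", nrow(prot))
  for (s in seq_len(n_sites)) {
    i <- hosts[s]
    cand <- setdiff(candidates[[i]], used[[i]])
    chars <- strsplit(prot$sequence[i], "")[[1]]
    want_y <- stats::runif(1) < tyrosine_fraction
    cand_pref <- cand[chars[cand] == if (want_y) "Y" else "K"]
    if (length(cand_pref) == 0L) cand_pref <- cand
    if (length(cand_pref) == 0L) stop("ran out of candidate residues")
    res <- if (length(cand_pref) == 1L) cand_pref else sample(cand_pref, 1)
    used[[i]] <- c(used[[i]], res)
    site_rows[[s]] <- data.frame(
      site_uid = s, accession = prot$accession[i], residue = res,
      letter = chars[res], stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)

  ## duplicate some single-site hosts into homolog copies -> shared peptides
  single_hosts <- names(which(table(sites$accession) == 1L))
  n_dup <- min(n_homolog_pairs, length(single_hosts))
  dup_acc <- if (n_dup > 0) sample(single_hosts, n_dup) else character(0)
  sites$homolog_accession <- NA_character_
  proteins <- prot
  for (acc in dup_acc) {
    i <- match(acc, prot$accession)
    hacc <- paste0(acc, "H")
    proteins <- rbind(proteins, data.frame(
      accession = hacc, gene = paste0(prot$gene[i], "H"),
      sequence = prot$sequence[i], is_kinase = prot$is_kinase[i],
      stringsAsFactors = FALSE))
    sites$homolog_accession[sites$accession == acc] <- hacc
  }

  ## competition truth
  n_comp <- round(n_sites * competed_fraction)
  comp_idx <- if (n_comp > 0) sample.int(n_sites, n_comp) else integer(0)
  sites$competed <- seq_len(n_sites) %in% comp_idx
  sites$true_ic50 <- NA_real_
  sites$true_hill <- NA_real_
  sites$true_drop_log2 <- 0
  if (n_comp > 0) {
    sites$true_ic50[comp_idx] <-
      10^stats::runif(n_comp, log10(ic50_range[1]), log10(ic50_range[2]))
    sites$true_hill[comp_idx] <-
      stats::runif(n_comp, hill_range[1], hill_range[2])
    sites$true_drop_log2[comp_idx] <-
      stats::runif(n_comp, drop_range_log2[1], drop_range_log2[2])
  }
  sites$true_bottom_frac <- 2^(-sites$true_drop_log2)

  ## peptide plan: >=1 tryptic + >=1 peptic peptide per site
  pep_rows <- list()
  for (s in seq_len(n_sites)) {
    acc <- sites$accession[s]; res <- sites$residue[s]
    seqlen <- nchar(prot$sequence[match(acc, prot$accession)])
    dg <- digests[[acc]]
    cover <- dg[dg$start <= res & dg$end >= res, , drop = FALSE]
    n_tryp <- min(nrow(cover), sample(1:2, 1))
    pick <- cover[sample.int(nrow(cover), n_tryp), , drop = FALSE]
    for (t in seq_len(nrow(pick))) {
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        site_uid = s, protease = "trypsin", peptide = pick$peptide[t],
        mod_pos = res - pick$start[t] + 1L, accession = acc,
        stringsAsFactors = FALSE)
    }
    n_pep <- sample(1:2, 1)
    starts_seen <- integer(0)
    for (q in seq_len(n_pep)) {
      for (try in 1:20) {
        L <- sample(6:14, 1)
        offset <- sample.int(L, 1) - 1L
        st <- res - offset
        en <- st + L - 1L
        if (st >= 1L && en <= seqlen && !(st %in% starts_seen)) break
      }
      if (st < 1L || en > seqlen) { st <- max(1L, res - 4L); en <- min(seqlen, st + 8L) }
      starts_seen <- c(starts_seen, st)
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        site_uid = s, protease = "pepsin",
        peptide = substring(prot$sequence[match(acc, prot$accession)], st, en),
        mod_pos = res - st + 1L, accession = acc, stringsAsFactors = FALSE)
    }
  }
  peptides <- do.call(rbind, pep_rows)
  ## drop accidental duplicate peptidoforms across sites
  peptides <- peptides[!duplicated(peptides[, c("protease", "peptide",
                                                "mod_pos")]), , drop = FALSE]
  rownames(peptides) <- NULL

  manifest <- structure(
    list(proteins = proteins,
         index = build_proteome_index(proteins$accession, proteins$sequence,
                                      proteins$gene),
         sites = sites, peptides = peptides,
         design = list(doses = c(0, 1, 3.16, 10, 31.6, 100, 316, 1000),
                       n_rep = 3L, proteases = c("pepsin", "trypsin")),
         noise = list(cv = 0.2, missing_rate = 0.05, rep_scale_sd = 0.05),
         seed = seed),
    class = "TruthManifest")
  .validate_manifest(manifest)
  manifest
}

.validate_manifest <- function(m) {
  seqs <- m$proteins$sequence
  names(seqs) <- m$proteins$accession
  letter <- substring(seqs[m$sites$accession], m$sites$residue,
                      m$sites$residue)
  stopifnot(all(letter == m$sites$letter),
            all(m$sites$letter %in% c("K", "Y")),
            0 %in% m$design$doses)
  pep_letter <- substring(m$peptides$peptide, m$peptides$mod_pos,
                          m$peptides$mod_pos)
  stopifnot(all(pep_letter %in% c("K", "Y")))
  invisible(m)
}

#' Planted (accession, residue) truth pairs, homolog copies included
#' @param manifest A `TruthManifest`.
#' @return data.frame `accession`, `residue`.
#' @export
planted_site_pairs <- function(manifest) {
  s <- manifest$sites
  out <- data.frame(accession = s$accession, residue = s$residue,
                    stringsAsFactors = FALSE)
  hom <- !is.na(s$homolog_accession)
  if (any(hom)) {
    out <- rbind(out, data.frame(accession = s$homolog_accession[hom],
                                 residue = s$residue[hom],
                                 stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Expected site key of a planted site (shared homolog members included)
#' @keywords internal
.truth_site_key <- function(site_row) {
  accs <- site_row$accession
  if (!is.na(site_row$homolog_accession)) {
    accs <- c(accs, site_row$homolog_accession)
  }
  .site_key(accs, rep(site_row$residue, length(accs)))
}

#' Simulate per-protease quantification tables from a truth manifest
#'
#' Reproduces the statistical structure of a competitive dose-response
#' experiment at the quantified-peptide level. For a competed site the
#' expected peptide intensity at dose c is
#' `base * (bf + (1 - bf) / (1 + (c/IC50)^h))` with `bf` the bottom
#' fraction; stable sites stay at `base`. Peptidoform base intensities are
#' log-uniform over three orders of magnitude, per-sample replicate scale
#' factors emulate run effects, observation noise is multiplicative
#' log-normal with the manifest's CV, and entries are dropped missing at
#' random (written as 0, the convention the parser maps back to missing).
#'
#' @param manifest A `TruthManifest`.
#' @param seed RNG seed (independent of the planting seed).
#' @param cv Multiplicative coefficient of variation.
#' @param missing_rate Missing-at-random probability per entry.
#' @param rep_scale_sd SD (natural-log scale) of per-sample scale factors.
#' @param base_range log10 range of peptidoform base intensities.
#' @param out_dir Optional directory; when given, the per-protease TSVs and
#'   the annotation TSV are written there.
#' @return list with `tables` (named list of per-protease data.frames in the
#'   quantification dialect), `annotation`, `base` (true peptidoform base
#'   intensities) and `paths` (when written).
#' @export
simulate_quant_tables <- function(manifest, seed = 1,
                                  cv = manifest$noise$cv,
                                  missing_rate = manifest$noise$missing_rate,
                                  rep_scale_sd = manifest$noise$rep_scale_sd,
                                  base_range = c(6, 9),
                                  out_dir = NULL) {
  stopifnot(inherits(manifest, "TruthManifest"))
  set.seed(seed)
  sigma <- sqrt(log(1 + cv^2))
  des <- manifest$design
  proteases <- sort(des$proteases, method = "radix")
  ann <- do.call(rbind, lapply(proteases, function(p) {
    do.call(rbind, lapply(des$doses, function(d) {
      data.frame(
        sample_id = sprintf("%s_%s_r%d", p,
                            if (d == 0) "DMSO"
                            else format(d, trim = TRUE, scientific = FALSE),
                            seq_len(des$n_rep)),
        condition = if (d == 0) "DMSO"
                    else format(d, trim = TRUE, scientific = FALSE),
        replicate = seq_len(des$n_rep), protease = p,
        stringsAsFactors = FALSE)
    }))
  }))
  ann <- read_sample_annotation(ann)

  pep <- manifest$peptides
  pep$base <- 10^stats::runif(nrow(pep), base_range[1], base_range[2])
  tables <- list()
  for (p in proteases) {
    sub <- pep[pep$protease == p, , drop = FALSE]
    a <- ann[ann$protease == p, , drop = FALSE]
    scale <- exp(stats::rnorm(nrow(a), 0, rep_scale_sd))
    names(scale) <- a$sample_id
    mat <- matrix(0, nrow(sub), nrow(a), dimnames = list(NULL, a$sample_id))
    for (i in seq_len(nrow(sub))) {
      st <- manifest$sites[sub$site_uid[i], ]
      frac <- if (st$competed) {
        st$true_bottom_frac + (1 - st$true_bottom_frac) /
          (1 + (a$dose / st$true_ic50)^st$true_hill)
      } else rep(1, nrow(a))
      expected <- sub$base[i] * scale * frac
      noise <- if (sigma > 0) exp(stats::rnorm(nrow(a), 0, sigma)) else 1
      obs <- expected * noise
      obs[stats::runif(nrow(a)) < missing_rate] <- 0
      mat[i, ] <- obs
    }
    tab <- data.frame(
      Peptide = sub$peptide,
      check.names = FALSE, stringsAsFactors = FALSE)
    tab[["Assigned Modifications"]] <- sprintf(
      "%d%s(754.2532)", sub$mod_pos,
      substring(sub$peptide, sub$mod_pos, sub$mod_pos))
    tab[["Protein"]] <- sub$accession
    tab[["Gene"]] <- manifest$proteins$gene[
      match(sub$accession, manifest$proteins$accession)]
    tab <- cbind(tab, as.data.frame(mat, check.names = FALSE))
    tables[[p]] <- tab
  }
  out <- list(tables = tables, annotation = ann, base = pep$base)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    for (p in names(tables)) {
      f <- file.path(out_dir, paste0("modified_peptides_", p, ".tsv"))
      utils::write.table(tables[[p]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[p] <- f
    }
    fa <- file.path(out_dir, "annotation.tsv")
    utils::write.table(ann[, c("sample_id", "condition", "replicate",
                               "protease")],
                       fa, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["annotation"] <- fa
    out$paths <- paths
  }
  out
}

#' Simulate one dose series at known truth
#'
#' Response-level helper for Monte-Carlo calibration of the IC50 interval:
#' log2 responses follow the 4PL mean with additive Gaussian noise whose SD
#' corresponds to a multiplicative CV on the intensity scale.
#'
#' @param top,bottom,hill,ic50 True curve parameters (responses in log2).
#' @param doses Dose ladder in nM (0 = DMSO).
#' @param n_rep Replicates per dose.
#' @param cv Multiplicative CV of intensities.
#' @return data.frame `dose`, `response`.
#' @export
simulate_dose_series <- function(top, bottom, hill, ic50,
                                 doses = c(0, 1, 3.16, 10, 31.6, 100, 316,
                                           1000),
                                 n_rep = 3, cv = 0.2) {
  d <- rep(doses, each = n_rep)
  mu <- .fourpl(d, top, bottom, log10(ic50), hill)
  sd_log2 <- sqrt(log(1 + cv^2)) / log(2)
  data.frame(dose = d, response = mu + stats::rnorm(length(d), 0, sd_log2))
}

#' Benchmark pipeline results against the planted truth
#'
#' Computes site-mapping precision/recall on (accession, residue) pairs,
#' log10-IC50 bias and median absolute error on truly competed sites,
#' competed-call sensitivity and stable-call specificity, and empirical CI
#' coverage of the true IC50.
#'
#' @param fits Results from [fit_all_sites()].
#' @param groups `SiteGroups` from the pipeline run.
#' @param manifest The `TruthManifest` the data were simulated from.
#' @return list of metrics.
#' @export
recovery_report <- function(fits, groups, manifest) {
  stopifnot(inherits(manifest, "TruthManifest"))
  planted <- planted_site_pairs(manifest)
  planted_keys <- paste0(planted$accession, ":", planted$residue)
  rec <- unique(paste0(groups$members$accession, ":",
                       groups$members$residue))
  precision <- if (length(rec) > 0) mean(rec %in% planted_keys) else NA_real_
  recall <- if (length(planted_keys) > 0) mean(planted_keys %in% rec)
            else NA_real_

  truth_keys <- vapply(seq_len(nrow(manifest$sites)), function(i)
    .truth_site_key(manifest$sites[i, ]), character(1))
  truth <- manifest$sites
  truth$site_key <- truth_keys
  joined <- merge(fits, truth[, c("site_key", "competed", "true_ic50")],
                  by = "site_key")
  comp <- joined[joined$competed, , drop = FALSE]
  stab <- joined[!joined$competed, , drop = FALSE]
  dlog <- log10(comp$ic50_nM) - log10(comp$true_ic50)
  dlog_called <- dlog[comp$call == "competed"]
  covered <- comp$converged & !is.na(comp$ci_low_nM) &
    comp$ci_low_nM <= comp$true_ic50 & comp$ci_high_nM >= comp$true_ic50
  list(
    mapping_precision = precision,
    mapping_recall = recall,
    n_sites_recovered = nrow(groups$sites),
    n_fits = nrow(fits),
    ic50_bias_log10 = mean(dlog_called, na.rm = TRUE),
    ic50_median_abs_dlog10 = stats::median(abs(dlog_called), na.rm = TRUE),
    ic50_frac_within_0p3 = mean(abs(dlog_called) <= 0.3, na.rm = TRUE),
    sensitivity = if (nrow(comp) > 0) mean(comp$call == "competed")
                  else NA_real_,
    specificity = if (nrow(stab) > 0) mean(stab$call == "stable")
                  else NA_real_,
    ci_coverage = if (nrow(comp) > 0) mean(covered[comp$converged],
                                           na.rm = TRUE) else NA_real_
  )
}
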