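# Independent oracles and small fixtures shared across tests. The oracles are
# deliberately naive (plain loops / gregexpr / grid scans) so they stay
# independent of the implementation paths they check.

# naive full-scan localization: every exact occurrence in every sequence
brute_force_locate <- function(peptide, accessions, sequences) {
  out <- list()
  for (i in seq_along(sequences)) {
    hits <- gregexpr(peptide, sequences[i], fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (s in as.integer(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        accession = accessions[i], start = s,
        end = s + nchar(peptide) - 1L, peptide = peptide,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$accession, res$start, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force specific digestion: enumerate every substring and keep those
# with valid termini, <= max_missed internal cleavage sites, and length in
# range
brute_force_digest <- function(sequence, cleave_after = c("K", "R"),
                               max_missed = 2, lmin = 5, lmax = 30) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  out <- list()
  for (start in 1:n) {
    for (end in start:min(n, start + lmax - 1L)) {
      len <- end - start + 1L
      if (len < lmin) next
      nterm_ok <- start == 1L || chars[start - 1L] %in% cleave_after
      cterm_ok <- end == n || chars[end] %in% cleave_after
      if (!nterm_ok || !cterm_ok) next
      missed <- if (end > start) {
        sum(chars[start:(end - 1L)] %in% cleave_after)
      } else 0L
      if (missed > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = end,
        peptide = substring(sequence, start, end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end), , drop = FALSE]
}

# sorted signature of a peptide-match table, for set-for-set comparison
match_signature <- function(df) {
  sort(paste(df$accession, df$start, df$end, sep = "/"))
}

digest_signature <- function(df) {
  sort(paste(df$start, df$end, sep = "/"))
}

# competition mean function, written independently of the package internals
oracle_fourpl_log2 <- function(dose, top, bottom, lic50, h) {
  log2(2^bottom + (2^top - 2^bottom) / (1 + (dose / 10^lic50)^h))
}

# small two-protein index used across mapping tests
toy_index <- function() {
  build_proteome_index(
    accession = c("ACC1", "ACC2"),
    sequence = c("MKEVPVAIKTLKAGYTE", "GGGKYRRKAAAK"),
    gene = c("GEN1", "GEN2"))
}

# one-protease annotation: 3 DMSO + 3 treated samples
toy_annotation <- function() {
  read_sample_annotation(data.frame(
    sample_id = c("t_DMSO_r1", "t_DMSO_r2", "t_DMSO_r3",
                  "t_10_r1", "t_10_r2", "t_10_r3"),
    condition = rep(c("DMSO", "10"), each = 3),
    replicate = rep(1:3, 2),
    protease = "trypsin",
    stringsAsFactors = FALSE))
}

# a ready-made small synthetic experiment (shared by several files; modest
# size keeps the whole suite fast)
toy_experiment <- function(seed = 101, n_sites = 12, competed_fraction = 0.25,
                           cv = 0, missing_rate = 0, rep_scale_sd = 0) {
  pr <- generate_proteome(20, length_range = c(120, 250), seed = seed)
  man <- plant_labeled_sites(pr, n_sites = n_sites,
                             competed_fraction = competed_fraction,
                             seed = seed + 1)
  sim <- simulate_quant_tables(man, seed = seed + 2, cv = cv,
                               missing_rate = missing_rate,
                               rep_scale_sd = rep_scale_sd)
  list(proteome = pr, manifest = man, sim = sim)
}
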