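toy_table <- function() {
  df <- data.frame(
    Peptide = c("EVPVAIKTLK", "IKTLKAGYTE"),
    check.names = FALSE, stringsAsFactors = FALSE)
  df[["Assigned Modifications"]] <- c("7K(754.2532)",
                                      "2K(754.2532), 1C(57.0215)")
  df[["Protein"]] <- c("ACC1", "ACC1")
  for (s in c("t_DMSO_r1", "t_DMSO_r2", "t_DMSO_r3",
              "t_10_r1", "t_10_r2", "t_10_r3")) {
    df[[s]] <- c(100, 50)
  }
  df
}

test_that("annotation validation derives doses and rejects duplicates", {
  ann <- toy_annotation()
  expect_equal(ann$dose, rep(c(0, 10), each = 3))
  bad <- toy_annotation()
  bad$replicate <- 1L
  expect_error(read_sample_annotation(bad), "duplicate")
  bad2 <- toy_annotation()
  bad2$condition[1] <- "vehicle"
  expect_error(read_sample_annotation(bad2), "DMSO")
})

test_that("quantification tables parse to identical records", {
  ann <- toy_annotation()
  ps <- parse_quant_table(toy_table(), ann, protease = "trypsin")
  expect_s3_class(ps, "PeptideSet")
  expect_equal(ps$peptides$peptide, c("EVPVAIKTLK", "IKTLKAGYTE"))
  expect_equal(ps$peptides$probe_positions, c("7", "2"))
  expect_equal(unname(ps$intensity[, "t_10_r2"]), c(100, 50))
  expect_equal(colnames(ps$intensity), ann$sample_id)
  expect_equal(nrow(attr(ps, "row_errors")), 0L)
})

test_that("zero intensities become missing; negatives are rejected", {
  tab <- toy_table()
  tab[["t_10_r1"]][1] <- 0
  ps <- parse_quant_table(tab, toy_annotation(), protease = "trypsin")
  expect_true(is.na(ps$intensity[1, "t_10_r1"]))
  expect_equal(unname(ps$intensity[2, "t_10_r1"]), 50)

  tab2 <- toy_table()
  tab2[["t_10_r1"]][1] <- -5
  expect_error(parse_quant_table(tab2, toy_annotation(), protease = "trypsin"),
               "negative")
})

test_that("unknown intensity columns and malformed mods are reported", {
  tab <- toy_table()
  tab[["mystery_sample"]] <- c(1, 2)
  expect_error(parse_quant_table(tab, toy_annotation(), protease = "trypsin"),
               "mystery_sample")

  tab2 <- toy_table()
  tab2[["Assigned Modifications"]][2] <- "K7(754.2532)"  # malformed order
  ps <- parse_quant_table(tab2, toy_annotation(), protease = "trypsin")
  errs <- attr(ps, "row_errors")
  expect_equal(errs$row, 2L)
  expect_equal(nrow(ps$peptides), 1L)

  # probe position pointing at a non-K/Y residue is a row error too
  tab3 <- toy_table()
  tab3[["Assigned Modifications"]][1] <- "3K(754.2532)"  # residue 3 is P
  ps3 <- parse_quant_table(tab3, toy_annotation(), protease = "trypsin")
  expect_equal(nrow(ps3$peptides), 1L)
  expect_match(attr(ps3, "row_errors")$message, "allowed residue")
})

test_that("generator tables round-trip through the parser", {
  te <- toy_experiment(seed = 301, n_sites = 10, cv = 0.2,
                       missing_rate = 0.1)
  ann <- te$sim$annotation
  tab <- te$sim$tables$trypsin
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tryp.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- parse_quant_table(path, ann, protease = "trypsin")
  plan <- te$manifest$peptides[te$manifest$peptides$protease == "trypsin", ]
  expect_equal(ps$peptides$peptide, plan$peptide)
  expect_equal(as.integer(ps$peptides$probe_positions), plan$mod_pos)
  # intensities: zeros in the emitted table come back as NA, others exact
  raw <- as.matrix(tab[, ann$sample_id[ann$protease == "trypsin"]])
  raw[raw == 0] <- NA
  expect_equal(unname(ps$intensity), unname(raw), tolerance = 1e-12)
})

presence_pattern_pset <- function(present, ann) {
  # one peptidoform per row of `present` (logical matrix over DMSO reps)
  n <- nrow(present)
  peptides <- data.frame(
    pep_id = seq_len(n), peptide = sprintf("PEPTIDEK%03d", seq_len(n)),
    probe_positions = "8", assigned_accession = "", protease = "trypsin",
    stringsAsFactors = FALSE)
  intensity <- matrix(NA_real_, n, nrow(ann),
                      dimnames = list(NULL, ann$sample_id))
  dmso <- ann$sample_id[ann$dose == 0]
  for (i in seq_len(n)) intensity[i, dmso[present[i, ]]] <- 100
  intensity[, ann$sample_id[ann$dose > 0]] <- 50
  abppsites:::.peptide_set(peptides, intensity)
}

test_that("DMSO presence filter applies the two-replicate rule", {
  ann <- toy_annotation()
  present <- rbind(c(TRUE, FALSE, FALSE),   # 1 replicate -> removed
                   c(TRUE, FALSE, TRUE),    # replicates {1,3} -> retained
                   c(TRUE, TRUE, TRUE))     # all -> retained
  ps <- presence_pattern_pset(present, ann)
  kept <- filter_dmso_presence(ps, ann)
  expect_equal(kept$peptides$pep_id, c(2L, 3L))

  # idempotent
  again <- filter_dmso_presence(kept, ann)
  expect_equal(again$peptides, kept$peptides)
  expect_equal(again$intensity, kept$intensity)
})

test_that("presence filter matches brute force on random patterns", {
  ann <- toy_annotation()
  set.seed(5)
  present <- matrix(runif(500 * 3) < 0.5, ncol = 3)
  ps <- presence_pattern_pset(present, ann)
  kept <- filter_dmso_presence(ps, ann, min_present = 2)
  want <- which(rowSums(present) >= 2)
  expect_equal(kept$peptides$pep_id, want)
})

test_that("filter refuses designs with fewer than two DMSO samples", {
  ann <- toy_annotation()[c(1, 4:6), ]
  ps <- presence_pattern_pset(matrix(TRUE, 2, 1), ann)
  expect_error(filter_dmso_presence(ps, ann), "at least 2")
})

test_that("site aggregation sums member peptides and conserves mass", {
  idx <- build_proteome_index("A", "MKEVPVAIKTLKAGYTE")
  ann <- toy_annotation()
  peptides <- data.frame(
    pep_id = 1:3,
    peptide = c("EVPVAIKTLK", "VAIKTLKAG", "KAGYTE"),
    probe_positions = c("7", "4", "1"),
    assigned_accession = "A", protease = "trypsin",
    stringsAsFactors = FALSE)
  # peptides 1 and 2 share residue K9... of the toy protein; peptide 3 is K12
  intensity <- matrix(NA_real_, 3, 6, dimnames = list(NULL, ann$sample_id))
  intensity[1, ] <- 100
  intensity[2, ] <- c(50, 50, 50, NA, 50, 50)
  intensity[3, ] <- 20
  ps <- abppsites:::.peptide_set(peptides, intensity)
  g <- cluster_to_sites(ps, idx)
  sqm <- aggregate_to_sites(ps, g, ann)
  expect_equal(nrow(sqm$intensity), 2L)
  k9 <- sqm$intensity["A:9", ]
  expect_equal(unname(k9), c(150, 150, 150, 100, 150, 150))
  expect_equal(unname(sqm$intensity["A:12", ]), rep(20, 6))
  expect_equal(sqm$log2["A:12", 1], log2(20))

  # per-sample conservation against an independent total
  expect_equal(unname(colSums(sqm$intensity, na.rm = TRUE)),
               unname(colSums(intensity, na.rm = TRUE)))
})

test_that("aggregation equals an independent recomputation on synthetic data", {
  te <- toy_experiment(seed = 305, n_sites = 10, cv = 0.2, missing_rate = 0.1)
  res <- run_pipeline(te$manifest$index, te$sim$tables, te$sim$annotation)
  g <- res$groups; psf <- res$pset_filtered
  # spreadsheet-style recomputation: loop sites x samples, sum by hand
  for (key in sample(rownames(res$sqm$intensity),
                     min(5, nrow(res$sqm$intensity)))) {
    ids <- g$assignment$pep_id[g$assignment$site_key == key]
    rows <- match(ids, psf$peptides$pep_id)
    rows <- rows[!is.na(rows)]
    for (s in colnames(res$sqm$intensity)) {
      vals <- psf$intensity[rows, s]
      want <- if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
      expect_equal(res$sqm$intensity[key, s], want)
    }
  }
})

test_that("input row order never changes aggregated values", {
  te <- toy_experiment(seed = 307, n_sites = 8, cv = 0.2)
  tab <- te$sim$tables
  set.seed(1)
  tab$trypsin <- tab$trypsin[sample(nrow(tab$trypsin)), ]
  tab$pepsin <- tab$pepsin[sample(nrow(tab$pepsin)), ]
  res1 <- run_pipeline(te$manifest$index, te$sim$tables, te$sim$annotation)
  res2 <- run_pipeline(te$manifest$index, tab, te$sim$annotation)
  expect_equal(res1$sqm$intensity, res2$sqm$intensity)
  expect_equal(res1$fits, res2$fits)
})

test_that("condition means average log2 replicates, DMSO ordered first", {
  ann <- toy_annotation()
  idx <- build_proteome_index("A", "MKEVPVAIKTLKAGYTE")
  peptides <- data.frame(
    pep_id = 1L, peptide = "EVPVAIKTLK", probe_positions = "7",
    assigned_accession = "A", protease = "trypsin", stringsAsFactors = FALSE)
  intensity <- matrix(c(2^10, 2^12, NA, 2^11, NA, NA), 1, 6,
                      dimnames = list(NULL, ann$sample_id))
  ps <- abppsites:::.peptide_set(peptides, intensity)
  g <- cluster_to_sites(ps, idx)
  sqm <- aggregate_to_sites(ps, g, ann)
  cm <- summarize_condition_means(sqm)
  expect_equal(cm$dose, c(0, 10))
  expect_equal(cm$condition, c("DMSO", "10"))
  expect_equal(cm$mean_log2, c(11, 11))   # {10,12} -> 11; single 11 -> 11
  expect_equal(cm$n_obs, c(2L, 1L))

  # all-missing condition -> NA mean
  intensity2 <- intensity
  intensity2[1, 4:6] <- NA
  ps2 <- abppsites:::.peptide_set(peptides, intensity2)
  sqm2 <- aggregate_to_sites(ps2, cluster_to_sites(ps2, idx), ann)
  cm2 <- summarize_condition_means(sqm2)
  expect_true(is.na(cm2$mean_log2[cm2$dose == 10]))
})

test_that("condition means equal brute-force means on synthetic data", {
  te <- toy_experiment(seed = 309, n_sites = 6, cv = 0.2, missing_rate = 0.1)
  res <- run_pipeline(te$manifest$index, te$sim$tables, te$sim$annotation)
  cm <- res$cond_means
  ann <- res$sqm$annotation
  for (i in sample(nrow(cm), 25)) {
    ids <- ann$sample_id[ann$protease == cm$protease[i] &
                           ann$dose == cm$dose[i]]
    vals <- res$sqm$log2[cm$site_key[i], ids]
    want <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    expect_equal(cm$mean_log2[i], want)
  }
})
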