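test_that("FASTA reading parses headers, genes and sequences", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|T1_HUMAN demo GN=G1", "MKEVPVAIKTLK"), fa)
  idx <- read_proteome_fasta(fa)
  expect_s3_class(idx, "ProteomeIndex")
  expect_equal(idx$accession, "P1")
  expect_equal(idx$gene, "G1")
  expect_equal(nchar(idx$sequence), 12L)

  # plain headers fall back to the first token; GN absent -> empty gene
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">PROT_A some description", "ACDEFGHIK"), fa2)
  idx2 <- read_proteome_fasta(fa2)
  expect_equal(idx2$accession, "PROT_A")
  expect_equal(idx2$gene, "")
})

test_that("FASTA reading rejects duplicates and empty files", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|A", "MKKK", ">sp|P1|B", "RRRR"), fa)
  expect_error(read_proteome_fasta(fa), "P1")

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa2)
  expect_error(read_proteome_fasta(fa2))
})

test_that("synthetic FASTA round-trips through the reader", {
  pr <- generate_proteome(50, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(pr, fa)
  idx <- read_proteome_fasta(fa)
  expect_length(idx$accession, 50L)
  expect_equal(sum(nchar(idx$sequence)), sum(nchar(pr$proteins$sequence)))
  expect_equal(idx$sequence, pr$proteins$sequence)
  expect_equal(idx$gene, pr$proteins$gene)
})

test_that("tryptic digestion equals brute-force substring enumeration", {
  rule <- digest_rule("trypsin", max_missed = 2, length_min = 1,
                      length_max = 30)
  got <- digest("MKRAPKLDEW", rule)
  want <- brute_force_digest("MKRAPKLDEW", c("K", "R"), 2, 1, 30)
  expect_equal(digest_signature(got), digest_signature(want))

  # random proteins, default length window, both specific rules
  set.seed(42)
  for (i in 1:8) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 180,
                      replace = TRUE), collapse = "")
    for (enzyme in c("trypsin", "chymotrypsin")) {
      rule <- digest_rule(enzyme)
      got <- digest(s, rule)
      want <- brute_force_digest(
        s, if (enzyme == "trypsin") c("K", "R") else c("F", "L", "Y", "W"),
        rule$max_missed, rule$length_min, rule$length_max)
      expect_equal(digest_signature(got), digest_signature(want))
    }
  }
})

test_that("digestion output satisfies its contracts", {
  s <- "MKEVPVAIKTLKAGYTEKRRLDDFWK"
  rule <- digest_rule("trypsin")
  dg <- digest(s, rule, accession = "A")
  expect_true(all(dg$peptide == substring(s, dg$start, dg$end)))
  expect_true(all(nchar(dg$peptide) == dg$end - dg$start + 1))
  expect_true(all(nchar(dg$peptide) >= rule$length_min &
                    nchar(dg$peptide) <= rule$length_max))
  expect_true(all(dg$n_missed <= rule$max_missed))
  # valid termini
  chars <- strsplit(s, "")[[1]]
  nterm_ok <- vapply(dg$start, function(st)
    st == 1 || chars[st - 1] %in% c("K", "R"), logical(1))
  cterm_ok <- vapply(dg$end, function(en)
    en == nchar(s) || chars[en] %in% c("K", "R"), logical(1))
  expect_true(all(nterm_ok))
  expect_true(all(cterm_ok))
})

test_that("a protein without cleavage sites yields itself when length allows", {
  dg <- digest("AAAAAAA", digest_rule("trypsin"))
  expect_equal(nrow(dg), 1L)
  expect_equal(dg$peptide, "AAAAAAA")
  # too short for the window -> nothing
  expect_equal(nrow(digest("AAA", digest_rule("trypsin"))), 0L)
})

test_that("proline suppression is available but off by default", {
  # K followed by P: cleaved under the default plain K/R rule
  s <- "AAAKPAAAKAAA"
  plain <- digest(s, digest_rule("trypsin", length_min = 1))
  expect_true("AAAK" %in% plain$peptide)
  supp <- digest(s, digest_rule("trypsin", length_min = 1,
                                proline_suppression = TRUE))
  expect_false("AAAK" %in% supp$peptide)
  expect_true("AAAKPAAAK" %in% supp$peptide)
})

test_that("nonspecific digestion is refused with guidance", {
  expect_error(digest("MKAAAK", digest_rule("pepsin_nonspecific")),
               "locate_peptide")
})

test_that("peptide localization matches a naive full scan", {
  idx <- build_proteome_index("A", "MKEVPVAIKTLKAGYTE")
  got <- locate_peptide("EVPVAIKTLK", idx)
  expect_equal(got$accession, "A")
  expect_equal(got$start, 3L)
  expect_equal(got$end, 12L)

  # full-record query
  full <- locate_peptide("MKEVPVAIKTLKAGYTE", idx)
  expect_equal(full$start, 1L)
  expect_equal(full$end, 17L)

  # no match -> empty, not an error
  expect_equal(nrow(locate_peptide("WWWWW", idx)), 0L)
})

test_that("identical records each report a match, ordered by accession", {
  idx <- build_proteome_index(c("C", "B"), c("MKAYKTLK", "MKAYKTLK"))
  got <- locate_peptide("KAYKT", idx)
  expect_equal(got$accession, c("B", "C"))
  expect_equal(got$start, c(2L, 2L))
})

test_that("I/L are distinct by default and collapsible on request", {
  idx <- build_proteome_index("A", "MKEVPVAILTLK")
  expect_equal(nrow(locate_peptide("VAILT", idx)), 1L)
  expect_equal(nrow(locate_peptide("VALIT", idx)), 0L)
  expect_equal(nrow(locate_peptide("VALIT", idx, il_equivalent = TRUE)), 1L)
})

test_that("non-canonical query residues are rejected; subject X never matches", {
  idx <- build_proteome_index("A", "MKXEVPK")
  expect_error(locate_peptide("KXE", idx), "non-canonical")
  expect_equal(nrow(locate_peptide("KAE", idx)), 0L)
})

test_that("localization equals the oracle on randomized queries", {
  pr <- generate_proteome(20, length_range = c(80, 200), seed = 9)
  idx <- proteome_index(pr)
  set.seed(10)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (q in 1:60) {
    # draw a true substring, then sometimes mutate one residue
    i <- sample.int(20, 1)
    s <- pr$proteins$sequence[i]
    len <- sample(5:15, 1)
    st <- sample.int(nchar(s) - len + 1L, 1)
    pep <- substring(s, st, st + len - 1L)
    if (q %% 2 == 0) {
      p <- sample.int(len, 1)
      substr(pep, p, p) <- sample(aa, 1)
    }
    got <- locate_peptide(pep, idx)
    want <- brute_force_locate(pep, pr$proteins$accession,
                               pr$proteins$sequence)
    expect_equal(match_signature(got), match_signature(want))
  }
})

test_that("uniqueness classification covers unique, shared and unmatched", {
  idx <- build_proteome_index(c("Z", "A", "M"),
                              c("MKAYKTLK", "MKAYKTLK", "MKAYKTLK"))
  m <- locate_peptide("KAYKT", idx)
  cls <- classify_uniqueness(m)
  expect_equal(cls$status, "shared")
  expect_equal(cls$accessions, c("A", "M", "Z"))

  one <- classify_uniqueness(m[m$accession == "A", , drop = FALSE])
  expect_equal(one$status, "unique")

  none <- classify_uniqueness(m[0, , drop = FALSE])
  expect_equal(none$status, "unmatched")
  expect_length(none$accessions, 0L)
})
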