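## Proteome handling: FASTA input, rule-based in-silico digestion, and exact
## peptide localization (the nonspecific/peptic path is substring search only;
## peptic peptides are never pre-enumerated).

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues. Sequences may additionally contain X/U/B/Z,
#' which never match any query peptide.
#' @keywords internal
.CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a proteome FASTA into a searchable index
#'
#' Parses a UniProt-style FASTA (accession from `sp|ACC|NAME` / `tr|ACC|NAME`
#' headers or the first whitespace-delimited token; gene symbol from a `GN=`
#' tag when present) and builds an exact-substring index used by
#' [locate_peptide()].
#'
#' @param path Path to a FASTA file.
#' @return A `ProteomeIndex` object: a list with `accession`, `gene`,
#'   `sequence` (parallel character vectors) and `aa` (an
#'   [Biostrings::AAStringSet] used for matching).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|T1 demo GN=G1", "MKEVPVAIKTLK"), fa)
#' idx <- read_proteome_fasta(fa)
#' idx$accession
#' @export
read_proteome_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(aa)
  acc <- vapply(headers, .parse_accession, character(1), USE.NAMES = FALSE)
  dup <- acc[duplicated(acc)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  gene <- vapply(headers, .parse_gene, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", acc[!nzchar(seqs)][1])
  names(aa) <- acc
  structure(
    list(accession = acc, gene = gene, sequence = unname(seqs),
         aa = Biostrings::AAStringSet(seqs)),
    class = "ProteomeIndex"
  )
}

#' Build a ProteomeIndex from in-memory sequences
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @param gene Optional gene symbols (empty string when unknown).
#' @return A `ProteomeIndex`.
#' @export
build_proteome_index <- function(accession, sequence, gene = NULL) {
  stopifnot(length(accession) == length(sequence), !anyDuplicated(accession))
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty sequence not allowed")
  if (is.null(gene)) gene <- rep("", length(accession))
  structure(
    list(accession = as.character(accession), gene = as.character(gene),
         sequence = unname(sequence), aa = Biostrings::AAStringSet(sequence)),
    class = "ProteomeIndex"
  )
}

#' @export
print.ProteomeIndex <- function(x, ...) {
  cat("ProteomeIndex:", length(x$accession), "proteins,",
      sum(nchar(x$sequence)), "residues\n")
  invisible(x)
}

.parse_accession <- function(header) {
  first <- strsplit(header, "[[:space:]]+")[[1]][1]
  parts <- strsplit(first, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L && parts[1] %in% c("sp", "tr")) parts[2] else first
}

.parse_gene <- function(header) {
  m <- regmatches(header, regexpr("GN=[^[:space:]]+", header))
  if (length(m) == 0L) "" else sub("^GN=", "", m)
}

#' Protease digestion rules
#'
#' Constructs the cleavage rule used by [digest()]. Trypsin cleaves C-terminal
#' to K/R (up to 2 missed cleavages by default), chymotrypsin C-terminal to
#' F/L/Y/W. Pepsin is modeled as fully nonspecific: it has no enumerable rule
#' and peptic peptides are handled by [locate_peptide()] only.
#'
#' @param name One of `"trypsin"`, `"chymotrypsin"`, `"pepsin_nonspecific"`.
#' @param max_missed Maximum number of internal uncleaved sites.
#' @param length_min,length_max Allowed peptide length range.
#' @param proline_suppression If `TRUE`, a cleavage site followed by proline
#'   is not cleaved. Off by default: plain K/R and F/L/Y/W rules.
#' @return A `DigestRule` list.
#' @export
digest_rule <- function(name = c("trypsin", "chymotrypsin", "pepsin_nonspecific"),
                        max_missed = if (name == "trypsin") 2L else 2L,
                        length_min = 5L, length_max = 30L,
                        proline_suppression = FALSE) {
  name <- match.arg(name)
  cleave_after <- switch(name,
    trypsin = c("K", "R"),
    chymotrypsin = c("F", "L", "Y", "W"),
    pepsin_nonspecific = character(0)
  )
  stopifnot(length_min <= length_max, max_missed >= 0L)
  structure(
    list(name = name, cleave_after = cleave_after,
         max_missed = as.integer(max_missed),
         length_min = as.integer(length_min),
         length_max = as.integer(length_max),
         proline_suppression = isTRUE(proline_suppression)),
    class = "DigestRule"
  )
}

#' Enumerate fully specific peptides of one protein
#'
#' Returns every peptide whose termini are valid under the cleavage rule
#' (C-terminal residue in the cleavage set or the protein C-terminus, and
#' the preceding residue in the cleavage set or the protein N-terminus),
#' with at most `rule$max_missed` internal cleavage sites and length within
#' the rule's range. Coordinates are 1-based inclusive.
#'
#' @param sequence Protein sequence (uppercase string).
#' @param rule A [digest_rule()]; must not be nonspecific.
#' @param accession Optional accession carried into the output.
#' @return data.frame with columns `accession`, `start`, `end`, `peptide`,
#'   `n_missed`.
#' @export
digest <- function(sequence, rule = digest_rule("trypsin"), accession = "") {
  stopifnot(inherits(rule, "DigestRule"))
  if (rule$name == "pepsin_nonspecific") {
    stop("nonspecific digestion is not enumerated; use locate_peptide() ",
         "to localize peptic peptides")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  sites <- which(chars %in% rule$cleave_after)
  if (rule$proline_suppression) {
    sites <- sites[!(sites < n & chars[sites + 1L] == "P")]
  }
  ## fragment boundaries: cut after each site; b[i]+1 .. b[i+1] is fragment i
  b <- unique(c(0L, sites[sites < n], n))
  nf <- length(b) - 1L
  out <- vector("list", 64L); k <- 0L
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + rule$max_missed)) {
      start <- b[i] + 1L
      end <- b[j + 1L]
      len <- end - start + 1L
      if (len < rule$length_min) next
      if (len > rule$length_max) break
      k <- k + 1L
      if (k > length(out)) out <- c(out, vector("list", length(out)))
      out[[k]] <- c(start, end, j - i)
    }
  }
  if (k == 0L) {
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      n_missed = integer(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(
    accession = rep(accession, k),
    start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    peptide = substring(sequence, m[, 1], m[, 2]),
    n_missed = as.integer(m[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Locate a peptide in the proteome by exact substring search
#'
#' Finds all and only the exact occurrences of `peptide` across every indexed
#' protein, sorted by (accession, start). This is the localization path for
#' nonspecifically generated (peptic) peptides, and is also valid for any
#' specific peptide. I and L are distinct by default; `il_equivalent = TRUE`
#' collapses them for matching (the reported peptide stays as given).
#'
#' @param peptide Query peptide (canonical residues only).
#' @param index A `ProteomeIndex`.
#' @param il_equivalent Treat I and L as equivalent during matching.
#' @return data.frame with columns `accession`, `start`, `end`, `peptide`.
#' @export
locate_peptide <- function(peptide, index, il_equivalent = FALSE) {
  stopifnot(inherits(index, "ProteomeIndex"),
            is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 1L)
  peptide <- toupper(peptide)
  bad <- setdiff(strsplit(peptide, "")[[1]], .CANONICAL_AA)
  if (length(bad) > 0L) {
    stop("peptide contains non-canonical residue(s): ", paste(bad, collapse = ""))
  }
  subject <- index$aa
  pattern <- peptide
  if (isTRUE(il_equivalent)) {
    pattern <- chartr("I", "L", pattern)
    subject <- Biostrings::AAStringSet(chartr("I", "L", index$sequence))
  }
  m <- Biostrings::vmatchPattern(pattern, subject, fixed = TRUE)
  hits <- which(S4Vectors::elementNROWS(m) > 0L)
  if (length(hits) == 0L) {
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(hits, function(i) {
    s <- BiocGenerics::start(m[[i]])
    data.frame(accession = rep(index$accession[i], length(s)),
               start = as.integer(s),
               end = as.integer(s + nchar(peptide) - 1L),
               peptide = rep(peptide, length(s)),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$accession, res$start, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify peptide uniqueness from its localization matches
#'
#' @param matches data.frame from [locate_peptide()].
#' @return list with `status` (`"unique"`, `"shared"`, or `"unmatched"`) and
#'   `accessions` (sorted distinct accessions carrying the peptide).
#' @export
classify_uniqueness <- function(matches) {
  accs <- sort(unique(matches$accession), method = "radix")
  status <- if (length(accs) == 0L) "unmatched"
            else if (length(accs) == 1L) "unique" else "shared"
  list(status = status, accessions = accs)
}
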