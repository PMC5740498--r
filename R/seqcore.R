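#' @importFrom stats median optimize rbinom rnorm rpois runif setNames lm
#'   lm.fit predict coef rmultinom rlnorm sd pnorm quantile rbeta
#' @importFrom utils read.delim write.table
NULL

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Standard genetic code
#'
#' Codon to single-letter amino acid lookup for the standard nuclear code
#' (64 codons; 61 sense, 3 stop). Stops are encoded as `"*"`.
#'
#' @return Named character vector of length 64; names are codons.
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L, sum(code == "*") == 3L)
  code
}

#' Construct a validated ORF sequence
#'
#' An open reading frame for mutagenesis design and variant scoring.
#' The sequence must use the {A,C,G,T} alphabet, have length divisible by 3,
#' begin with ATG, and contain exactly one stop codon, at the end.
#'
#' @param id Sequence identifier.
#' @param nucleotides DNA string.
#' @return An object of class `orf_sequence` with fields `id` and
#'   `nucleotides`.
#' @examples
#' orf <- orf_sequence("toy", "ATGAAATAA")
#' translate_orf(orf)  # "MK"
#' @export
orf_sequence <- function(id, nucleotides) {
  nucleotides <- toupper(as.character(nucleotides))
  if (!grepl("^[ACGT]+$", nucleotides))
    stop("ORF contains characters outside {A,C,G,T}")
  if (nchar(nucleotides) %% 3L != 0L)
    stop("ORF length is not divisible by 3")
  if (substr(nucleotides, 1L, 3L) != "ATG")
    stop("ORF does not begin with ATG")
  codons <- orf_codons(nucleotides)
  aa <- unname(genetic_code()[codons])
  stops <- which(aa == "*")
  if (length(stops) != 1L || stops != length(codons))
    stop("ORF must contain exactly one stop codon, at the end")
  structure(list(id = as.character(id), nucleotides = nucleotides),
            class = "orf_sequence")
}

orf_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' @export
print.orf_sequence <- function(x, ...) {
  cat(sprintf("<orf_sequence> %s: %d nt, %d codons (incl. stop)\n",
              x$id, nchar(x$nucleotides), nchar(x$nucleotides) %/% 3L))
  invisible(x)
}

#' Translate an ORF to protein
#'
#' @param orf An [orf_sequence()].
#' @return Protein string; the terminal stop is dropped, so the protein has
#'   `nchar(nucleotides)/3 - 1` residues.
#' @export
translate_orf <- function(orf) {
  stopifnot(inherits(orf, "orf_sequence"))
  aa <- unname(genetic_code()[orf_codons(orf$nucleotides)])
  paste(aa[-length(aa)], collapse = "")
}

#' Construct a codon-level variant
#'
#' @param codon_index 1-based codon position in the ORF.
#' @param wt_codon,mut_codon Wild-type and mutant codons (3-mers).
#' @param orf Optional [orf_sequence()]; when supplied, `wt_codon` is checked
#'   against the ORF.
#' @return A `codon_variant` list.
#' @export
codon_variant <- function(codon_index, wt_codon, mut_codon, orf = NULL) {
  wt_codon <- toupper(wt_codon); mut_codon <- toupper(mut_codon)
  stopifnot(codon_index >= 1L, nchar(wt_codon) == 3L, nchar(mut_codon) == 3L)
  if (wt_codon == mut_codon) stop("wt_codon and mut_codon are identical")
  if (!is.null(orf)) {
    actual <- orf_codons(orf$nucleotides)[codon_index]
    if (is.na(actual) || actual != wt_codon)
      stop(sprintf("wt_codon %s does not match ORF codon %s at index %d",
                   wt_codon, actual, codon_index))
  }
  structure(list(codon_index = as.integer(codon_index),
                 wt_codon = wt_codon, mut_codon = mut_codon),
            class = "codon_variant")
}

#' Classify a codon variant as synonymous, missense or nonsense
#'
#' @param v A [codon_variant()].
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`.
#' @export
classify_codon_variant <- function(v) {
  code <- genetic_code()
  wt <- code[[v$wt_codon]]; mut <- code[[v$mut_codon]]
  if (mut == "*") "nonsense" else if (wt == mut) "synonymous" else "missense"
}

#' Amino-acid level variant
#'
#' @param position 1-based residue position.
#' @param wt_aa,mut_aa Single-letter residues; `mut_aa` may be `"*"` (stop)
#'   or equal to `wt_aa` only for synonymous records (written `"="` in files).
#' @return An `aa_variant` list.
#' @export
aa_variant <- function(position, wt_aa, mut_aa) {
  stopifnot(position >= 1L, wt_aa %in% AA_ALPHABET,
            mut_aa %in% c(AA_ALPHABET, "*"))
  structure(list(position = as.integer(position),
                 wt_aa = wt_aa, mut_aa = mut_aa), class = "aa_variant")
}

#' Convert a codon variant to its amino-acid consequence
#'
#' @param v A [codon_variant()].
#' @return An [aa_variant()]; for synonymous changes `mut_aa == wt_aa`.
#' @export
codon_to_aa_variant <- function(v) {
  code <- genetic_code()
  aa_variant(v$codon_index, code[[v$wt_codon]], code[[v$mut_codon]])
}

#' Compact variant string notation
#'
#' Missense/nonsense variants are written `"K48E"` / `"K48*"`; synonymous
#' changes `"K48="`. [parse_variant_string()] inverts the format.
#'
#' @param position Residue position(s).
#' @param wt_aa,mut_aa Residues (vectorized).
#' @return Character vector of variant strings.
#' @export
format_variant_string <- function(wt_aa, position, mut_aa) {
  ifelse(mut_aa == wt_aa, paste0(wt_aa, position, "="),
         paste0(wt_aa, position, mut_aa))
}

#' @rdname format_variant_string
#' @param x Variant strings such as `"K48E"`, `"K48*"`, `"K48="`.
#' @export
parse_variant_string <- function(x) {
  m <- regmatches(x, regexec("^([A-Y])([0-9]+)([A-Y*=])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable variant string: ", x[bad][1L])
  data.frame(
    wt_aa = vapply(m, `[[`, "", 2L),
    position = as.integer(vapply(m, `[[`, "", 3L)),
    mut_aa = {
      mut <- vapply(m, `[[`, "", 4L)
      ifelse(mut == "=", vapply(m, `[[`, "", 2L), mut)
    },
    stringsAsFactors = FALSE
  )
}

#' Substitutions reachable by a single nucleotide change
#'
#' Enumerates, for every codon of the ORF body, the 9 single-nucleotide
#' neighbours of the actual codon and reports the amino-acid substitutions
#' they encode. By default synonymous changes and stops are excluded, giving
#' the set of missense changes accessible to single-nucleotide mutagenesis.
#'
#' @param orf An [orf_sequence()].
#' @param include_synonymous,include_stop Include synonymous / nonsense
#'   outcomes.
#' @return data.frame with columns `position`, `wt_aa`, `mut_aa`
#'   (unique rows).
#' @export
snv_accessible_substitutions <- function(orf, include_synonymous = FALSE,
                                         include_stop = FALSE) {
  code <- genetic_code()
  codons <- orf_codons(orf$nucleotides)
  codons <- codons[-length(codons)]  # drop stop
  out <- vector("list", length(codons))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(codons)) {
    wt <- codons[i]; wt_aa <- code[[wt]]
    muts <- character(0)
    for (p in 1:3) for (b in bases) {
      if (substr(wt, p, p) == b) next
      nb <- wt; substr(nb, p, p) <- b
      muts <- c(muts, code[[nb]])
    }
    keep <- rep(TRUE, length(muts))
    if (!include_synonymous) keep <- keep & muts != wt_aa
    if (!include_stop) keep <- keep & muts != "*"
    muts <- unique(muts[keep])
    if (length(muts))
      out[[i]] <- data.frame(position = i, wt_aa = wt_aa, mut_aa = muts,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(position = integer(0), wt_aa = character(0),
                      mut_aa = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Number of possible amino-acid substitutions
#'
#' Each of the `protein_length` residues can mutate to any of the 19 other
#' amino acids.
#'
#' @param protein_length Number of residues considered.
#' @return `protein_length * 19`.
#' @export
possible_substitution_count <- function(protein_length) {
  if (any(protein_length < 1)) stop("protein_length must be positive")
  as.integer(protein_length) * 19L
}

#' Map coverage as a whole-number percentage
#'
#' @param achieved Number of distinct amino-acid changes measured.
#' @param possible Number of possible amino-acid changes.
#' @return Percentage rounded to the nearest integer.
#' @export
coverage_percent <- function(achieved, possible) {
  stopifnot(possible > 0, achieved >= 0)
  round(100 * achieved / possible)
}

# ---- file formats -----------------------------------------------------------

#' Read / write ORF FASTA
#'
#' @param path FASTA file path.
#' @return [read_orf_fasta()]: an [orf_sequence()] (first record).
#' @export
read_orf_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  orf_sequence(names(ss)[1L], as.character(ss[[1L]]))
}

#' @rdname read_orf_fasta
#' @param orf An [orf_sequence()].
#' @export
write_orf_fasta <- function(orf, path) {
  ss <- Biostrings::DNAStringSet(setNames(orf$nucleotides, orf$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write a variant table TSV
#'
#' Tab-separated with header columns `gene`, `position`, `wt_aa`, `mut_aa`
#' and, when codon-level information is present, `codon_index`, `wt_codon`,
#' `mut_codon`. Additional columns (scores, errors, provenance) round-trip
#' unchanged.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "position", "wt_aa", "mut_aa")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_variant_table
#' @param df data.frame to write.
#' @export
write_variant_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
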