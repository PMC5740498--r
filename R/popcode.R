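# POPCode mutagenic oligo design: one oligo per codon, the target codon
# replaced by NNK, flanking arms grown until a predicted melting temperature
# target is met so the mutation rate is as even as possible across the ORF.

#' NNK degenerate codon table
#'
#' The 32 codons with any base at positions 1-2 and G or T at position 3.
#' NNK saturation mutagenesis reaches all 20 amino acids while admitting a
#' single stop codon (TAG; TAA and TGA end in A).
#'
#' @return data.frame with columns `codon`, `aa`, plus attributes
#'   `n_amino_acids` and `n_stop`.
#' @export
nnk_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), c("G", "T"), paste0))
  codons <- sort(codons)
  aa <- unname(genetic_code()[codons])
  out <- data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
  attr(out, "n_amino_acids") <- length(unique(aa[aa != "*"]))
  attr(out, "n_stop") <- sum(aa == "*")
  out
}

#' Oligo design configuration
#'
#' @param tm_target Target melting temperature for each arm, degrees C.
#' @param arm_min,arm_max Minimum / maximum arm length, nt.
#' @param salt_mM Monovalent cation concentration, mM.
#' @param oligo_nM Oligo concentration, nM.
#' @param codons_targeted Optional integer vector of codon indices; default
#'   all codons except the initiator ATG and the stop.
#' @return A `design_config` list.
#' @export
design_config <- function(tm_target = 60, arm_min = 10, arm_max = 40,
                          salt_mM = 50, oligo_nM = 50,
                          codons_targeted = NULL) {
  stopifnot(arm_min >= 10, tm_target >= 40, tm_target <= 75,
            arm_max >= arm_min, salt_mM > 0, oligo_nM > 0)
  structure(list(tm_target = tm_target, arm_min = as.integer(arm_min),
                 arm_max = as.integer(arm_max), salt_mM = salt_mM,
                 oligo_nM = oligo_nM, codons_targeted = codons_targeted),
            class = "design_config")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), duplex sense 5'->3'.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# Duplex initiation with a terminal G:C vs A:T pair.
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Predicted duplex melting temperature under the unified nearest-neighbor
#' thermodynamic parameter set, with entropic salt correction
#' `0.368 * (N-1) * ln[Na+]` and the usual `R ln(CT/4)` term for
#' non-self-complementary duplexes in excess of one strand.
#'
#' @param seq DNA string (no degenerate bases), length >= 8.
#' @param cfg A [design_config()] supplying salt and oligo concentration.
#' @return Melting temperature in degrees C.
#' @export
predict_tm <- function(seq, cfg = design_config()) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) stop("degenerate or invalid base in sequence")
  n <- nchar(seq)
  if (n < 8L) stop("sequence shorter than 8 nt")
  steps <- substring(seq, seq_len(n - 1L), 2:n)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  ends <- c(substr(seq, 1L, 1L), substr(seq, n, n))
  for (e in ends) {
    key <- if (e %in% c("G", "C")) "GC" else "AT"
    dH <- dH + NN_INIT_DH[[key]]
    dS <- dS + NN_INIT_DS[[key]]
  }
  na <- cfg$salt_mM / 1000
  ct <- cfg$oligo_nM * 1e-9
  dS_corr <- dS + 0.368 * (n - 1L) * log(na)
  tm_k <- dH * 1000 / (dS_corr + 1.9872 * log(ct / 4))
  tm_k - 273.15
}

#' Design POPCode mutagenic oligos
#'
#' One oligo per targeted codon: the codon is replaced with NNK and each
#' flanking arm is the shortest extension of the wild-type context whose
#' predicted melting temperature reaches `cfg$tm_target`, within
#' `[arm_min, arm_max]`. Arms are grown outward one nucleotide at a time,
#' left arm first on ties; if the target temperature is unreachable at
#' `arm_max` the maximal arm is used with a warning.
#'
#' @param orf An [orf_sequence()].
#' @param cfg A [design_config()].
#' @param flank_left,flank_right Constant amplicon sequence flanking the ORF
#'   (e.g. vector arms); oligo arms for codons near the ORF ends may extend
#'   into them. Codons whose available flank is still shorter than `arm_min`
#'   raise an error.
#' @return data.frame with one row per oligo: `codon_index`, `sequence`
#'   (arms joined by the literal `NNK`), `left_arm`, `right_arm`,
#'   `tm_left`, `tm_right`.
#' @export
design_popcode_oligos <- function(orf, cfg = design_config(),
                                  flank_left = "", flank_right = "") {
  nt <- orf$nucleotides
  n_codon <- nchar(nt) %/% 3L
  targets <- cfg$codons_targeted
  if (is.null(targets)) targets <- seq(2L, n_codon - 1L)
  stopifnot(all(targets >= 1L), all(targets <= n_codon))
  rows <- vector("list", length(targets))
  warned <- FALSE
  for (j in seq_along(targets)) {
    ci <- targets[j]
    lflank <- paste0(flank_left, substr(nt, 1L, 3L * (ci - 1L)))
    rflank <- paste0(substr(nt, 3L * ci + 1L, nchar(nt)), flank_right)
    if (nchar(lflank) < cfg$arm_min || nchar(rflank) < cfg$arm_min)
      stop(sprintf("codon %d has < %d nt of flank", ci, cfg$arm_min))
    la <- cfg$arm_min; ra <- cfg$arm_min
    arm_seq <- function(flank, len, side) {
      if (side == "L") substr(flank, nchar(flank) - len + 1L, nchar(flank))
      else substr(flank, 1L, len)
    }
    tm_l <- predict_tm(arm_seq(lflank, la, "L"), cfg)
    tm_r <- predict_tm(arm_seq(rflank, ra, "R"), cfg)
    repeat {
      grow_l <- tm_l < cfg$tm_target && la < min(cfg$arm_max, nchar(lflank))
      grow_r <- tm_r < cfg$tm_target && ra < min(cfg$arm_max, nchar(rflank))
      if (!grow_l && !grow_r) break
      if (grow_l) {                       # left arm first on ties
        la <- la + 1L
        tm_l <- predict_tm(arm_seq(lflank, la, "L"), cfg)
      } else {
        ra <- ra + 1L
        tm_r <- predict_tm(arm_seq(rflank, ra, "R"), cfg)
      }
    }
    if ((tm_l < cfg$tm_target || tm_r < cfg$tm_target) && !warned) {
      warning("tm_target unreachable at arm_max for some codons; ",
              "using maximal arms")
      warned <- TRUE
    }
    left <- arm_seq(lflank, la, "L"); right <- arm_seq(rflank, ra, "R")
    rows[[j]] <- data.frame(codon_index = ci,
                            sequence = paste0(left, "NNK", right),
                            left_arm = left, right_arm = right,
                            tm_left = tm_l, tm_right = tm_r,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write designed oligos
#'
#' @param oligos Output of [design_popcode_oligos()].
#' @param path Output file; `.tsv` writes the full table, `.fa`/`.fasta`
#'   writes oligo sequences named `oligo_<codon_index>`.
#' @export
write_oligos <- function(oligos, path) {
  if (grepl("\\.(fa|fasta)$", path)) {
    lines <- as.vector(rbind(paste0(">oligo_", oligos$codon_index),
                             oligos$sequence))
    writeLines(lines, path)
  } else {
    write.table(oligos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
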