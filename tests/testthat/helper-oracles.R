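# Independent oracles: deliberately plain re-implementations used to verify
# the package's vectorized code on small instances. These stay naive (loops,
# literal parameter transcription) on purpose.

# Literal second transcription of the unified nearest-neighbor duplex
# parameters (dH kcal/mol, dS cal/mol/K), computed step by step.
oracle_tm <- function(seq, salt_mM = 50, oligo_nM = 50) {
  dh_tab <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
                 CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
                 CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
                 CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds_tab <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
                 CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
                 CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
                 CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  dh <- 0; ds <- 0
  for (i in 1:(nchar(seq) - 1)) {
    nn <- substr(seq, i, i + 1)
    dh <- dh + dh_tab[[nn]]
    ds <- ds + ds_tab[[nn]]
  }
  for (end in c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))) {
    if (end == "G" || end == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (nchar(seq) - 1) * log(salt_mM / 1000)
  dh * 1000 / (ds + 1.9872 * log(oligo_nM * 1e-9 / 4)) - 273.15
}

# Spreadsheet-style evaluation of the BarSeq equation chain, one quantity at
# a time, for a single replicate. counts: clones x timepoints matrices per
# temperature; pools: named list of pool-size vectors.
oracle_barseq_s <- function(counts_perm, counts_sel, pools_perm, pools_sel,
                            timepoints, pseudocount = 0.5) {
  n <- nrow(counts_perm); K <- length(timepoints)
  s <- numeric(n)
  for (i in 1:n) {
    acc <- 1
    for (k in 2:K) {
      dt <- timepoints[k] - timepoints[k - 1]
      phi <- list()
      for (tau in c("perm", "sel")) {
        cmat <- if (tau == "perm") counts_perm else counts_sel
        pool <- if (tau == "perm") pools_perm else pools_sel
        r_now <- (cmat[i, k] + pseudocount) /
          sum(cmat[, k] + pseudocount)
        r_prev <- (cmat[i, k - 1] + pseudocount) /
          sum(cmat[, k - 1] + pseudocount)
        P_now <- r_now * pool[k]; P_prev <- r_prev * pool[k - 1]
        rho <- (P_now / P_prev)^(1 / dt)
        rho_star <- (pool[k] / pool[k - 1])^(1 / dt)
        phi[[tau]] <- rho / rho_star
      }
      acc <- acc * phi$sel / phi$perm
    }
    s[i] <- acc
  }
  s
}

# pair-counting Mann-Whitney U by explicit double loop
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x < y) + 0.5 * (x == y)
  u
}

# a tiny deterministic barcode library for read-counting tests
toy_barcode_library <- function() {
  data.frame(
    barcode = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
    clone_id = c("v1", "v2", "null1", "wt1"),
    genotype = c("c.2:AAA>GAA", "c.3:TGG>TAG", "", ""),
    control_class = c("variant", "variant", "null_control", "wt_control"),
    stringsAsFactors = FALSE)
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(sprintf("@read%d", i), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  path
}

# deterministic toy ORF used across tests: M K W L R V *
toy_orf <- function() orf_sequence("toy", "ATGAAATGGCTGCGCGTGTAA")
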