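# build a count table directly, with two replicates everywhere
make_table <- function(variants, depth = 1e6) {
  conds <- c("nonselect", "select", "wtctrl")
  counts <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    data.frame(codon_index = v$codon_index, wt_codon = v$wt_codon,
               mut_codon = v$mut_codon,
               condition = rep(conds, each = 2), replicate = rep(1:2, 3),
               count = c(v$ns1, v$ns2, v$s1, v$s2, v$w1, v$w2),
               stringsAsFactors = FALSE)
  }))
  pos <- unique(variants$codon_index)
  depths <- expand.grid(codon_index = pos, condition = conds,
                        replicate = 1:2, stringsAsFactors = FALSE)
  depths$depth <- depth
  codon_count_table(counts, depths)
}

test_that("codon calls require agreement of both mates", {
  orf <- toy_orf()  # ATG AAA TGG CTG CGC GTG TAA
  tiles <- tile_definitions(2, 6)
  ref <- substr(orf$nucleotides, 4, 18)
  mut <- ref; substr(mut, 1, 3) <- "GAA"   # K2E at tile offset 1
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # pair 1: both mates mutant; pair 2: mate1 mutant, mate2 wild-type
  fq1 <- write_fastq(c(mut, mut, ref))
  fq2 <- write_fastq(c(rc(mut), rc(ref), rc(ref)))
  cc <- call_codon_changes(fq1, fq2, orf, tiles)
  expect_equal(nrow(cc$counts), 1)
  expect_equal(cc$counts$count, 1)
  expect_equal(cc$counts$mut_codon, "GAA")
  expect_equal(cc$counts$codon_index, 2)
  expect_true(all(cc$depth$depth[cc$depth$codon_index %in% 2:6] == 3))
  # single-mate mode counts the discordant pair too
  cs <- call_codon_changes(fq1, fq2, orf, tiles, require_both_mates = FALSE)
  expect_equal(cs$counts$count, 2)
  # mate length mismatch errors
  expect_error(call_codon_changes(write_fastq("ACGTAA"), write_fastq("ACG"),
                                  orf, tiles), "length")
})

test_that("an error-free 1% variant fixture counts exactly", {
  orf <- toy_orf()
  tiles <- tile_definitions(2, 6)
  ref <- substr(orf$nucleotides, 4, 18)
  mut <- ref; substr(mut, 4, 6) <- "TCG"   # W3S
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  reads <- c(rep(mut, 10), rep(ref, 990))
  cc <- call_codon_changes(write_fastq(reads),
                           write_fastq(vapply(reads, rc, "")), orf, tiles)
  expect_equal(cc$counts$count, 10)
  expect_equal(unique(cc$depth$depth[cc$depth$codon_index %in% 2:6]), 1000)
})

test_that("the low-input filter applies the three-sigma control rule", {
  # wtctrl mean 5e-6 with replicate sd 1e-6 (Poisson floor is smaller)
  v <- data.frame(codon_index = 2, wt_codon = "AAA", mut_codon = "GAA",
                  ns1 = 7, ns2 = 7, s1 = 5, s2 = 5, w1 = 4, w2 = 6)
  tab <- make_table(v, depth = 1e6)
  flt <- filter_low_input(tab)
  expect_false(flt$keep)  # 7e-6 <= 5e-6 + 3*~1.3e-6? no: sd floor...
  v2 <- v; v2$ns1 <- 20; v2$ns2 <- 20
  expect_true(filter_low_input(make_table(v2))$keep)
  # all-zero control with positive input is kept (floored sd)
  v3 <- v; v3$w1 <- 0; v3$w2 <- 0; v3$ns1 <- 50; v3$ns2 <- 50
  expect_true(filter_low_input(make_table(v3))$keep)
  # filtering on the selective condition is available
  v4 <- v; v4$ns1 <- 100; v4$ns2 <- 100; v4$s1 <- 5; v4$s2 <- 5
  expect_true(filter_low_input(make_table(v4), "nonselect")$keep)
  expect_false(filter_low_input(make_table(v4), "select")$keep)
})

test_that("enrichment ratios follow the subtraction arithmetic", {
  # f_ns = 1e-4, f_wt = 5e-6, f_sel = 6e-5 -> E = 5.5/9.5 = 0.579
  v <- data.frame(codon_index = 2, wt_codon = "AAA", mut_codon = "GAA",
                  ns1 = 100, ns2 = 100, s1 = 60, s2 = 60, w1 = 5, w2 = 5)
  sc <- tileseq_score(make_table(v, depth = 1e6))
  expect_false(sc$filtered)
  expect_equal(sc$E, (6e-5 - 5e-6) / (1e-4 - 5e-6), tolerance = 1e-12)
  expect_equal(sc$E, 0.579, tolerance = 1e-3)
  expect_equal(sc$df, 2)
  # full depletion: f_sel == f_wt -> E at the epsilon floor, ~0
  v2 <- v; v2$s1 <- 5; v2$s2 <- 5
  sc2 <- tileseq_score(make_table(v2))
  expect_lt(sc2$E, 0.01)
  # no selection effect with clean control: E = 1
  v3 <- v; v3$s1 <- 100; v3$s2 <- 100; v3$w1 <- 0; v3$w2 <- 0
  sc3 <- tileseq_score(make_table(v3))
  expect_equal(sc3$E, 1, tolerance = 1e-12)
  # amino-acid consequence derived from the codons
  expect_equal(sc$wt_aa, "K"); expect_equal(sc$mut_aa, "E")
  expect_equal(sc$type, "missense")
})

test_that("enrichment is invariant to condition-wide depth scaling", {
  v <- data.frame(codon_index = c(2, 3), wt_codon = c("AAA", "TGG"),
                  mut_codon = c("GAA", "TAG"),
                  ns1 = c(200, 150), ns2 = c(190, 160),
                  s1 = c(100, 3), s2 = c(110, 4), w1 = c(2, 1),
                  w2 = c(3, 2))
  tab1 <- make_table(v, depth = 1e6)
  # scale nonselect replicate 1 by 5x (counts and depth together)
  tab2 <- tab1
  pick <- tab2$counts$condition == "nonselect" & tab2$counts$replicate == 1
  tab2$counts$count[pick] <- tab2$counts$count[pick] * 5
  dpick <- tab2$depths$condition == "nonselect" & tab2$depths$replicate == 1
  tab2$depths$depth[dpick] <- tab2$depths$depth[dpick] * 5
  s1 <- tileseq_score(tab1); s2 <- tileseq_score(tab2)
  expect_equal(s2$E, s1$E, tolerance = 1e-9)
})

test_that("anchoring pins nonsense to 0 and synonymous to 1 exactly", {
  set.seed(51)
  n <- 30
  types <- rep(c("nonsense", "synonymous", "missense"), each = n)
  E <- c(rnorm(n, 0.05, 0.02), rnorm(n, 1.4, 0.1), runif(n, 0, 1.5))
  sc <- data.frame(codon_index = seq_along(E), wt_codon = "AAA",
                   mut_codon = "GAA", position = seq_along(E),
                   wt_aa = "K", mut_aa = "E", type = types, E = E,
                   sd = 0.1, df = 2, filtered = FALSE, reason = "")
  an <- anchor_scores(sc)
  expect_identical(median(an$score[an$type == "nonsense"]), 0)
  expect_identical(median(an$score[an$type == "synonymous"]), 1)
  # linear: halfway E maps to 0.5
  mid <- (median(E[types == "nonsense"]) + median(E[types == "synonymous"])) / 2
  an2 <- anchor_scores(rbind(sc, transform(sc[1, ], E = mid, type = "missense")))
  expect_equal(an2$score[nrow(an2)], 0.5, tolerance = 1e-12)
  # degenerate anchors error
  sc3 <- sc; sc3$E <- 1
  expect_error(anchor_scores(sc3), "dynamic range")
  # too few anchors error
  expect_error(anchor_scores(sc[c(1:3, 31:60, 61:90), ]), ">= 5")
})

test_that("both-mate agreement suppresses independent base errors", {
  # pure wild-type template: every call is a sequencing error
  for (eps in c(0.01, 0.001)) {
    cfg <- sim_config(L = 25, n_clones = 1, tileseq_depth = 4e5,
                      base_error = eps, template_error = 0, seed = 19)
    set.seed(cfg$seed)
    orf <- dmsmap:::simulate_orf(cfg$L)
    wtlib <- data.frame(barcode = NA, clone_id = "wt", genotype = "",
                        control_class = "wt_control", fitness = 1)
    both <- simulate_tileseq(cfg, wtlib, orf, mate_mode = "both")
    single <- simulate_tileseq(cfg, wtlib, orf, mate_mode = "single")
    rate_both <- sum(both$counts$count) / sum(both$depths$depth)
    rate_single <- sum(single$counts$count) / sum(single$depths$depth)
    expect_gt(rate_single / max(rate_both, 1e-12), 10)
  }
})

test_that("simulated TileSeq screens recover true variant scores", {
  cfg <- sim_config(L = 40, n_clones = 12000, tileseq_depth = 1e6, seed = 23)
  sim <- simulate_library(cfg, mode = "tileseq")
  tab <- simulate_tileseq(cfg, sim$library, sim$orf)
  an <- anchor_scores(tileseq_score(tab))
  aam <- collapse_to_aa(an, gene = "sim")
  tkey <- format_variant_string(sim$truth$wt_aa, sim$truth$position,
                                sim$truth$mut_aa)
  akey <- format_variant_string(aam$wt_aa, aam$position, aam$mut_aa)
  idx <- match(akey, tkey)
  expect_true(all(!is.na(idx)))  # every scored variant exists in the truth
  expect_gt(cor(aam$score, sim$truth$true_score[idx]), 0.9)
})
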