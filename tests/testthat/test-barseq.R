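make_sheet <- function(timepoints, reps, pool = NULL) {
  sm <- expand.grid(timepoint_h = timepoints,
                    temperature = c("permissive", "selective"),
                    replicate = seq_len(reps), stringsAsFactors = FALSE)
  sm$pool_size <- if (is.null(pool)) 1e6 else pool
  sm
}

test_that("barcode counting assigns exact, rescuable and ambiguous reads", {
  lib <- toy_barcode_library()
  sheet <- data.frame(tag = c("ACGT", "TGCA"), timepoint_h = c(0, 12),
                      temperature = "selective", replicate = 1,
                      pool_size = 1e5, stringsAsFactors = FALSE)
  # 100 exact reads distributed over tags and barcodes
  reads <- paste0(rep(sheet$tag, each = 50),
                  rep(lib$barcode, length.out = 100))
  counts <- count_barcodes(write_fastq(reads), lib, sheet)
  expect_equal(sum(counts$counts), 100)
  expect_equal(counts$unmatched, 0)
  # Hamming-1 rescue to a unique barcode
  one_off <- paste0("ACGT", "AAAAAAAAAT")
  c2 <- count_barcodes(write_fastq(one_off), lib, sheet)
  expect_equal(c2$counts["AAAAAAAAAA", 1], 1, ignore_attr = TRUE)
  expect_equal(c2$unmatched, 0)
  # equidistant to two barcodes -> unmatched
  lib2 <- lib
  lib2$barcode[2] <- "AAAAAAAACC"  # distance 2 from barcode 1
  amb <- paste0("ACGT", "AAAAAAAAAC")  # distance 1 from both
  c3 <- count_barcodes(write_fastq(amb), lib2, sheet)
  expect_equal(sum(c3$counts), 0)
  expect_equal(c3$unmatched, 1)
  expect_error(count_barcodes(write_fastq(reads), lib,
                              rbind(sheet, sheet)), "duplicate")
})

test_that("Bayesian variance regularization matches direct arithmetic", {
  expect_equal(regularize_sd(0.2, n = 3, prior_sd = 0.3, v0 = 3),
               sqrt((3 * 0.09 + 2 * 0.04) / 4), tolerance = 1e-12)
  expect_equal(regularize_sd(0.2, 3, 0.3, 3), 0.2958, tolerance = 1e-4)
  expect_equal(regularize_sd(0.3, 3, 0.3, 3), sqrt(5 * 0.09 / 4),
               tolerance = 1e-12)
  expect_equal(regularize_sd(0.3, 3, 0.3, 3), 0.3354, tolerance = 1e-4)
  # strictly increasing in the empirical sd
  s <- seq(0.05, 0.5, by = 0.05)
  out <- regularize_sd(s, 3, 0.3, 3)
  expect_true(all(diff(out) > 0))
  expect_error(regularize_sd(0.2, 2, 0.3, v0 = 0), "denominator")
})

test_that("the sd prior regression recovers exact linear structure", {
  set.seed(12)
  n <- 40
  cnt <- 10^runif(n, 1, 4)
  sp <- runif(n)
  sd_emp <- 0.3 - 0.05 * log10(cnt + 1) + 0.1 * sp
  pred <- fit_sd_prior(sd_emp, cnt, sp, floor = 1e-6)
  expect_equal(pred, sd_emp, tolerance = 1e-8, ignore_attr = TRUE)
  # floor clamps low predictions
  pred2 <- fit_sd_prior(sd_emp, cnt, sp, floor = 0.2)
  expect_true(all(pred2 >= 0.2))
  expect_error(fit_sd_prior(sd_emp[1:5], cnt[1:5], sp[1:5]), ">= 10")
})

test_that("the fitness equation chain matches step-by-step evaluation", {
  # micro-instance: 4 clones (variant, null, 2x wt), 2 timepoints, 1 rep
  lib <- toy_barcode_library()
  lib$control_class <- c("variant", "null_control", "wt_control",
                         "wt_control")
  tp <- c(0, 12)
  cperm <- rbind(c(100, 210), c(100, 190), c(100, 205), c(100, 200))
  csel <- rbind(c(100, 40), c(100, 2), c(100, 410), c(100, 390))
  pool_perm <- c(4e5, 8e5)
  pool_sel <- c(4e5, 6.5e5)
  sm <- rbind(
    data.frame(timepoint_h = tp, temperature = "permissive", replicate = 1,
               pool_size = pool_perm),
    data.frame(timepoint_h = tp, temperature = "selective", replicate = 1,
               pool_size = pool_sel))
  counts <- barseq_counts(cbind(cperm, csel), sm)
  rownames(counts$counts) <- lib$barcode
  fit <- barseq_fitness(counts, lib, regularize = FALSE)
  s_oracle <- oracle_barseq_s(cperm, csel, pool_perm, pool_sel, tp)
  expect_equal(fit$s, s_oracle, tolerance = 1e-12)
  s_null <- s_oracle[2]; s_wt <- median(s_oracle[3:4])
  expect_equal(fit$s_prime, (s_oracle - s_null) / (s_wt - s_null),
               tolerance = 1e-12)
})

test_that("clones tracking controls score 0 and 1 and anchors are exact", {
  set.seed(13)
  lib <- data.frame(
    barcode = replicate(12, paste(sample(c("A","C","G","T"), 10, TRUE),
                                  collapse = "")),
    clone_id = sprintf("c%02d", 1:12),
    genotype = c(rep("c.2:AAA>GAA", 4), rep("", 8)),
    control_class = rep(c("variant", "null_control", "wt_control"),
                        each = 4), stringsAsFactors = FALSE)
  sm <- make_sheet(c(0, 6, 12), reps = 2)
  # wt-like growth for wt controls and clones 1-2; null-like for the rest
  base <- matrix(0, 12, nrow(sm))
  for (s in seq_len(nrow(sm))) {
    t <- sm$timepoint_h[s]
    grow_wt <- 2^(0.5 * t); grow_null <- 2^(0.05 * t)
    sel <- sm$temperature[s] == "selective"
    g <- c(rep(if (sel) grow_wt else grow_wt, 2),   # variant clones 1-2: wt-like
           rep(if (sel) grow_null else grow_wt, 2), # variant clones 3-4: null-like
           rep(if (sel) grow_null else grow_wt, 4), # null controls
           rep(grow_wt, 4))                         # wt controls
    base[, s] <- 1000 * g
    sm$pool_size[s] <- sum(base[, s])
  }
  rownames(base) <- lib$barcode
  counts <- barseq_counts(base, sm)
  fit <- barseq_fitness(counts, lib, pseudocount = 0, regularize = FALSE)
  expect_equal(fit$s_prime[1:2], c(1, 1), tolerance = 1e-9)
  expect_equal(fit$s_prime[3:4], c(0, 0), tolerance = 1e-9)
  # control medians are exactly anchored within each replicate
  sp <- attr(fit, "replicate_s_prime")
  for (r in 1:2) {
    expect_identical(median(sp[lib$control_class == "null_control", r]), 0)
    expect_identical(median(sp[lib$control_class == "wt_control", r]), 1)
  }
})

test_that("scores are invariant to per-sample sequencing depth", {
  set.seed(14)
  cfg <- sim_config(L = 30, n_clones = 60, n_null = 10, n_wt = 10,
                    barseq_depth = 1e5, seed = 5)
  sim <- simulate_library(cfg, mode = "barseq")
  counts <- simulate_barseq(cfg, sim$library)
  fit1 <- barseq_fitness(counts, sim$library, regularize = FALSE)
  scaled <- counts
  scaled$counts[, 3] <- scaled$counts[, 3] * 17  # one sample upscaled
  fit2 <- barseq_fitness(scaled, sim$library, regularize = FALSE)
  # invariance is exact up to the fixed 0.5 pseudocount added to raw counts
  expect_equal(fit2$s_prime, fit1$s_prime, tolerance = 1e-4)
  # without the pseudocount the invariance is exact (zero-free counts)
  exact <- simulate_barseq(cfg, sim$library, exact = TRUE)
  fit1p <- barseq_fitness(exact, sim$library, pseudocount = 0,
                          regularize = FALSE)
  scaled2 <- exact
  scaled2$counts[, 3] <- scaled2$counts[, 3] * 17
  fit2p <- barseq_fitness(scaled2, sim$library, pseudocount = 0,
                          regularize = FALSE)
  expect_equal(fit2p$s_prime, fit1p$s_prime, tolerance = 1e-12)
})

test_that("single-mutant aggregation is inverse-variance weighted", {
  lib <- data.frame(
    barcode = c("A", "C", "G", "T", "AA"),
    clone_id = paste0("c", 1:5),
    genotype = c("c.2:AAA>GAA", "c.2:AAA>GAG", "c.2:AAA>GAA;c.3:TGG>TCG",
                 "c.3:TGG>AGG", ""),
    control_class = c(rep("variant", 4), "wt_control"),
    stringsAsFactors = FALSE)
  rec <- data.frame(clone_id = lib$clone_id,
                    s_prime = c(0.4, 0.6, 0.9, 0.2, 1),
                    se = c(0.1, 0.1, 0.1, 0.1, 0.1), df = 3)
  agg <- aggregate_single_mutants(rec, lib)
  # clones 1+2 both encode K2E via different codons: equal weights -> 0.5
  expect_equal(agg$score[agg$position == 2 & agg$mut_aa == "E"], 0.5)
  # the double mutant (clone 3) is excluded; W3R has one clone
  expect_equal(agg$score[agg$position == 3], 0.2)
  expect_equal(agg$n_clones, c(2, 1))
  # unequal weights: w ~ 1/se^2
  rec2 <- rec; rec2$s_prime[1:2] <- c(0.2, 0.8); rec2$se[1:2] <- c(0.1, 0.4)
  agg2 <- aggregate_single_mutants(rec2, lib)
  expect_equal(agg2$score[agg2$position == 2],
               (0.2 / 0.01 + 0.8 / 0.16) / (1 / 0.01 + 1 / 0.16),
               tolerance = 1e-12)
  expect_equal(agg2$score[agg2$position == 2], 25 / 106.25,
               tolerance = 1e-12)
})

test_that("simulated BarSeq screens recover true clone fitness", {
  cfg <- sim_config(L = 40, n_clones = 400, n_null = 20, n_wt = 20,
                    barseq_depth = 5e5, seed = 17)
  sim <- simulate_library(cfg, mode = "barseq")
  counts <- simulate_barseq(cfg, sim$library)
  fit <- barseq_fitness(counts, sim$library)
  v <- fit$control_class == "variant"
  expect_gt(cor(fit$s_prime[v], sim$library$fitness[v]), 0.9)
  # regularized sd is positive and se consistent
  expect_true(all(fit$sd_reg > 0))
  expect_equal(fit$se, fit$sd_reg / sqrt(fit$df))
  # noiseless infinite-depth limit recovers fitness exactly
  exact <- simulate_barseq(cfg, sim$library, exact = TRUE)
  fe <- barseq_fitness(exact, sim$library, pseudocount = 0,
                       regularize = FALSE)
  expect_lt(max(abs(fe$s_prime - sim$library$fitness)), 1e-6)
})
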