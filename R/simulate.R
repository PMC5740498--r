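# Synthetic ground truth for every scoring stage: a random ORF, a clone
# library with Poisson-distributed codon changes drawn from the NNK set,
# growth-competition dynamics for BarSeq, and an error-model readout for
# TileSeq. True variant effects follow a bimodal mixture (deleterious scores
# near 0, neutral scores near 1) and clone fitness is multiplicative across
# the clone's variants.

#' Simulation configuration
#'
#' Defaults describe a typical pooled complementation screen: clones average
#' `lambda = 2.1` codon changes; a fraction `p_del` of missense variants is
#' deleterious with scores drawn from Beta(0.5, 5), the rest neutral with
#' scores from Normal(1, 0.05) truncated at 0 (values above 1 model
#' hypercomplementation); synonymous variants are fixed at 1 and nonsense at
#' 0. Selective-temperature growth runs from `g_null` to `g_wt` doublings per
#' hour; the permissive condition grows every clone at `g_wt`. BarSeq samples
#' three replicates at five timepoints over 48 h; TileSeq compares two
#' replicates each of non-selective, selective and wild-type-control
#' libraries.
#'
#' @param L Protein length in residues (codons excluding the stop).
#' @param n_clones Number of variant clones.
#' @param lambda Mean amino-acid changes per clone (Poisson).
#' @param p_del Fraction of missense variants that are deleterious.
#' @param neutral_sd SD of the neutral score distribution.
#' @param g_wt,g_null Wild-type and null growth rates at the selective
#'   temperature (doublings/hour).
#' @param timepoints_h BarSeq sampling times in hours (first must be 0).
#' @param n_reps BarSeq replicates.
#' @param barseq_depth Reads per BarSeq sample.
#' @param n_null,n_wt Numbers of null / wild-type control clones (BarSeq).
#' @param od_noise_sd Log-scale SD of the lognormal noise on pool-size (OD)
#'   estimates.
#' @param tileseq_depth Read pairs per tile and condition/replicate.
#' @param t_select_h Hours of selective growth for the TileSeq competition.
#' @param base_error Per-base, per-mate sequencing error rate.
#' @param template_error Per-base template (PCR/plasmid) error rate, shared
#'   by both mates.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(L = 50L, n_clones = 20000L, lambda = 2.1,
                       p_del = 0.4, neutral_sd = 0.05,
                       g_wt = 0.5, g_null = 0.05,
                       timepoints_h = c(0, 6, 12, 24, 48), n_reps = 3L,
                       barseq_depth = 1e6, n_null = 50L, n_wt = 50L,
                       od_noise_sd = 0.02, tileseq_depth = 2e6,
                       t_select_h = 48, base_error = 1e-3,
                       template_error = 1e-5, seed = 7L) {
  stopifnot(g_null > 0, g_null < g_wt, lambda > 0, barseq_depth > 0,
            tileseq_depth > 0, timepoints_h[1L] == 0,
            all(diff(timepoints_h) > 0))
  structure(list(L = as.integer(L), n_clones = as.integer(n_clones),
                 lambda = lambda, p_del = p_del, neutral_sd = neutral_sd,
                 g_wt = g_wt, g_null = g_null, timepoints_h = timepoints_h,
                 n_reps = as.integer(n_reps), barseq_depth = barseq_depth,
                 n_null = as.integer(n_null), n_wt = as.integer(n_wt),
                 od_noise_sd = od_noise_sd, tileseq_depth = tileseq_depth,
                 t_select_h = t_select_h, base_error = base_error,
                 template_error = template_error, seed = as.integer(seed)),
            class = "sim_config")
}

#' Probability of more than one amino-acid change per clone
#'
#' Under Poisson-distributed change counts with mean `lambda`, the fraction
#' of clones carrying more than one change is
#' `1 - exp(-lambda) - lambda*exp(-lambda)`.
#'
#' @param lambda Mean changes per clone (>= 0).
#' @return Probability in `[0, 1)`.
#' @examples
#' multi_mutant_fraction(2.1)  # ~0.62
#' @export
multi_mutant_fraction <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  1 - exp(-lambda) - lambda * exp(-lambda)
}

# random ORF: ATG + (L-1) sense codons + TAA
simulate_orf <- function(L, id = "simgene") {
  code <- genetic_code()
  sense <- names(code)[code != "*" & names(code) != "ATG"]
  body <- sample(sense, L - 1L, replace = TRUE)
  orf_sequence(id, paste0("ATG", paste(body, collapse = ""), "TAA"))
}

random_barcodes <- function(n, len = 25L) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

draw_true_score <- function(type, cfg) {
  if (type == "synonymous") return(1)
  if (type == "nonsense") return(0)
  if (runif(1) < cfg$p_del) rbeta(1, 0.5, 5)
  else max(0, rnorm(1, 1, cfg$neutral_sd))
}

#' Simulate a mutagenized clone library with ground truth
#'
#' Each clone receives Poisson-distributed codon changes at uniform codon
#' positions (excluding the initiator and stop), with mutant codons drawn
#' uniformly from the NNK set minus the wild-type codon. The codon-change
#' rate is calibrated so that amino-acid changes per clone average `lambda`
#' (synonymous NNK draws dilute the codon rate). In `"barseq"` mode
#' clones are resampled until they carry at least one amino-acid change (the
#' arrayed library retains only such clones), barcodes are attached, and
#' null/wild-type control clones appended. Clone fitness is the product of
#' its variants' true scores, clipped at 0.
#'
#' @param cfg A [sim_config()].
#' @param mode `"barseq"` (truncated, barcoded, with controls) or
#'   `"tileseq"` (untruncated pool).
#' @param orf Optional [orf_sequence()]; generated from the seed when absent.
#' @return list with `orf`, `library` (data.frame `barcode`, `clone_id`,
#'   `genotype`, `control_class`, `fitness`) and `truth` (data.frame
#'   `position`, `wt_aa`, `mut_aa`, `type`, `true_score`).
#' @export
simulate_library <- function(cfg, mode = c("barseq", "tileseq"), orf = NULL) {
  mode <- match.arg(mode)
  set.seed(cfg$seed)
  if (is.null(orf)) orf <- simulate_orf(cfg$L)
  code <- genetic_code()
  wt_codons <- orf_codons(orf$nucleotides)
  target <- seq(2L, cfg$L)            # mutagenized codons (skip Met1, stop)
  nnk <- nnk_table()$codon
  n <- cfg$n_clones

  # lambda counts amino-acid changes per clone; some NNK codon draws are
  # synonymous, so the codon-change rate is inflated by the ORF-wide mean
  # probability that a uniform non-wild-type NNK draw changes the residue
  p_nonsyn <- mean(vapply(target, function(p) {
    alt <- setdiff(nnk, wt_codons[p])
    mean(code[alt] != code[[wt_codons[p]]])
  }, 0))
  lambda_codon <- cfg$lambda / p_nonsyn

  # draw change counts, positions (distinct within a clone, by rejection)
  # and NNK mutant codons (!= wild type, by rejection) for all clones at once
  k <- numeric(n); need <- seq_len(n)
  changes <- data.frame(clone = integer(0), pos = integer(0),
                        mut = character(0), stringsAsFactors = FALSE)
  repeat {
    kk <- pmin(rpois(length(need), lambda_codon), length(target))
    k[need] <- kk
    clone_of <- rep(need, kk)
    m <- sum(kk)
    pos <- integer(m); mut <- character(m)
    todo <- seq_len(m)
    repeat {                       # distinct positions within each clone
      pos[todo] <- sample(target, length(todo), replace = TRUE)
      dup <- tapply(pos, clone_of, anyDuplicated)
      bad_clones <- as.integer(names(dup))[dup > 0L]
      todo <- which(clone_of %in% bad_clones)
      if (!length(todo)) break
    }
    todo <- seq_len(m)
    repeat {                       # mutant codon from NNK, != wt codon
      mut[todo] <- nnk[sample.int(32L, length(todo), replace = TRUE)]
      todo <- which(mut == wt_codons[pos])
      if (!length(todo)) break
    }
    new_changes <- data.frame(clone = clone_of, pos = pos, mut = mut,
                              stringsAsFactors = FALSE)
    changes <- rbind(changes[!(changes$clone %in% need), , drop = FALSE],
                     new_changes)
    if (mode != "barseq") break
    # truncation: clones must carry at least one amino-acid change
    aa_change <- code[new_changes$mut] != code[wt_codons[new_changes$pos]]
    n_aa <- setNames(rep(0L, length(need)), need)
    got <- tapply(aa_change, new_changes$clone, sum)
    n_aa[names(got)] <- got
    need <- as.integer(names(n_aa))[n_aa == 0L]
    if (!length(need)) break
  }
  changes <- changes[order(changes$clone, changes$pos), , drop = FALSE]

  # ground truth per unique amino-acid variant
  ch_wt_aa <- unname(code[wt_codons[changes$pos]])
  ch_mut_aa <- unname(code[changes$mut])
  ch_type <- ifelse(ch_mut_aa == "*", "nonsense",
                    ifelse(ch_mut_aa == ch_wt_aa, "synonymous", "missense"))
  ch_key <- paste0(ch_wt_aa, changes$pos,
                   ifelse(ch_mut_aa == ch_wt_aa, "=", ch_mut_aa))
  first <- !duplicated(ch_key)
  truth_df <- data.frame(position = changes$pos[first],
                         wt_aa = ch_wt_aa[first], mut_aa = ch_mut_aa[first],
                         type = ch_type[first], stringsAsFactors = FALSE)
  nmiss <- sum(truth_df$type == "missense")
  miss_scores <- ifelse(runif(nmiss) < cfg$p_del, rbeta(nmiss, 0.5, 5),
                        pmax(0, rnorm(nmiss, 1, cfg$neutral_sd)))
  truth_df$true_score <- ifelse(truth_df$type == "synonymous", 1,
                                ifelse(truth_df$type == "nonsense", 0, NA))
  truth_df$true_score[truth_df$type == "missense"] <- miss_scores

  # clone genotype strings and multiplicative fitness
  score_of <- setNames(truth_df$true_score, ch_key[first])
  ch_score <- unname(score_of[ch_key])
  fitness <- rep(1, n)
  if (nrow(changes)) {
    fprod <- tapply(ch_score, changes$clone, prod)
    fitness[as.integer(names(fprod))] <- pmax(0, fprod)
    gstr <- tapply(sprintf("c.%d:%s>%s", changes$pos,
                           wt_codons[changes$pos], changes$mut),
                   changes$clone, paste, collapse = ";")
    genotypes <- rep("", n)
    genotypes[as.integer(names(gstr))] <- gstr
  } else genotypes <- rep("", n)
  lib <- data.frame(clone_id = sprintf("clone%05d", seq_len(n)),
                    genotype = genotypes, control_class = "variant",
                    fitness = fitness, stringsAsFactors = FALSE)
  if (mode == "barseq") {
    ctrl <- data.frame(
      clone_id = c(sprintf("null%03d", seq_len(cfg$n_null)),
                   sprintf("wt%03d", seq_len(cfg$n_wt))),
      genotype = "",
      control_class = rep(c("null_control", "wt_control"),
                          c(cfg$n_null, cfg$n_wt)),
      fitness = rep(c(0, 1), c(cfg$n_null, cfg$n_wt)),
      stringsAsFactors = FALSE)
    lib <- rbind(lib, ctrl)
    lib$barcode <- random_barcodes(nrow(lib))
  } else {
    lib$barcode <- NA_character_
  }
  lib <- lib[, c("barcode", "clone_id", "genotype", "control_class",
                 "fitness")]
  truth_df <- truth_df[order(truth_df$position, truth_df$mut_aa), ]
  rownames(truth_df) <- NULL
  list(orf = orf, library = lib, truth = truth_df)
}

# Fitness-to-growth mapping. The cumulative BarSeq score multiplies one
# hourly-rate ratio per scoring interval, so the quantity it recovers is the
# factor 2^(K*g) with K the number of intervals. Mapping fitness linearly
# onto that factor (rather than onto g itself) makes the noiseless pipeline
# recover fitness exactly.
fitness_to_growth <- function(fitness, g_null, g_wt, K) {
  G_null <- 2^(K * g_null); G_wt <- 2^(K * g_wt)
  G <- G_null + fitness * (G_wt - G_null)
  log2(pmax(G, 1e-12)) / K
}

#' Simulate BarSeq counts from a clone library
#'
#' Clone populations grow as `P(t) = P0 * 2^(g*t)`: at the permissive
#' temperature every clone grows at `g_wt`; at the selective temperature a
#' clone's rate interpolates between `g_null` and `g_wt` according to its
#' fitness (see package vignette for the exact mapping). Per sample, barcode
#' counts are multinomial draws of `barseq_depth` reads from the population
#' proportions, and reported pool sizes are the true totals perturbed by
#' lognormal OD noise.
#'
#' @param cfg A [sim_config()].
#' @param library Library data.frame from [simulate_library()] (barseq
#'   mode).
#' @param exact Use infinite-depth, noise-free counts (exact proportions;
#'   for deterministic-limit checks).
#' @return A [barseq_counts()] object.
#' @export
simulate_barseq <- function(cfg, library, exact = FALSE) {
  set.seed(cfg$seed + 1L)
  tp <- cfg$timepoints_h
  K <- length(tp) - 1L
  n <- nrow(library)
  g_sel <- fitness_to_growth(library$fitness, cfg$g_null, cfg$g_wt, K)
  g_perm <- rep(cfg$g_wt, n)
  P0 <- rep(100, n)
  samples <- expand.grid(timepoint_h = tp,
                         temperature = c("permissive", "selective"),
                         replicate = seq_len(cfg$n_reps),
                         stringsAsFactors = FALSE)
  counts <- matrix(0, n, nrow(samples), dimnames = list(library$barcode, NULL))
  pool <- numeric(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    g <- if (samples$temperature[s] == "selective") g_sel else g_perm
    P <- P0 * 2^(g * samples$timepoint_h[s])
    tot <- sum(P)
    noise <- if (exact) 1 else rlnorm(1, 0, cfg$od_noise_sd)
    pool[s] <- tot * noise
    counts[, s] <- if (exact) P / tot * 1e9 else
      as.numeric(rmultinom(1L, cfg$barseq_depth, P / tot))
  }
  samples$pool_size <- pool
  barseq_counts(counts, samples)
}

# single-base codon neighbors of a codon
codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) for (b in bases) {
    if (substr(codon, p, p) == b) next
    nb <- codon; substr(nb, p, p) <- b
    out <- c(out, nb)
  }
  out
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Simulate a TileSeq codon count table
#'
#' Computes exact per-codon template frequencies for the non-selective pool
#' (uniform clone representation), the selective pool (clone representation
#' reweighted by the fitness-dependent growth factor over `t_select_h`
#' hours), and a pure wild-type control; then draws binomial read-pair
#' counts under the sequencing error model. A template codon is carried by
#' both mates; template (PCR/plasmid) errors at per-base rate
#' `template_error` are shared by the mates and therefore survive both-mate
#' agreement, while per-mate base-call errors at rate `base_error` must
#' coincide in both mates to produce a call, suppressing them quadratically.
#' Set `mate_mode = "single"` to emulate counting from one mate only (error
#' suppression comparisons).
#'
#' @param cfg A [sim_config()].
#' @param library Library data.frame from [simulate_library()] (tileseq
#'   mode).
#' @param orf The simulated [orf_sequence()].
#' @param mate_mode `"both"` (default) or `"single"`.
#' @return A [codon_count_table()].
#' @export
simulate_tileseq <- function(cfg, library, orf, mate_mode = c("both",
                                                              "single")) {
  mate_mode <- match.arg(mate_mode)
  set.seed(cfg$seed + 2L)
  wt_codons <- orf_codons(orf$nucleotides)
  target <- seq(2L, cfg$L)
  eps <- cfg$base_error; eps_t <- cfg$template_error
  # selective-condition clone weights: linear-in-fitness growth factor
  G_null <- 2^(cfg$g_null * cfg$t_select_h)
  G_wt <- 2^(cfg$g_wt * cfg$t_select_h)
  w_sel <- G_null + library$fitness * (G_wt - G_null)
  q <- list(nonselect = rep(1 / nrow(library), nrow(library)),
            select = w_sel / sum(w_sel))
  # per-codon variant template frequencies from clone genotypes
  geno <- lapply(library$genotype, parse_genotype)
  freq <- list(nonselect = list(), select = list())
  for (i in seq_along(geno)) {
    g <- geno[[i]]
    if (!nrow(g)) next
    for (j in seq_len(nrow(g))) {
      key <- paste0(g$codon_index[j], ":", g$mut_codon[j])
      for (cond in names(freq)) {
        cur <- freq[[cond]][[key]]
        freq[[cond]][[key]] <- (if (is.null(cur)) 0 else cur) + q[[cond]][i]
      }
    }
  }
  # observable codons per position: clone variants plus SNV neighbors of wt
  counts <- list(); depths <- list()
  p_read3 <- (1 - eps)^3                 # one mate reads a codon faithfully
  for (ci in target) {
    wt <- wt_codons[ci]
    nb <- codon_neighbors(wt)
    var_keys <- grep(paste0("^", ci, ":"), names(freq$nonselect), value = TRUE)
    var_codons <- sub("^[0-9]+:", "", var_keys)
    all_mut <- union(var_codons, nb)
    d_wt <- vapply(all_mut, codon_hamming, 0, b = wt)
    for (cond in c("nonselect", "select", "wtctrl")) {
      f_var <- setNames(rep(0, length(all_mut)), all_mut)
      if (cond != "wtctrl") {
        keys <- paste0(ci, ":", all_mut)
        have <- keys %in% names(freq[[cond]])
        f_var[have] <- unlist(freq[[cond]][keys[have]])
      }
      f_wt <- 1 - sum(f_var)
      # template errors (shared between mates): wt template mutates into a
      # single-base neighbor at rate eps_t/3 per specific change
      f_tmpl <- f_var * (1 - 3 * eps_t) + f_wt * (eps_t / 3) * (d_wt == 1L)
      f_wt_tmpl <- f_wt * (1 - 3 * eps_t)
      # per-mate misread of wt into this codon
      p_mis <- (eps / 3)^d_wt * (1 - eps)^(3 - d_wt)
      p_call <- if (mate_mode == "both")
        f_tmpl * p_read3^2 + f_wt_tmpl * p_mis^2
      else f_tmpl * p_read3 + f_wt_tmpl * p_mis
      for (rep_i in 1:2) {
        n_k <- rbinom(length(all_mut), cfg$tileseq_depth, pmin(p_call, 1))
        keep <- n_k > 0L
        if (any(keep))
          counts[[length(counts) + 1L]] <- data.frame(
            codon_index = ci, wt_codon = wt, mut_codon = all_mut[keep],
            condition = cond, replicate = rep_i, count = n_k[keep],
            stringsAsFactors = FALSE)
        depths[[length(depths) + 1L]] <- data.frame(
          codon_index = ci, condition = cond, replicate = rep_i,
          depth = cfg$tileseq_depth, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, counts); rownames(counts) <- NULL
  depths <- do.call(rbind, depths); rownames(depths) <- NULL
  codon_count_table(counts, depths)
}

#' Simulate paired TileSeq reads as FASTQ files
#'
#' Generates literal read pairs for a (small) clone pool: each pair samples a
#' clone, builds the template tile sequence from its genotype with shared
#' template errors, then corrupts each mate independently at the per-base
#' error rate. Mate 2 is written reverse-complemented. Intended for
#' exercising [call_codon_changes()] on realistic input; use
#' [simulate_tileseq()] for deep count tables.
#'
#' @param cfg A [sim_config()].
#' @param library,orf From [simulate_library()] (tileseq mode).
#' @param tiles [tile_definitions()] covering the targeted codons.
#' @param n_pairs Read pairs per tile.
#' @param dir Output directory.
#' @param weights Optional clone sampling weights (default uniform).
#' @return Character vector of the two FASTQ paths.
#' @export
simulate_tileseq_reads <- function(cfg, library, orf, tiles,
                                   n_pairs = 2000L, dir = tempdir(),
                                   weights = NULL) {
  set.seed(cfg$seed + 3L)
  nt <- orf$nucleotides
  eps <- cfg$base_error; eps_t <- cfg$template_error
  if (is.null(weights)) weights <- rep(1, nrow(library))
  bases <- c("A", "C", "G", "T")
  corrupt <- function(v, rate) {
    hit <- which(runif(length(v)) < rate)
    if (length(hit))
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
    v
  }
  f1 <- file.path(dir, "sim_R1.fastq"); f2 <- file.path(dir, "sim_R2.fastq")
  con1 <- file(f1, "w"); con2 <- file(f2, "w")
  on.exit({ close(con1); close(con2) })
  rid <- 0L
  geno <- lapply(library$genotype, parse_genotype)
  for (ti in seq_len(nrow(tiles))) {
    span <- tiles$nt_span[ti]
    off <- 3L * (tiles$first_codon[ti] - 1L)
    ref <- strsplit(substr(nt, off + 1L, off + span), "")[[1L]]
    clone_idx <- sample.int(nrow(library), n_pairs, replace = TRUE,
                            prob = weights)
    for (i in seq_len(n_pairs)) {
      tmpl <- ref
      g <- geno[[clone_idx[i]]]
      if (nrow(g)) {
        inside <- g$codon_index >= tiles$first_codon[ti] &
          g$codon_index <= tiles$last_codon[ti]
        for (j in which(inside)) {
          p0 <- 3L * (g$codon_index[j] - tiles$first_codon[ti])
          tmpl[(p0 + 1L):(p0 + 3L)] <- strsplit(g$mut_codon[j], "")[[1L]]
        }
      }
      tmpl <- corrupt(tmpl, eps_t)
      m1 <- paste(corrupt(tmpl, eps), collapse = "")
      m2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(corrupt(tmpl, eps), collapse = ""))))
      rid <- rid + 1L
      q <- strrep("I", span)
      writeLines(c(sprintf("@pair%06d/1", rid), m1, "+", q), con1)
      writeLines(c(sprintf("@pair%06d/2", rid), m2, "+", q), con2)
    }
  }
  c(f1, f2)
}

#' Simulate BarSeq reads as FASTQ
#'
#' Writes tag+barcode reads for exercising [count_barcodes()]: for each
#' sample, `n_reads` reads are drawn from the supplied clone proportions.
#'
#' @param library Barcoded library data.frame.
#' @param sample_sheet Sample sheet with `tag` column.
#' @param n_reads Reads per sample.
#' @param probs Matrix of clone proportions (clones x samples); default
#'   uniform.
#' @param path Output FASTQ path.
#' @param seed Seed.
#' @return `path`.
#' @export
simulate_barseq_reads <- function(library, sample_sheet, n_reads = 1000L,
                                  probs = NULL,
                                  path = tempfile(fileext = ".fastq"),
                                  seed = 1L) {
  set.seed(seed)
  if (is.null(probs))
    probs <- matrix(1 / nrow(library), nrow(library), nrow(sample_sheet))
  con <- file(path, "w"); on.exit(close(con))
  rid <- 0L
  for (s in seq_len(nrow(sample_sheet))) {
    idx <- sample.int(nrow(library), n_reads, replace = TRUE,
                      prob = probs[, s])
    for (i in idx) {
      rid <- rid + 1L
      seq <- paste0(sample_sheet$tag[s], library$barcode[i])
      writeLines(c(sprintf("@r%06d", rid), seq, "+",
                   strrep("I", nchar(seq))), con)
    }
  }
  path
}
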