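# DMS-BarSeq: pooled clones carrying barcoded variant plasmids are grown
# competitively at permissive and selective temperatures; barcode counts at
# successive timepoints reconstruct per-clone growth, and the cumulative
# growth-rate advantage over the pool, normalized between internal null and
# wild-type controls, is the fitness score.

#' Genotype string helpers
#'
#' Clone genotypes are stored in files as semicolon-joined codon changes,
#' e.g. `"c.4:AAA>GAA;c.9:TGG>TTG"`; the empty string denotes a wild-type or
#' null-control insert.
#'
#' @param genotype data.frame with columns `codon_index`, `wt_codon`,
#'   `mut_codon`.
#' @return [format_genotype()]: a single string; [parse_genotype()]: the
#'   data.frame form.
#' @export
format_genotype <- function(genotype) {
  if (is.null(genotype) || nrow(genotype) == 0L) return("")
  paste(sprintf("c.%d:%s>%s", genotype$codon_index, genotype$wt_codon,
                genotype$mut_codon), collapse = ";")
}

#' @rdname format_genotype
#' @param x Genotype string.
#' @export
parse_genotype <- function(x) {
  if (is.na(x) || x == "")
    return(data.frame(codon_index = integer(0), wt_codon = character(0),
                      mut_codon = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^c\\.([0-9]+):([ACGT]{3})>([ACGT]{3})$",
                                 parts))
  if (any(vapply(m, length, 1L) != 4L)) stop("unparseable genotype: ", x)
  data.frame(codon_index = as.integer(vapply(m, `[[`, "", 2L)),
             wt_codon = vapply(m, `[[`, "", 3L),
             mut_codon = vapply(m, `[[`, "", 4L), stringsAsFactors = FALSE)
}

#' Count amino-acid changes per genotype string
#'
#' Vectorized count of non-synonymous codon changes in genotype strings
#' (format of [format_genotype()]).
#'
#' @param genotypes Character vector of genotype strings.
#' @return Integer vector of amino-acid change counts.
#' @export
count_aa_changes <- function(genotypes) {
  parts <- strsplit(genotypes, ";", fixed = TRUE)
  nch <- lengths(parts)
  clone <- rep(seq_along(genotypes), nch)
  x <- unlist(parts, use.names = FALSE)
  clone <- clone[nzchar(x)]
  x <- x[nzchar(x)]
  out <- integer(length(genotypes))
  if (length(x)) {
    code <- genetic_code()
    nc <- nchar(x)
    wt <- substr(x, nc - 6L, nc - 4L)
    mut <- substr(x, nc - 2L, nc)
    nonsyn <- code[wt] != code[mut]
    agg <- tapply(nonsyn, clone, sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# Amino-acid changes (non-synonymous) implied by a genotype string.
genotype_aa_changes <- function(x) {
  g <- parse_genotype(x)
  if (nrow(g) == 0L)
    return(data.frame(position = integer(0), wt_aa = character(0),
                      mut_aa = character(0), stringsAsFactors = FALSE))
  code <- genetic_code()
  out <- data.frame(position = g$codon_index,
                    wt_aa = unname(code[g$wt_codon]),
                    mut_aa = unname(code[g$mut_codon]),
                    stringsAsFactors = FALSE)
  out[out$wt_aa != out$mut_aa, , drop = FALSE]
}

#' Assemble a BarSeq counts object
#'
#' @param counts Integer matrix, one row per library clone (rownames =
#'   barcodes), one column per sample.
#' @param samples data.frame describing the columns: `timepoint_h`,
#'   `temperature` (`"permissive"`/`"selective"`), `replicate`, `pool_size`
#'   (estimated cells on the plate, from OD).
#' @param unmatched Optional count of reads not assigned to any
#'   (sample, clone).
#' @return A `barseq_counts` object.
#' @export
barseq_counts <- function(counts, samples, unmatched = 0L) {
  stopifnot(ncol(counts) == nrow(samples),
            all(samples$temperature %in% c("permissive", "selective")),
            all(samples$pool_size > 0), all(counts >= 0), all(is.finite(counts)))
  for (tau in unique(samples$temperature))
    for (rep in unique(samples$replicate)) {
      tp <- sort(samples$timepoint_h[samples$temperature == tau &
                                       samples$replicate == rep])
      if (length(tp) && (tp[1L] != 0 || any(diff(tp) <= 0)))
        stop("timepoints must start at 0 and strictly increase")
    }
  structure(list(counts = counts, samples = samples,
                 unmatched = as.integer(unmatched)),
            class = "barseq_counts")
}

#' Count sample-tag/barcode combinations in BarSeq reads
#'
#' Each read is expected to carry a sample tag followed by a clone barcode at
#' fixed offsets. Tags are matched exactly; barcodes are matched exactly
#' first, then rescued if within Hamming distance 1 of a unique library
#' barcode. Reads matching no tag, no barcode, or two barcodes equally well
#' are tallied as unmatched.
#'
#' @param fastq Path to a FASTQ file of reads.
#' @param library Barcode library data.frame with columns `barcode`,
#'   `clone_id`, `genotype`, `control_class`.
#' @param sample_sheet data.frame with columns `tag`, `timepoint_h`,
#'   `temperature`, `replicate`, `pool_size`.
#' @return A [barseq_counts()] object.
#' @export
count_barcodes <- function(fastq, library, sample_sheet) {
  if (anyDuplicated(sample_sheet$tag)) stop("duplicate sample tags")
  if (anyDuplicated(library$barcode)) stop("duplicate library barcodes")
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  tag_len <- nchar(sample_sheet$tag[1L])
  bc_len <- nchar(library$barcode[1L])
  stopifnot(all(nchar(sample_sheet$tag) == tag_len),
            all(nchar(library$barcode) == bc_len))
  tags <- substr(reads, 1L, tag_len)
  bcs <- substr(reads, tag_len + 1L, tag_len + bc_len)
  sample_idx <- match(tags, sample_sheet$tag)
  clone_idx <- match(bcs, library$barcode)
  # 1-mismatch rescue for reads with a valid tag but no exact barcode match
  need <- which(!is.na(sample_idx) & is.na(clone_idx))
  if (length(need)) {
    lib_mat <- do.call(rbind, strsplit(library$barcode, ""))
    for (i in need) {
      q <- strsplit(bcs[i], "")[[1L]]
      if (length(q) != bc_len) next
      d <- rowSums(lib_mat != matrix(q, nrow(lib_mat), bc_len, byrow = TRUE))
      hits <- which(d <= 1L)
      if (length(hits) == 1L) clone_idx[i] <- hits
    }
  }
  ok <- !is.na(sample_idx) & !is.na(clone_idx)
  counts <- matrix(0L, nrow(library), nrow(sample_sheet),
                   dimnames = list(library$barcode, NULL))
  if (any(ok)) {
    tab <- table(factor(clone_idx[ok], levels = seq_len(nrow(library))),
                 factor(sample_idx[ok], levels = seq_len(nrow(sample_sheet))))
    counts <- counts + as.integer(tab)
    dim(counts) <- c(nrow(library), nrow(sample_sheet))
    dimnames(counts) <- list(library$barcode, NULL)
  }
  barseq_counts(counts, sample_sheet, unmatched = sum(!ok))
}

#' Bayesian regularization of a replicate standard deviation
#'
#' Shrinks an empirical across-replicate standard deviation toward a prior
#' estimate: `sigma^2 = (v0*sigma0^2 + (n-1)*s^2) / (v0 + n - 2)`, where `v0`
#' is the pseudo-count (degrees of freedom) granted to the prior, `sigma0`
#' the prior standard deviation, `n` the number of replicates and `s` the
#' empirical standard deviation.
#'
#' @param sd_emp Empirical standard deviation(s).
#' @param n Number of replicates.
#' @param prior_sd Prior standard deviation(s).
#' @param v0 Prior pseudo-count (default 3).
#' @return Regularized standard deviation(s).
#' @export
regularize_sd <- function(sd_emp, n, prior_sd, v0 = 3) {
  stopifnot(n >= 2, all(prior_sd > 0))
  if (v0 + n - 2 <= 0) stop("degenerate denominator: v0 + n - 2 <= 0")
  sqrt((v0 * prior_sd^2 + (n - 1) * sd_emp^2) / (v0 + n - 2))
}

#' Regression prior for replicate standard deviations
#'
#' Fits a least-squares regression of the empirical standard deviation on
#' log10 mean permissive-condition barcode count and the fitness score, and
#' returns per-clone prior standard deviations, clamped below at `floor`.
#'
#' @param sd_emp Empirical standard deviations (finite values used for the
#'   fit; at least 10 required).
#' @param mean_permissive_count Mean raw barcode count across permissive
#'   samples per clone.
#' @param s_prime Normalized fitness scores per clone.
#' @param floor Positive lower bound for the returned prior (default 0.001).
#' @return Numeric vector of prior standard deviations (same length as
#'   inputs).
#' @export
fit_sd_prior <- function(sd_emp, mean_permissive_count, s_prime,
                         floor = 1e-3) {
  lc <- log10(mean_permissive_count + 1)
  ok <- is.finite(sd_emp) & is.finite(lc) & is.finite(s_prime)
  if (sum(ok) < 10L) stop("need >= 10 clones with finite sd_emp")
  if (sd(lc[ok]) == 0 && sd(s_prime[ok]) == 0)
    stop("all-identical predictors")
  fit <- lm(sd_emp ~ lc + s_prime, data = data.frame(sd_emp, lc, s_prime),
            subset = ok)
  pred <- predict(fit, newdata = data.frame(lc = lc, s_prime = s_prime))
  pmax(pred, floor)
}

#' BarSeq fitness scores from a growth time course
#'
#' Implements the cumulative growth-rate scoring chain per replicate:
#' relative population share `r = c / sum(c)` (after adding `pseudocount` to
#' every barcode count), absolute population `P = r * P_star`, hourly growth
#' rate `rho = (P_tk / P_tk-1)^(1/(tk - tk-1))`, pool rate `rho_star` from
#' pool totals, fitness advantage `phi = rho / rho_star`, temperature
#' normalization `phi' = phi(selective) / phi(permissive)`, cumulative score
#' `s = prod_k phi'`, and control anchoring
#' `s' = (s - median s_null) / (median s_wt - median s_null)`. Across
#' replicates the mean `s'`, empirical standard deviation and replicate count
#' are reported; standard deviations are then Bayesian-regularized against a
#' regression prior ([fit_sd_prior()], [regularize_sd()]).
#'
#' @param counts A [barseq_counts()] object.
#' @param library Barcode library data.frame (`barcode`, `clone_id`,
#'   `genotype`, `control_class` with values `variant`, `null_control`,
#'   `wt_control`).
#' @param pseudocount Added to every barcode count (default 0.5).
#' @param v0 Prior pseudo-count for [regularize_sd()].
#' @param regularize Set `FALSE` to skip the regularization step (then
#'   `sd_reg = sd_emp`).
#' @return data.frame with one row per clone: `clone_id`, `control_class`,
#'   `s`, `s_prime`, `sd_emp`, `sd_reg`, `se`, `df`, `mean_permissive_count`.
#'   Per-replicate scores and growth intermediates are attached as attributes
#'   `replicate_s_prime` and `intermediates`.
#' @export
barseq_fitness <- function(counts, library, pseudocount = 0.5, v0 = 3,
                           regularize = TRUE) {
  stopifnot(inherits(counts, "barseq_counts"))
  cm <- counts$counts; sm <- counts$samples
  stopifnot(all(c("null_control", "wt_control") %in% library$control_class))
  reps <- sort(unique(sm$replicate))
  n_clone <- nrow(cm)
  s_rep <- matrix(NA_real_, n_clone, length(reps))
  sp_rep <- matrix(NA_real_, n_clone, length(reps))
  intermediates <- vector("list", length(reps))
  for (ri in seq_along(reps)) {
    phi <- list()
    for (tau in c("permissive", "selective")) {
      sel <- which(sm$temperature == tau & sm$replicate == reps[ri])
      sel <- sel[order(sm$timepoint_h[sel])]
      if (length(sel) < 2L) stop("need >= 2 timepoints per condition")
      tp <- sm$timepoint_h[sel]
      c_tau <- cm[, sel, drop = FALSE] + pseudocount
      r <- sweep(c_tau, 2L, colSums(c_tau), "/")
      P <- sweep(r, 2L, sm$pool_size[sel], "*")
      dt <- diff(tp)
      rho <- (P[, -1L, drop = FALSE] / P[, -length(sel), drop = FALSE])^
        rep(1 / dt, each = n_clone)
      ps <- sm$pool_size[sel]
      rho_star <- (ps[-1L] / ps[-length(ps)])^(1 / dt)
      phi[[tau]] <- sweep(rho, 2L, rho_star, "/")
    }
    phi_prime <- phi$selective / phi$permissive
    s <- apply(phi_prime, 1L, prod)
    s_null <- median(s[library$control_class == "null_control"])
    s_wt <- median(s[library$control_class == "wt_control"])
    if (s_wt == s_null) stop("wt and null control medians coincide")
    s_rep[, ri] <- s
    sp_rep[, ri] <- (s - s_null) / (s_wt - s_null)
    intermediates[[ri]] <- list(phi_permissive = phi$permissive,
                                phi_selective = phi$selective,
                                phi_prime = phi_prime)
  }
  n <- length(reps)
  perm_cols <- which(sm$temperature == "permissive")
  out <- data.frame(
    clone_id = library$clone_id,
    control_class = library$control_class,
    s = rowMeans(s_rep),
    s_prime = rowMeans(sp_rep),
    sd_emp = if (n > 1) apply(sp_rep, 1L, sd) else NA_real_,
    df = n,
    mean_permissive_count = rowMeans(cm[, perm_cols, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  if (regularize && n > 1) {
    prior <- fit_sd_prior(out$sd_emp, out$mean_permissive_count, out$s_prime)
    out$sd_reg <- regularize_sd(out$sd_emp, n, prior, v0 = v0)
  } else {
    out$sd_reg <- out$sd_emp
  }
  out$se <- out$sd_reg / sqrt(out$df)
  attr(out, "replicate_s_prime") <- sp_rep
  attr(out, "intermediates") <- intermediates
  out
}

#' Aggregate single-mutant clones into per-variant scores
#'
#' Clones carrying exactly one amino-acid change are biological replicates of
#' that variant; their normalized scores are combined by inverse-variance
#' weighting (`w = 1/se^2`) with combined standard error
#' `sqrt(1 / sum(w))`.
#'
#' @param records Output of [barseq_fitness()].
#' @param library Barcode library data.frame aligned with `records`.
#' @return data.frame with columns `position`, `wt_aa`, `mut_aa`, `score`,
#'   `se`, `df` (summed replicate counts), `n_clones`.
#' @export
aggregate_single_mutants <- function(records, library) {
  stopifnot(nrow(records) == nrow(library))
  keep <- library$control_class == "variant"
  rows <- list()
  for (i in which(keep)) {
    aa <- genotype_aa_changes(library$genotype[i])
    if (nrow(aa) != 1L) next
    key <- format_variant_string(aa$wt_aa, aa$position, aa$mut_aa)
    rows[[length(rows) + 1L]] <-
      cbind(aa, s_prime = records$s_prime[i], se = records$se[i],
            df = records$df[i], key = key, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(position = integer(0), wt_aa = character(0),
                      mut_aa = character(0), score = numeric(0),
                      se = numeric(0), df = numeric(0),
                      n_clones = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  out <- lapply(split(df, df$key), function(g) {
    w <- 1 / g$se^2
    data.frame(position = g$position[1L], wt_aa = g$wt_aa[1L],
               mut_aa = g$mut_aa[1L],
               score = sum(w * g$s_prime) / sum(w),
               se = sqrt(1 / sum(w)), df = sum(g$df),
               n_clones = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
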