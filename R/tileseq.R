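# DMS-TileSeq: variant allele frequencies are read out by deep paired-end
# sequencing of short amplicon tiles. A codon change is only counted when
# both mates of a pair report the identical mutant codon, which suppresses
# independent base-calling errors quadratically. Frequencies are depth-
# normalized, wild-type-control error rates subtracted, and the enrichment
# ratio of adjusted frequencies after vs before selection is the raw score,
# anchored so that nonsense medians sit at 0 and synonymous medians at 1.

#' Tile definitions over an ORF
#'
#' @param first_codon,last_codon 1-based inclusive codon bounds, one entry
#'   per tile. Tiles must be non-overlapping and jointly contiguous.
#' @return data.frame `tile_id`, `first_codon`, `last_codon`, `nt_span`.
#' @export
tile_definitions <- function(first_codon, last_codon) {
  stopifnot(length(first_codon) == length(last_codon),
            all(last_codon >= first_codon))
  o <- order(first_codon)
  first_codon <- first_codon[o]; last_codon <- last_codon[o]
  if (any(first_codon[-1L] <= last_codon[-length(last_codon)]))
    stop("tiles overlap in codon space")
  data.frame(tile_id = seq_along(first_codon), first_codon = first_codon,
             last_codon = last_codon,
             nt_span = 3L * (last_codon - first_codon + 1L))
}

#' Call codon changes supported by both mates of paired reads
#'
#' Reads are compared ungapped to the reference tile at fixed amplicon
#' coordinates: mate 1 is the forward tile sequence, mate 2 its reverse
#' complement. A pair is assigned to the tile of matching length with the
#' fewest mismatches; pairs with no length-matched tile (e.g. indels) or with
#' more than `max_mismatch_frac` mismatches on either mate are discarded. A
#' codon change is counted once per pair only when both mates report the
#' identical mutant codon (set `require_both_mates = FALSE` to count mate-1
#' calls alone, for error-model comparisons). Positional depth is the number
#' of retained pairs covering the codon.
#'
#' @param fastq1,fastq2 Paths to mate-1 and mate-2 FASTQ files (same order).
#' @param orf An [orf_sequence()].
#' @param tiles Output of [tile_definitions()].
#' @param require_both_mates Count only both-mate-concordant changes
#'   (default).
#' @param max_mismatch_frac Per-mate mismatch tolerance (default 0.1).
#' @return list with `counts` (data.frame `codon_index`, `wt_codon`,
#'   `mut_codon`, `count`) and `depth` (data.frame `codon_index`, `depth`),
#'   plus `n_pairs`, `n_discarded`.
#' @export
call_codon_changes <- function(fastq1, fastq2, orf, tiles,
                               require_both_mates = TRUE,
                               max_mismatch_frac = 0.1) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  if (any(nchar(r1) != nchar(r2))) stop("mate length mismatch within a pair")
  r2f <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
  nt <- orf$nucleotides
  ref_tile <- substring(nt, 3L * tiles$first_codon - 2L, 3L * tiles$last_codon)
  wt_codons <- orf_codons(nt)
  counts <- list()
  depth <- setNames(rep(0L, nchar(nt) %/% 3L), seq_len(nchar(nt) %/% 3L))
  n_disc <- 0L
  for (ti in seq_len(nrow(tiles))) {
    span <- tiles$nt_span[ti]
    sel <- which(nchar(r1) == span)
    if (!length(sel)) next
    # among same-length tiles keep pairs matching this one best
    same_len <- which(tiles$nt_span == span)
    if (length(same_len) > 1L) {
      mm <- vapply(same_len, function(tj) {
        ref <- ref_tile[tj]
        mapply(function(a) sum(strsplit(a, "")[[1L]] !=
                                 strsplit(ref, "")[[1L]]), r1[sel])
      }, numeric(length(sel)))
      if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1L)
      sel <- sel[apply(mm, 1L, which.min) == match(ti, same_len)]
      if (!length(sel)) next
    }
    ref <- ref_tile[ti]
    refv <- strsplit(ref, "")[[1L]]
    m1 <- do.call(rbind, strsplit(r1[sel], ""))
    m2 <- do.call(rbind, strsplit(r2f[sel], ""))
    mm1 <- rowSums(m1 != matrix(refv, nrow(m1), span, byrow = TRUE))
    mm2 <- rowSums(m2 != matrix(refv, nrow(m2), span, byrow = TRUE))
    ok <- mm1 <= max_mismatch_frac * span & mm2 <= max_mismatch_frac * span
    n_disc <- n_disc + sum(!ok)
    m1 <- m1[ok, , drop = FALSE]; m2 <- m2[ok, , drop = FALSE]
    if (!nrow(m1)) next
    codon_idx <- tiles$first_codon[ti]:tiles$last_codon[ti]
    depth[as.character(codon_idx)] <-
      depth[as.character(codon_idx)] + nrow(m1)
    for (cj in seq_along(codon_idx)) {
      cols <- (3L * cj - 2L):(3L * cj)
      obs1 <- do.call(paste0, as.data.frame(m1[, cols, drop = FALSE]))
      obs2 <- do.call(paste0, as.data.frame(m2[, cols, drop = FALSE]))
      wt <- wt_codons[codon_idx[cj]]
      hit <- if (require_both_mates) obs1 != wt & obs1 == obs2 else obs1 != wt
      if (any(hit)) {
        tab <- table(obs1[hit])
        counts[[length(counts) + 1L]] <- data.frame(
          codon_index = codon_idx[cj], wt_codon = wt,
          mut_codon = names(tab), count = as.integer(tab),
          stringsAsFactors = FALSE)
      }
    }
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(codon_index = integer(0), wt_codon = character(0),
               mut_codon = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(counts = counts,
       depth = data.frame(codon_index = as.integer(names(depth)),
                          depth = as.integer(depth)),
       n_pairs = length(r1), n_discarded = n_disc)
}

#' Assemble a codon count table across conditions and replicates
#'
#' @param counts Long data.frame: `codon_index`, `wt_codon`, `mut_codon`,
#'   `condition` (`nonselect`, `select`, `wtctrl`), `replicate`, `count`.
#' @param depths Long data.frame: `codon_index`, `condition`, `replicate`,
#'   `depth`.
#' @return A `codon_count_table` object.
#' @export
codon_count_table <- function(counts, depths) {
  stopifnot(all(counts$condition %in% c("nonselect", "select", "wtctrl")),
            all(depths$depth >= 0))
  for (cond in c("nonselect", "select", "wtctrl"))
    if (length(unique(depths$replicate[depths$condition == cond])) < 2L)
      stop("condition '", cond, "' needs >= 2 replicates")
  structure(list(counts = counts, depths = depths),
            class = "codon_count_table")
}

# frequency of every (variant, condition, replicate): count/depth at the
# variant's codon; absent combinations get count 0.
variant_freqs <- function(table) {
  cnt <- table$counts; dep <- table$depths
  vkey <- unique(cnt[, c("codon_index", "wt_codon", "mut_codon")])
  samples <- unique(dep[, c("condition", "replicate")])
  grid <- merge(vkey, samples)
  grid <- merge(grid, dep, by = c("codon_index", "condition", "replicate"),
                all.x = TRUE)
  grid <- merge(grid, cnt,
                by = c("codon_index", "wt_codon", "mut_codon",
                       "condition", "replicate"), all.x = TRUE)
  grid$count[is.na(grid$count)] <- 0L
  if (any(is.na(grid$depth))) stop("missing depth for some codon/sample")
  grid$freq <- grid$count / grid$depth
  grid
}

#' Filter variants with insufficient pre-selection signal
#'
#' A variant is kept only when its frequency in the chosen input condition
#' exceeds the wild-type control mean by more than three wild-type-control
#' standard deviations; otherwise the allele frequency is too close to the
#' sequencing-error floor to detect post-selection depletion. The control
#' standard deviation across replicates is floored at the Poisson expectation
#' `sqrt(mean count)/mean depth`, which keeps the rule meaningful with few
#' control replicates (and keeps variants with an all-zero control).
#'
#' @param table A [codon_count_table()].
#' @param filter_on Which condition is treated as the input: `"nonselect"`
#'   (default; the pre-selection library) or `"select"`.
#' @return data.frame per variant: `codon_index`, `wt_codon`, `mut_codon`,
#'   `keep`, `input_freq`, `wt_mean`, `wt_sd`.
#' @export
filter_low_input <- function(table, filter_on = c("nonselect", "select")) {
  filter_on <- match.arg(filter_on)
  fr <- variant_freqs(table)
  key <- c("codon_index", "wt_codon", "mut_codon")
  sp <- split(fr, fr[key], drop = TRUE)
  out <- lapply(sp, function(g) {
    wt <- g[g$condition == "wtctrl", ]
    inp <- g[g$condition == filter_on, ]
    wt_mean <- mean(wt$freq)
    pois_floor <- sqrt(max(mean(wt$count), 1e-12)) / mean(wt$depth)
    wt_sd <- max(sd(wt$freq), pois_floor, na.rm = TRUE)
    input_freq <- mean(inp$freq)
    data.frame(g[1L, key, drop = FALSE],
               keep = input_freq > wt_mean + 3 * wt_sd,
               input_freq = input_freq, wt_mean = wt_mean, wt_sd = wt_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Enrichment-ratio scores from a codon count table
#'
#' For each variant passing [filter_low_input()], per-replicate frequencies
#' are adjusted by subtracting the mean wild-type-control frequency (the
#' sequencing-error estimate), floored at `epsilon = 1/(10 * max depth)`, and
#' the enrichment ratio `E = adj_select / adj_nonselect` is computed per
#' replicate pair; mean, standard deviation and replicate count are reported
#' across replicates. Variants whose adjusted non-select frequency is not
#' positive are flagged unscorable.
#'
#' @param table A [codon_count_table()].
#' @param filter_on Passed to [filter_low_input()].
#' @return data.frame per variant: codon identity, derived amino-acid change
#'   (`position`, `wt_aa`, `mut_aa`, `type`), `E`, `sd`, `df`, `filtered`,
#'   `reason`.
#' @export
tileseq_score <- function(table, filter_on = "nonselect") {
  fr <- variant_freqs(table)
  flt <- filter_low_input(table, filter_on = filter_on)
  eps <- 1 / (10 * max(table$depths$depth))
  code <- genetic_code()
  key <- c("codon_index", "wt_codon", "mut_codon")
  sp <- split(fr, fr[key], drop = TRUE)
  out <- lapply(sp, function(g) {
    id <- g[1L, key]
    row <- merge(id, flt)[1L, ]
    wt_mean <- mean(g$freq[g$condition == "wtctrl"])
    ns <- g[g$condition == "nonselect", ]; ns <- ns[order(ns$replicate), ]
    se_ <- g[g$condition == "select", ]; se_ <- se_[order(se_$replicate), ]
    adj_ns <- ns$freq - wt_mean
    adj_se <- pmax(se_$freq - wt_mean, eps)
    wt_aa <- code[[id$wt_codon]]; mut_aa <- code[[id$mut_codon]]
    type <- if (mut_aa == "*") "nonsense" else
      if (wt_aa == mut_aa) "synonymous" else "missense"
    base <- data.frame(id, position = id$codon_index, wt_aa = wt_aa,
                       mut_aa = mut_aa, type = type, stringsAsFactors = FALSE)
    if (!row$keep)
      return(cbind(base, E = NA_real_, sd = NA_real_, df = NA_integer_,
                   filtered = TRUE, reason = "low_input"))
    if (any(adj_ns <= 0))
      return(cbind(base, E = NA_real_, sd = NA_real_, df = NA_integer_,
                   filtered = TRUE, reason = "unscorable"))
    nrep <- min(length(adj_ns), length(adj_se))
    E <- adj_se[seq_len(nrep)] / adj_ns[seq_len(nrep)]
    cbind(base, E = mean(E), sd = if (nrep > 1) sd(E) else NA_real_,
          df = nrep, filtered = FALSE, reason = "")
  })
  out <- do.call(rbind, out)
  out <- out[order(out$codon_index, out$mut_codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor enrichment ratios to nonsense/synonymous medians
#'
#' Affine rescaling of enrichment ratios so that the median of nonsense
#' variants maps to 0 and the median of synonymous variants to 1; standard
#' deviations are scaled by the same factor.
#'
#' @param scores Output of [tileseq_score()] (or any data.frame with `E`,
#'   `sd`, `type`, `filtered` columns).
#' @param min_class Minimum number of scored variants required in each anchor
#'   class (default 5).
#' @return The input with `score`, `sd` (rescaled) and `se = sd/sqrt(df)`
#'   columns added; unfiltered rows only are scored.
#' @export
anchor_scores <- function(scores, min_class = 5L) {
  ok <- !scores$filtered & is.finite(scores$E)
  med_non <- median(scores$E[ok & scores$type == "nonsense"])
  med_syn <- median(scores$E[ok & scores$type == "synonymous"])
  if (sum(ok & scores$type == "nonsense") < min_class ||
      sum(ok & scores$type == "synonymous") < min_class)
    stop("need >= ", min_class, " scored synonymous and nonsense variants")
  if (med_syn == med_non) stop("anchor medians equal: no dynamic range")
  scale <- med_syn - med_non
  scores$score <- ifelse(ok, (scores$E - med_non) / scale, NA_real_)
  scores$sd <- scores$sd / abs(scale)
  scores$se <- scores$sd / sqrt(scores$df)
  attr(scores, "anchors") <- c(nonsense = med_non, synonymous = med_syn)
  scores
}

#' Collapse codon-level anchored scores to an amino-acid score map
#'
#' Codon variants encoding the same amino-acid change are combined by
#' inverse-variance weighting of their anchored scores.
#'
#' @param anchored Output of [anchor_scores()].
#' @param gene Gene label for the map.
#' @param types Variant types to retain (default missense and nonsense).
#' @return Score map data.frame: `gene`, `position`, `wt_aa`, `mut_aa`,
#'   `score`, `sd`, `se`, `df`, `provenance = "measured"`.
#' @export
collapse_to_aa <- function(anchored, gene = "gene",
                           types = c("missense", "nonsense")) {
  d <- anchored[!anchored$filtered & anchored$type %in% types &
                  is.finite(anchored$score), , drop = FALSE]
  d$key <- format_variant_string(d$wt_aa, d$position, d$mut_aa)
  out <- lapply(split(d, d$key), function(g) {
    se <- g$se
    if (any(!is.finite(se)) || any(se <= 0)) se <- rep(1, nrow(g))
    w <- (1 / se^2) / sum(1 / se^2)
    data.frame(gene = gene, position = g$position[1L], wt_aa = g$wt_aa[1L],
               mut_aa = g$mut_aa[1L], score = sum(w * g$score),
               sd = sqrt(sum(w^2 * g$sd^2)), se = sqrt(sum(w^2 * g$se^2)),
               df = sum(g$df), provenance = "measured",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
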