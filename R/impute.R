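# Map completion and refinement: a random-forest regressor is trained on the
# measured scores using intrinsic (map-derived), conservation, chemicophysical
# and structural features; its predictions fill unmeasured variants and are
# blended into low-confidence measurements by confidence weighting, with the
# 10-fold cross-validation RMSD serving as the prediction's uncertainty.

#' Residue chemicophysical property table
#'
#' Fixed per-residue scales used for feature deltas: average residue mass
#' (Da), van der Waals volume (Zamyatnin, A^3), Grantham polarity index,
#' formal charge at pH 7 (His counted +0.1 for its partial protonation), and
#' Kyte-Doolittle hydropathy.
#'
#' @return data.frame with rownames = single-letter residues and columns
#'   `mass`, `volume`, `polarity`, `charge`, `hydropathy`.
#' @export
aa_properties <- function() {
  data.frame(
    row.names = c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V"),
    mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
             137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
             101.10, 186.21, 163.18, 99.13),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0, 0, 1, 0, 0, 0, 0, 0, 0,
               0, 0),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2)
  )
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Build the imputation feature table
#'
#' One row per possible amino-acid substitution of the protein. Intrinsic
#' features are derived from the measured map with inverse-variance weights
#' `1/se^2`: the weighted mean score of observed substitutions at the same
#' position (`pos_mean_weighted`); where BarSeq clone data are supplied, the
#' weighted mean score of multi-mutant clones containing the variant
#' (`multi_clone_mean`) and the multiplicative-model estimate of a single
#' variant A from double-mutant clones AB and the measured single B
#' (`multiplicative_estimate`, score(AB)/score(B) averaged over pairs).
#' Chemicophysical deltas (`d_mass`, `d_volume`, `d_polarity`, `d_charge`,
#' `d_hydropathy`) are mutant minus wild-type, hence antisymmetric under
#' swapping the residues; `blosum62` is the substitution-matrix score.
#' Per-position annotation columns (e.g. `amas`, `sift`, `provean`,
#' `solvent_acc`, `interface_burial_*`, `hbond`, `saltbridge`) are merged by
#' position; `sec_struct` (H/E/C) is one-hot encoded. Missing values are kept
#' as `NA` here and median-filled (with missingness indicators) at training
#' time by [impute_scores()].
#'
#' @param map Score map data.frame (`position`, `wt_aa`, `mut_aa`, `score`,
#'   `se`) of measured variants.
#' @param protein Protein string of the mapped gene.
#' @param clones Optional BarSeq clone data.frame with columns `genotype`,
#'   `s_prime`, `se` ([barseq_fitness()] output joined with the library).
#' @param annotations Optional per-position annotation data.frame with a
#'   `position` column.
#' @return data.frame with identifier columns `position`, `wt_aa`, `mut_aa`
#'   and one column per feature.
#' @export
build_features <- function(map, protein, clones = NULL, annotations = NULL) {
  aas <- rownames(aa_properties())
  L <- nchar(protein)
  wt <- strsplit(protein, "")[[1L]]
  grid <- expand.grid(position = seq_len(L), mut_aa = aas,
                      stringsAsFactors = FALSE)
  grid$wt_aa <- wt[grid$position]
  grid <- grid[grid$mut_aa != grid$wt_aa, c("position", "wt_aa", "mut_aa")]
  grid <- grid[order(grid$position, grid$mut_aa), ]
  rownames(grid) <- NULL

  mkey <- format_variant_string(map$wt_aa, map$position, map$mut_aa)
  w_map <- 1 / map$se^2
  w_map[!is.finite(w_map)] <- 0
  # confidence-weighted mean of observed substitutions per position
  pos_w <- tapply(w_map, map$position, sum)
  pos_ws <- tapply(w_map * map$score, map$position, sum)
  pos_mean <- setNames(as.numeric(pos_ws / pos_w), names(pos_w))
  grid$pos_mean_weighted <- unname(pos_mean[as.character(grid$position)])

  grid$multi_clone_mean <- NA_real_
  grid$multiplicative_estimate <- NA_real_
  if (!is.null(clones) && nrow(clones)) {
    gkey <- format_variant_string(grid$wt_aa, grid$position, grid$mut_aa)
    single_score <- setNames(map$score, mkey)
    mm_w <- setNames(rep(0, nrow(grid)), gkey)
    mm_ws <- mm_w
    mult_n <- mm_w; mult_sum <- mm_w
    for (i in seq_len(nrow(clones))) {
      aa <- genotype_aa_changes(clones$genotype[i])
      if (nrow(aa) < 2L) next
      keys <- format_variant_string(aa$wt_aa, aa$position, aa$mut_aa)
      keys <- keys[keys %in% gkey]
      w <- 1 / clones$se[i]^2
      if (!is.finite(w)) w <- 0
      mm_w[keys] <- mm_w[keys] + w
      mm_ws[keys] <- mm_ws[keys] + w * clones$s_prime[i]
      if (length(keys) == 2L) {
        for (j in 1:2) {
          other <- single_score[keys[3L - j]]
          if (is.finite(other) && abs(other) > 1e-6) {
            mult_n[keys[j]] <- mult_n[keys[j]] + 1
            mult_sum[keys[j]] <- mult_sum[keys[j]] +
              clones$s_prime[i] / other
          }
        }
      }
    }
    grid$multi_clone_mean <- ifelse(mm_w > 0, mm_ws / mm_w, NA_real_)
    grid$multiplicative_estimate <-
      ifelse(mult_n > 0, mult_sum / mult_n, NA_real_)
  }

  props <- aa_properties()
  for (p in colnames(props))
    grid[[paste0("d_", p)]] <- props[grid$mut_aa, p] - props[grid$wt_aa, p]
  bl <- blosum62_matrix()
  grid$blosum62 <- bl[cbind(grid$wt_aa, grid$mut_aa)]

  if (!is.null(annotations)) {
    if (!"position" %in% names(annotations))
      stop("annotations must carry a 'position' column")
    ann <- annotations
    if (anyDuplicated(ann$position)) stop("duplicate annotation positions")
    if (any(!seq_len(L) %in% ann$position))
      warning("annotations missing for some positions; features will be NA")
    if ("sec_struct" %in% names(ann)) {
      for (cat in c("H", "E", "C"))
        ann[[paste0("sec_struct_", cat)]] <-
          as.numeric(ann$sec_struct == cat)
      ann$sec_struct <- NULL
    }
    grid <- merge(grid, ann, by = "position", all.x = TRUE, sort = FALSE)
    grid <- grid[order(grid$position, grid$mut_aa), ]
    rownames(grid) <- NULL
  }
  grid
}

#' Random-forest configuration
#'
#' Hyperparameters of the imputation regressor: 500 trees, `mtry` one third
#' of the feature count, bootstrap sampling with replacement of `n_obs`
#' rows, node size 5, unlimited `maxnodes`, one permutation per tree for
#' importance.
#'
#' @param n_tree,mtry,nodesize,n_perm,seed Hyperparameters; `mtry = NULL`
#'   resolves to `floor(n_features/3)` at fit time.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_tree = 500L, mtry = NULL, nodesize = 5L,
                          n_perm = 1L, seed = 42L) {
  structure(list(n_tree = as.integer(n_tree), mtry = mtry,
                 nodesize = as.integer(nodesize), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)), class = "forest_config")
}

feature_matrix <- function(features) {
  id <- c("position", "wt_aa", "mut_aa")
  as.matrix(features[, setdiff(names(features), id), drop = FALSE])
}

# median-fill by training-column medians, adding a missingness indicator for
# any column with NAs
median_fill <- function(X, train_idx) {
  ind <- NULL
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) {
      med <- median(X[train_idx, j], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      ind <- cbind(ind, as.numeric(nas))
      colnames(ind)[ncol(ind)] <- paste0(colnames(X)[j], "_missing")
      X[nas, j] <- med
    }
  }
  if (!is.null(ind)) X <- cbind(X, ind)
  X
}

#' Impute variant scores with a random forest
#'
#' Trains the regressor on measured variants, predicts every variant in the
#' feature table, estimates prediction error as the root-mean-squared
#' deviation in 10-fold cross-validation (folds assigned by a seeded uniform
#' shuffle of the measured variants), and reports permutation feature
#' importances (% increase in MSE).
#'
#' @param map Measured score map (`position`, `wt_aa`, `mut_aa`, `score`).
#' @param features Output of [build_features()] covering the full variant
#'   grid.
#' @param cfg A [forest_config()].
#' @param folds Number of cross-validation folds (default 10).
#' @return list with `predictions` (the feature table's identifier columns
#'   plus `prediction`), `cv_rmsd`, `cv_predictions` (held-out predictions
#'   for measured variants), and `importance` (named vector, %IncMSE).
#' @export
impute_scores <- function(map, features, cfg = forest_config(), folds = 10L) {
  fkey <- format_variant_string(features$wt_aa, features$position,
                                features$mut_aa)
  mkey <- format_variant_string(map$wt_aa, map$position, map$mut_aa)
  train_idx <- match(mkey, fkey)
  if (any(is.na(train_idx))) stop("map contains variants absent from features")
  if (length(train_idx) < 50L)
    warning("fewer than 50 measured variants; imputation will be unreliable")
  X <- feature_matrix(features)
  X <- median_fill(X, train_idx)
  y <- map$score
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(ncol(X) / 3)) else cfg$mtry
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = X[train_idx, , drop = FALSE], y = y, ntree = cfg$n_tree, mtry = mtry,
    replace = TRUE, sampsize = length(train_idx), nodesize = cfg$nodesize,
    maxnodes = NULL, nPerm = cfg$n_perm, importance = TRUE)
  pred <- predict(rf, X)
  imp <- randomForest::importance(rf, type = 1L)[, 1L]

  n <- length(train_idx)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  cv_pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- train_idx[fold_id != f]
    te <- train_idx[fold_id == f]
    rf_f <- randomForest::randomForest(
      x = X[tr, , drop = FALSE], y = y[fold_id != f], ntree = cfg$n_tree,
      mtry = mtry, replace = TRUE, sampsize = length(tr),
      nodesize = cfg$nodesize, nPerm = cfg$n_perm)
    cv_pred[fold_id == f] <- predict(rf_f, X[te, , drop = FALSE])
  }
  cv_rmsd <- sqrt(mean((cv_pred - y)^2))
  list(predictions = cbind(features[, c("position", "wt_aa", "mut_aa")],
                           prediction = unname(pred)),
       cv_rmsd = cv_rmsd, cv_predictions = cv_pred, importance = imp,
       forest = rf)
}

#' Reinterpret above-wild-type scores as deleterious
#'
#' On the anchored scale (wild type = 1), scores above 1 reflect variants
#' that complement better than the wild-type human protein in yeast;
#' evolutionary evidence favours treating these as deleterious in the native
#' context, so scores `s > 1` are replaced by `1/s` (scores at or below 1
#' are unchanged). Standard deviations and errors propagate by the
#' first-order factor `1/s^2`. The transform is idempotent and maps
#' `(0, Inf)` into `(0, 1]`.
#'
#' @param map Score map data.frame with `score` and optionally `sd`, `se`.
#' @return The map with transformed scores.
#' @export
transform_hypercomplementers <- function(map) {
  hi <- is.finite(map$score) & map$score > 1
  fac <- rep(1, nrow(map))
  fac[hi] <- 1 / map$score[hi]^2
  map$score[hi] <- 1 / map$score[hi]
  for (col in c("sd", "se"))
    if (col %in% names(map)) map[[col]] <- map[[col]] * fac
  map
}

#' Refine a measured map with model predictions
#'
#' Blends each measured score with the random-forest prediction by
#' [join_scores()], treating the prediction as a pseudo-measurement with
#' standard deviation and standard error equal to the cross-validation RMSD
#' and `df_virtual` degrees of freedom. Variants absent from the measured map
#' receive the prediction directly with provenance `"imputed"`; measured
#' variants get provenance `"refined"`.
#'
#' @param map Measured score map (`position`, `wt_aa`, `mut_aa`, `score`,
#'   `sd`, `se`, `df`).
#' @param imputation Result of [impute_scores()].
#' @param df_virtual Virtual degrees of freedom granted to a prediction
#'   (default 1).
#' @param gene Gene label for rows created by imputation.
#' @return Complete score map with `provenance` in
#'   `{"refined", "imputed"}`.
#' @export
refine_map <- function(map, imputation, df_virtual = 1, gene = "gene") {
  pred <- imputation$predictions
  rmsd <- imputation$cv_rmsd
  pkey <- format_variant_string(pred$wt_aa, pred$position, pred$mut_aa)
  mkey <- format_variant_string(map$wt_aa, map$position, map$mut_aa)
  idx <- match(mkey, pkey)
  if (any(is.na(idx))) stop("imputation does not cover the map")
  j <- join_scores(map$score, map$sd, map$se, map$df,
                   pred$prediction[idx], rmsd, rmsd, df_virtual)
  refined <- data.frame(gene = if ("gene" %in% names(map)) map$gene else gene,
                        position = map$position, wt_aa = map$wt_aa,
                        mut_aa = map$mut_aa, score = j$mu_joint,
                        sd = j$sigma_joint, se = j$se_joint, df = j$df_joint,
                        provenance = "refined", stringsAsFactors = FALSE)
  missing <- pred[!(pkey %in% mkey), , drop = FALSE]
  imputed <- data.frame(gene = gene, position = missing$position,
                        wt_aa = missing$wt_aa, mut_aa = missing$mut_aa,
                        score = missing$prediction, sd = rmsd, se = rmsd,
                        df = df_virtual, provenance = "imputed",
                        stringsAsFactors = FALSE)
  out <- rbind(refined, imputed)
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
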