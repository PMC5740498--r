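# Cross-platform calibration: TileSeq enrichment scales are mapped onto the
# BarSeq fitness scale through a monotone transform f(x) = a*exp(x) + b*x + c
# fitted by constrained least squares; uncertainties propagate through the
# first-order (Taylor) factor f'(x) = a*exp(x) + b. Shared variants are then
# joined by confidence weighting.

#' Fit the monotone cross-platform rescaling transform
#'
#' Least-squares fit of `f(x) = a*exp(x) + b*x + c` mapping scores `x` on one
#' platform's scale onto paired scores `y` on the other, constrained to
#' `a >= 0`, `b > 0` so the transform is strictly increasing. For fixed `a`
#' the problem is linear in `(b, c)`, so the fit profiles `a` by
#' one-dimensional minimization over the inner exact linear solution
#' (with `b` clamped to a small positive value when the unconstrained
#' solution violates monotonicity).
#'
#' @param x,y Paired scores (same variants) on the source and target scales;
#'   at least 20 pairs.
#' @return A `rescale_fit` list with elements `a`, `b`, `c`, `rss`, `n`.
#' @export
fit_rescale <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 20L) stop("need >= 20 shared variants")
  if (diff(range(x)) == 0) stop("degenerate score range")
  ex <- exp(x)
  b_min <- 1e-8
  inner <- function(a) {
    r <- y - a * ex
    fit <- lm.fit(cbind(1, x), r)
    b <- fit$coefficients[2L]; c0 <- fit$coefficients[1L]
    if (!is.finite(b) || b <= 0) {
      b <- b_min
      c0 <- mean(r - b * x)
    }
    res <- r - (b * x + c0)
    list(a = a, b = unname(b), c = unname(c0), rss = sum(res^2))
  }
  a_max <- max(1, 10 * sd(y) / sd(ex))
  opt <- optimize(function(a) inner(a)$rss, c(0, a_max), tol = 1e-12)
  cand <- list(inner(opt$minimum), inner(0))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "rss"))]]
  structure(list(a = best$a, b = best$b, c = best$c, rss = best$rss,
                 n = length(x)), class = "rescale_fit")
}

#' @export
print.rescale_fit <- function(x, ...) {
  cat(sprintf("<rescale_fit> f(x) = %.4g*exp(x) + %.4g*x + %.4g  (rss %.3g, n %d)\n",
              x$a, x$b, x$c, x$rss, x$n))
  invisible(x)
}

#' Apply a fitted rescaling transform
#'
#' `score' = a*exp(score) + b*score + c`; the standard deviation transforms
#' by the first-order approximation `sd' = sd * (a*exp(score) + b)`.
#'
#' @param score,sd Scores and standard deviations to transform (vectorized).
#' @param fit A [fit_rescale()] result.
#' @return list with `score` and `sd`.
#' @export
apply_rescale <- function(score, sd, fit) {
  stopifnot(inherits(fit, "rescale_fit"))
  list(score = fit$a * exp(score) + fit$b * score + fit$c,
       sd = sd * (fit$a * exp(score) + fit$b))
}

#' Confidence-weighted joining of two measurements
#'
#' Combines two measurements of the same quantity with weights inversely
#' proportional to their standard errors:
#' `w0 = 1/(1 + se0/se1)`, `w1 = 1/(1 + se1/se0)`,
#' `mu_joint = w0*mu0 + w1*mu1`,
#' `sigma_joint^2 = w0*(sigma0^2 + mu0^2) + w1*(sigma1^2 + mu1^2) - mu_joint^2`,
#' `se_joint = sigma_joint / sqrt(df0 + df1)`. Should floating-point
#' cancellation drive `sigma_joint^2` below zero, it is clamped at the
#' within-component bound `w0*sigma0^2 + w1*sigma1^2` with a warning.
#'
#' @param mu0,sigma0,se0,df0 First measurement: mean, standard deviation,
#'   standard error, degrees of freedom (vectorized).
#' @param mu1,sigma1,se1,df1 Second measurement.
#' @return data.frame with `mu_joint`, `sigma_joint`, `se_joint`, `df_joint`,
#'   `w0`, `w1`.
#' @export
join_scores <- function(mu0, sigma0, se0, df0, mu1, sigma1, se1, df1) {
  if (any(se0 <= 0) || any(se1 <= 0)) stop("standard errors must be positive")
  stopifnot(all(df0 >= 1), all(df1 >= 1))
  w0 <- 1 / (1 + se0 / se1)
  w1 <- 1 / (1 + se1 / se0)
  mu_joint <- w0 * mu0 + w1 * mu1
  var_joint <- w0 * (sigma0^2 + mu0^2) + w1 * (sigma1^2 + mu1^2) - mu_joint^2
  bad <- var_joint < 0
  if (any(bad)) {
    warning("sigma_joint^2 fell below zero by cancellation; clamped")
    var_joint[bad] <- pmax(w0 * sigma0^2 + w1 * sigma1^2, 0)[bad]
  }
  df_joint <- df0 + df1
  data.frame(mu_joint = mu_joint, sigma_joint = sqrt(var_joint),
             se_joint = sqrt(var_joint) / sqrt(df_joint),
             df_joint = df_joint, w0 = w0, w1 = w1)
}

#' Join two score maps after rescaling
#'
#' Fits the rescaling transform on the variants shared by the two maps,
#' brings `map_x` (e.g. TileSeq) onto the scale of `map_y` (e.g. BarSeq),
#' and joins shared variants by [join_scores()]. Variants present in only
#' one map are carried through with their original provenance.
#'
#' @param map_x,map_y Score map data.frames (`position`, `wt_aa`, `mut_aa`,
#'   `score`, `sd`, `se`, `df`).
#' @return Joined score map with `provenance` = `"joint"` for shared
#'   variants.
#' @export
join_score_maps <- function(map_x, map_y) {
  kx <- format_variant_string(map_x$wt_aa, map_x$position, map_x$mut_aa)
  ky <- format_variant_string(map_y$wt_aa, map_y$position, map_y$mut_aa)
  shared <- intersect(kx, ky)
  ix <- match(shared, kx); iy <- match(shared, ky)
  fit <- fit_rescale(map_x$score[ix], map_y$score[iy])
  resc <- apply_rescale(map_x$score, map_x$sd, fit)
  map_x$score <- resc$score
  map_x$sd <- resc$sd
  map_x$se <- map_x$sd / sqrt(map_x$df)
  j <- join_scores(map_y$score[iy], map_y$sd[iy], map_y$se[iy], map_y$df[iy],
                   map_x$score[ix], map_x$sd[ix], map_x$se[ix], map_x$df[ix])
  joint <- data.frame(gene = if ("gene" %in% names(map_y))
    map_y$gene[iy] else "gene",
    position = map_y$position[iy], wt_aa = map_y$wt_aa[iy],
    mut_aa = map_y$mut_aa[iy], score = j$mu_joint, sd = j$sigma_joint,
    se = j$se_joint, df = j$df_joint, provenance = "joint",
    stringsAsFactors = FALSE)
  only_x <- map_x[!(kx %in% shared),
                  intersect(names(joint), names(map_x)), drop = FALSE]
  only_y <- map_y[!(ky %in% shared),
                  intersect(names(joint), names(map_y)), drop = FALSE]
  fill <- function(d) {
    if (!nrow(d)) return(joint[0, ])
    for (col in setdiff(names(joint), names(d))) d[[col]] <- NA
    d$provenance <- "measured"
    d[names(joint)]
  }
  out <- rbind(joint, fill(only_x), fill(only_y))
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rescale_fit") <- fit
  out
}
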