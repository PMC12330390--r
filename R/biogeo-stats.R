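# Distance matrices, distance-decay regressions, PERMANOVA and rank-sum
# group contrasts.

#' Great-circle distance in kilometers
#'
#' Haversine distance with a mean Earth radius of 6,371 km. Vectorized over
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1) # 111.19 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stop_if(any(abs(c(lat1, lat2)) > 90), "latitude out of [-90, 90]")
  stop_if(any(abs(c(lon1, lon2)) > 180 + 180), "longitude out of range") # allow 0..360
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; undefined (error) when both vectors are all
#' zero.
#'
#' @param x,y nonnegative abundance vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(6, 0, 2), c(2, 2, 0)) # 0.6667
bray_curtis <- function(x, y) {
  stop_if(length(x) != length(y), "vectors differ in length")
  stop_if(any(x < 0) || any(y < 0), "abundances must be nonnegative")
  denom <- sum(x + y)
  stop_if(denom == 0, "undefined distance: both vectors are all zero")
  sum(abs(x - y)) / denom
}

#' Sample-by-sample dissimilarity matrix from an abundance table
#'
#' Bray-Curtis for taxonomic composition, Euclidean for functional
#' composition (both via [vegan::vegdist()]).
#'
#' @param table an `abundance_table` (or any list with a species-by-sample
#'   `tpm` matrix).
#' @param metric `"braycurtis"` or `"euclidean"`.
#' @return a [stats::dist] over samples.
#' @export
dissimilarity_matrix <- function(table, metric = c("braycurtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- t(table$tpm)
  vegan::vegdist(m, method = if (metric == "braycurtis") "bray" else "euclidean")
}

#' Geographic-distance / community-dissimilarity pairs
#'
#' Builds the pair list a distance-decay fit consumes: every unordered sample
#' pair with its great-circle distance and community dissimilarity.
#'
#' @inheritParams dissimilarity_matrix
#' @return data.frame: `sample_a`, `sample_b`, `geographic_km`,
#'   `dissimilarity`.
#' @export
ddr_pairs <- function(table, metric = c("braycurtis", "euclidean")) {
  metric <- match.arg(metric)
  md <- table$metadata
  stop_if(!all(c("lat", "lon") %in% names(md)), "metadata needs lat and lon")
  d <- as.matrix(dissimilarity_matrix(table, metric))
  n <- nrow(md)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(
    sample_a = md$sample_id[idx[, 1]],
    sample_b = md$sample_id[idx[, 2]],
    geographic_km = haversine_km(md$lat[idx[, 1]], md$lon[idx[, 1]],
                                 md$lat[idx[, 2]], md$lon[idx[, 2]]),
    dissimilarity = d[idx],
    stringsAsFactors = FALSE)
}

#' Distance-decay regression (log-log)
#'
#' Ordinary least squares of log10(community similarity) on log10(geographic
#' distance). For Bray-Curtis dissimilarity the similarity is `1 - d`; for
#' unbounded (Euclidean) dissimilarity it is `1 / (1 + d)`, a bounded monotone
#' transform. Pairs with zero distance or zero similarity are excluded (the
#' log-log axes require positive values) and counted.
#'
#' @param pairs data.frame from [ddr_pairs()] (columns `geographic_km`,
#'   `dissimilarity`).
#' @param similarity how to turn dissimilarity into similarity:
#'   `"one-minus"` (Bray-Curtis) or `"inverse"` (`1/(1+d)`, Euclidean).
#' @return object of class `ddr_fit`: `slope`, `intercept`, `r2_adjusted`,
#'   `p_value`, `n_pairs` (used), `n_excluded`, plus the underlying `lm` fit.
#' @export
ddr_fit <- function(pairs, similarity = c("one-minus", "inverse")) {
  similarity <- match.arg(similarity)
  stop_if(!all(c("geographic_km", "dissimilarity") %in% names(pairs)),
          "pairs needs columns geographic_km and dissimilarity")
  sim <- switch(similarity,
                "one-minus" = 1 - pairs$dissimilarity,
                "inverse" = 1 / (1 + pairs$dissimilarity))
  ok <- pairs$geographic_km > 0 & sim > 0 &
    is.finite(pairs$geographic_km) & is.finite(sim)
  stop_if(sum(ok) < 3, "insufficient data: fewer than 3 usable pairs")
  y <- log10(sim[ok])
  if (var(y) == 0) {
    # flat relationship: slope exactly 0 and no evidence against it
    return(structure(list(slope = 0, intercept = y[1], r2_adjusted = 0,
                          p_value = 1, n_pairs = sum(ok),
                          n_excluded = sum(!ok), lm = NULL),
                     class = "ddr_fit"))
  }
  fit <- lm(log10(sim[ok]) ~ log10(pairs$geographic_km[ok]))
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2_adjusted = sm$adj.r.squared,
                 p_value = slope_p,
                 n_pairs = sum(ok),
                 n_excluded = sum(!ok),
                 lm = fit), class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf("Distance-decay fit (log10-log10): slope = %.4f, R2_adj = %.3f, p = %.3g\n",
              x$slope, x$r2_adjusted, x$p_value))
  cat(x$n_pairs, "pairs used,", x$n_excluded, "excluded (non-positive axis values)\n")
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-way permutational multivariate analysis of variance (via
#' [vegan::adonis2()]): pseudo-F from the within/between sum-of-squares
#' partition of the distance matrix, with `p = (1 + #(permuted F >= observed))
#' / (1 + n_permutations)`.
#'
#' @param d a [stats::dist] or square matrix of dissimilarities.
#' @param groups group label per sample (>= 2 groups, each with >= 2 samples).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list: `pseudo_F`, `R2`, `p_value`, `n_permutations`. When the
#'   matrix has no variation at all, `pseudo_F` is `NA` with
#'   `no_variation = TRUE`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  stop_if(attr(d, "Size") != length(groups),
          "groups length does not match the distance matrix")
  tab <- table(groups)
  stop_if(length(tab) < 2, "invalid grouping: need at least 2 groups")
  stop_if(any(tab < 2), "invalid grouping: a group has fewer than 2 samples")
  if (all(as.vector(d) == 0)) {
    return(list(pseudo_F = NA_real_, R2 = NA_real_, p_value = NA_real_,
                n_permutations = n_permutations, no_variation = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(g = groups)
  res <- vegan::adonis2(d ~ g, data = dat, permutations = n_permutations)
  list(pseudo_F = res$F[1], R2 = res$R2[1], p_value = res$`Pr(>F)`[1],
       n_permutations = n_permutations, no_variation = FALSE)
}

# exact fourth-moment excess kurtosis of the null Mann-Whitney U (no ties)
mw_excess_kurtosis <- function(m, n) {
  N <- m + n
  v <- m * n * (N + 1) / 12
  mu4 <- (m * n * (N + 1) / 240) *
    (5 * (m^2 * n + m * n^2) - 2 * (m^2 + n^2) + 3 * m * n - 2 * (m + n))
  mu4 / v^2 - 3
}

#' Two-sample rank-sum (Mann-Whitney) contrast
#'
#' Two-sided (or one-sided) Mann-Whitney U test. When both groups have at most
#' 8 observations and there are no ties, the p-value comes from the exact null
#' distribution of U; otherwise a tie-corrected normal approximation with
#' continuity correction is used, sharpened by an Edgeworth fourth-cumulant
#' term when there are no ties.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param alternative `"two.sided"` (default), `"greater"` (a shifted right of
#'   b) or `"less"`.
#' @param exact_max largest per-group size for the exact path (default 8).
#' @return object of class `group_contrast`: `statistic` (U, for group a),
#'   `p_value`, `method`, `n_a`, `n_b`, medians of both groups.
#' @export
#' @examples
#' rank_sum_contrast(1:3, 4:6)$p_value # 0.1 (exact)
rank_sum_contrast <- function(values_a, values_b,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 8) {
  alternative <- match.arg(alternative)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  stop_if(length(a) == 0 || length(b) == 0, "empty group")
  stop_if(any(!is.finite(c(a, b))), "values must be finite")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (m <= exact_max && n <= exact_max && !has_ties) {
    p_le <- pwilcox(U, m, n)
    p_ge <- 1 - pwilcox(U - 1, m, n)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    mu <- m * n / 2
    sig2 <- m * n / 12 * ((m + n + 1) -
                            sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    sig <- sqrt(sig2)
    g2 <- if (has_ties) 0 else mw_excess_kurtosis(m, n)
    F_edge <- function(z) pnorm(z) - dnorm(z) * (z^3 - 3 * z) * g2 / 24
    p_le <- F_edge((U + 0.5 - mu) / sig)
    p_ge <- 1 - F_edge((U - 0.5 - mu) / sig)
    p_le <- min(max(p_le, 0), 1); p_ge <- min(max(p_ge, 0), 1)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- if (has_ties) "normal approximation (tie-corrected)"
      else "normal approximation (Edgeworth-corrected)"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 alternative = alternative,
                 n_a = m, n_b = n,
                 median_a = median(a), median_b = median(b)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Rank-sum contrast: U = %g, p = %.4g (%s, %s)\n",
              x$statistic, x$p_value, x$method, x$alternative))
  cat(sprintf("n = %d vs %d; medians %.4g vs %.4g\n",
              x$n_a, x$n_b, x$median_a, x$median_b))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' [stats::p.adjust()] kept as the package's single place to adjust families
#' of contrasts).
#'
#' @param p_values vector of raw p-values.
#' @return adjusted p-values (same length/order).
#' @export
bh_adjust <- function(p_values) p.adjust(p_values, method = "BH")

#' Linear regression of genome size on range size
#'
#' @param range_sizes,genome_sizes numeric vectors of equal length.
#' @return list: `slope`, `intercept`, `r2_adjusted`, `p_value` (slope t-test),
#'   `conf_int` (95% CI on the slope), `n`, and the `lm` fit.
#' @export
genome_size_regression <- function(range_sizes, genome_sizes) {
  stop_if(length(range_sizes) != length(genome_sizes), "vectors differ in length")
  ok <- is.finite(range_sizes) & is.finite(genome_sizes)
  stop_if(sum(ok) < 3, "need at least 3 complete observations")
  fit <- lm(genome_sizes[ok] ~ range_sizes[ok])
  sm <- summary(fit)
  ci <- stats::confint(fit)[2, ]
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2_adjusted = sm$adj.r.squared,
       p_value = sm$coefficients[2, 4],
       conf_int = unname(ci), n = sum(ok), lm = fit)
}
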