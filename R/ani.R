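# Within- vs between-region genome similarity (ANI) contrasts at the species
# and strain tiers.

#' Filter ANI records by taxonomic tier
#'
#' The species tier keeps every genome pair; the strain tier keeps pairs with
#' genome-wide ANI of at least 95% (inclusive).
#'
#' @param records data.frame with columns `genome_a`, `genome_b`,
#'   `ani_percent`, `region_a`, `region_b`.
#' @param tier `"species"` or `"strain"`.
#' @return the filtered records.
#' @export
tier_filter <- function(records, tier = c("species", "strain")) {
  tier <- match.arg(tier)
  req <- c("genome_a", "genome_b", "ani_percent", "region_a", "region_b")
  stop_if(!all(req %in% names(records)),
          paste("records need columns:", paste(req, collapse = ", ")))
  if (tier == "strain") records <- records[records$ani_percent >= 95, , drop = FALSE]
  records
}

#' Within- vs between-region ANI contrast for one region
#'
#' Compares the ANI of genome pairs where both genomes come from the focal
#' region (within) against pairs where exactly one does (between), with a
#' rank-sum test ([rank_sum_contrast()]). Pairs not involving the focal region
#' are ignored.
#'
#' @param records ANI records (see [tier_filter()]).
#' @param focal_region region label.
#' @param alternative passed to [rank_sum_contrast()]; default two-sided.
#' @return a `group_contrast` with extra fields `focal_region`, `n_within`,
#'   `n_between`, `median_within`, `median_between`.
#' @export
within_between_contrast <- function(records, focal_region,
                                    alternative = "two.sided") {
  w <- records$region_a == focal_region & records$region_b == focal_region
  b <- xor(records$region_a == focal_region, records$region_b == focal_region)
  stop_if(sum(w) < 1 || sum(b) < 1,
          sprintf("insufficient data: region '%s' needs at least one within and one between pair",
                  focal_region))
  ct <- rank_sum_contrast(records$ani_percent[w], records$ani_percent[b],
                          alternative = alternative)
  ct$focal_region <- focal_region
  ct$n_within <- sum(w); ct$n_between <- sum(b)
  ct$median_within <- ct$median_a; ct$median_between <- ct$median_b
  ct
}

#' Region-pair summaries of between-region ANI
#'
#' Summarizes every unordered region pair: number of between-region genome
#' pairs, median ANI, and the great-circle distance between region centroids
#' (unweighted mean of member-sample coordinates). Summaries are ordered by
#' centroid distance, longest first (ties broken lexicographically by pair
#' label). All pairwise rank-sum contrasts between the region-pair ANI
#' distributions are attached with BH-adjusted p-values.
#'
#' @param records ANI records.
#' @param metadata sample metadata with columns `region`, `lat`, `lon` (used
#'   for the centroids).
#' @return data.frame of class `region_pair_summary`: `region_pair`,
#'   `n_pairs`, `median_ani`, `centroid_distance_km`; pairwise contrasts in
#'   `attr(, "contrasts")`.
#' @export
region_pair_ordering <- function(records, metadata) {
  stop_if(!all(c("region", "lat", "lon") %in% names(metadata)),
          "metadata needs columns region, lat, lon")
  cent <- aggregate(cbind(lat, lon) ~ region, data = metadata, FUN = mean)
  regions <- sort(cent$region)
  stop_if(length(regions) < 2, "need at least 2 regions")
  prs <- combn(regions, 2)
  pair_label <- apply(prs, 2, paste, collapse = "-")
  ani_of <- function(r1, r2) {
    sel <- (records$region_a == r1 & records$region_b == r2) |
      (records$region_a == r2 & records$region_b == r1)
    records$ani_percent[sel]
  }
  out <- data.frame(
    region_pair = pair_label,
    n_pairs = NA_integer_, median_ani = NA_real_,
    centroid_distance_km = NA_real_, stringsAsFactors = FALSE)
  ani_sets <- vector("list", ncol(prs))
  for (i in seq_len(ncol(prs))) {
    r1 <- prs[1, i]; r2 <- prs[2, i]
    v <- ani_of(r1, r2)
    ani_sets[[i]] <- v
    out$n_pairs[i] <- length(v)
    out$median_ani[i] <- if (length(v)) median(v) else NA_real_
    c1 <- cent[cent$region == r1, ]; c2 <- cent[cent$region == r2, ]
    out$centroid_distance_km[i] <- haversine_km(c1$lat, c1$lon, c2$lat, c2$lon)
  }
  ord <- order(-out$centroid_distance_km, out$region_pair)
  out <- out[ord, ]
  ani_sets <- ani_sets[ord]
  rownames(out) <- NULL
  # pairwise contrasts among the between-region ANI distributions
  have <- which(out$n_pairs > 0)
  ctr <- NULL
  if (length(have) >= 2) {
    cmb <- combn(have, 2)
    ctr <- data.frame(
      group_a = out$region_pair[cmb[1, ]],
      group_b = out$region_pair[cmb[2, ]],
      statistic = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(cmb))) {
      ct <- rank_sum_contrast(ani_sets[[cmb[1, i]]], ani_sets[[cmb[2, i]]])
      ctr$statistic[i] <- ct$statistic
      ctr$p_value[i] <- ct$p_value
    }
    ctr$p_adjusted <- bh_adjust(ctr$p_value)
  }
  attr(out, "contrasts") <- ctr
  class(out) <- c("region_pair_summary", "data.frame")
  out
}
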