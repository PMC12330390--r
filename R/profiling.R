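# Community profiling: TPM abundances from read-mapping summaries, geographic
# occupancy classes for species and functional genes, and the range-size
# index.

#' TPM abundance of species in one sample
#'
#' The abundance of a species is its total mapped bases normalized by the
#' length of its representative sequence and by the sample's sequencing
#' effort, expressed in transcripts-per-million form: per-species rates
#' `mapped_bases / ref_length_bp` are renormalized so that a sample sums to
#' 1e6 over species with nonzero recruitment.
#'
#' @param summaries data.frame with columns `species_id`, `sample_id`,
#'   `mapped_bases`, `ref_length_bp` (and optionally `sample_total_bases`);
#'   all rows must share one `sample_id`.
#' @param sample_id the sample to profile (defaults to the single sample
#'   present).
#' @return named TPM vector over the species in `summaries` (zero vector when
#'   no bases mapped).
#' @export
#' @examples
#' s <- data.frame(species_id = c("a", "b", "c"), sample_id = "s1",
#'                 mapped_bases = c(300, 100, 100),
#'                 ref_length_bp = c(3000, 1000, 2000))
#' tpm_abundance(s)  # 4e5, 4e5, 2e5
tpm_abundance <- function(summaries, sample_id = NULL) {
  req <- c("species_id", "sample_id", "mapped_bases", "ref_length_bp")
  stop_if(!all(req %in% names(summaries)),
          paste("summaries needs columns:", paste(req, collapse = ", ")))
  if (is.null(sample_id)) {
    sample_id <- unique(summaries$sample_id)
    stop_if(length(sample_id) != 1, "summaries span several samples; give sample_id")
  }
  s <- summaries[summaries$sample_id == sample_id, , drop = FALSE]
  stop_if(nrow(s) == 0, sprintf("no rows for sample '%s'", sample_id))
  stop_if(any(s$ref_length_bp <= 0), "ref_length_bp must be positive")
  stop_if(any(s$mapped_bases < 0), "mapped_bases must be nonnegative")
  if ("sample_total_bases" %in% names(s)) {
    stop_if(any(s$mapped_bases > s$sample_total_bases),
            "mapped_bases exceeds sample_total_bases")
  }
  rate <- s$mapped_bases / s$ref_length_bp
  tot <- sum(rate)
  tpm <- if (tot == 0) rep(0, length(rate)) else rate / tot * 1e6
  setNames(tpm, s$species_id)
}

#' Build a species-by-sample TPM abundance table
#'
#' @param mapping long mapping-summary data.frame (see [tpm_abundance()]).
#' @param metadata data.frame with columns `sample_id`, `region` and
#'   optionally `habitat`, `lat`, `lon`; one row per sample.
#' @return object of class `abundance_table`: list with `tpm` (species x
#'   samples matrix, absent species at 0) and `metadata` (ordered as the
#'   matrix columns).
#' @export
build_abundance_table <- function(mapping, metadata) {
  stop_if(!all(c("sample_id", "region") %in% names(metadata)),
          "metadata needs columns sample_id, region")
  stop_if(anyDuplicated(metadata$sample_id) > 0, "duplicate sample_id in metadata")
  stop_if(any(is.na(metadata$region)), "invalid metadata: sample without region")
  samples <- metadata$sample_id
  stop_if(!all(mapping$sample_id %in% samples),
          "invalid metadata: mapping contains samples without metadata")
  species <- sort(unique(mapping$species_id))
  tpm <- matrix(0, length(species), length(samples),
                dimnames = list(species, samples))
  for (sm in unique(mapping$sample_id)) {
    v <- tpm_abundance(mapping, sm)
    tpm[names(v), sm] <- v
  }
  structure(list(tpm = tpm, metadata = metadata[match(samples, metadata$sample_id), ]),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("TPM abundance table:", nrow(x$tpm), "species x", ncol(x$tpm), "samples,",
      length(unique(x$metadata$region)), "regions\n")
  invisible(x)
}

#' Classify species by geographic occupancy
#'
#' A species is present in a region when its TPM exceeds `presence_threshold`
#' in at least one sample of that region. Species present in every region are
#' core; species present in exactly one region are endemic; the rest are
#' intermediate.
#'
#' @param table an [build_abundance_table()] result, or a list with `tpm` and
#'   `metadata`.
#' @param presence_threshold TPM detection cutoff (strict `>`); default 0, i.e.
#'   any recruitment counts as presence.
#' @return data.frame of class `occupancy_profile`: `species_id`,
#'   `n_regions`, `regions_present` (comma-joined), `occupancy_class`; the
#'   per-class counts and per-region endemic counts are attached as attributes
#'   `class_counts` and `endemic_by_region`.
#' @export
classify_occupancy <- function(table, presence_threshold = 0) {
  stop_if(!is.list(table) || is.null(table$tpm) || is.null(table$metadata),
          "table must have elements tpm and metadata")
  check_number(presence_threshold, "presence_threshold", lower = 0)
  md <- table$metadata
  stop_if(any(is.na(md$region)), "invalid metadata: sample without region")
  regions <- sort(unique(md$region))
  K <- length(regions)
  pres <- vapply(regions, function(r) {
    cols <- md$sample_id[md$region == r]
    apply(table$tpm[, cols, drop = FALSE] > presence_threshold, 1, any)
  }, logical(nrow(table$tpm)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1, dimnames = list(rownames(table$tpm), regions))
  n_reg <- rowSums(pres)
  cls <- ifelse(n_reg == K, "core", ifelse(n_reg == 1, "endemic",
                ifelse(n_reg == 0, "absent", "intermediate")))
  out <- data.frame(
    species_id = rownames(table$tpm),
    n_regions = as.integer(n_reg),
    regions_present = apply(pres, 1, function(p) paste(regions[p], collapse = ",")),
    occupancy_class = cls,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "class_counts") <- table(factor(cls, c("core", "intermediate", "endemic", "absent")))
  endem <- out$regions_present[out$occupancy_class == "endemic"]
  attr(out, "endemic_by_region") <- table(factor(endem, regions))
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Species range-size index
#'
#' One minus the sample standard deviation (denominator K - 1) of a species'
#' abundance fractions across the K geographic regions. For K = 4 the index
#' runs from 0.5 (all abundance in one region) to 1.0 (even spread).
#'
#' @param abundance_fractions nonnegative vector over K >= 2 regions summing
#'   to 1 (a species' region-summed abundance divided by its global total).
#' @return the index (scalar).
#' @export
#' @examples
#' range_size(c(1, 0, 0, 0))             # 0.5
#' range_size(c(0.25, 0.25, 0.25, 0.25)) # 1.0
range_size <- function(abundance_fractions) {
  x <- as.numeric(abundance_fractions)
  stop_if(length(x) < 2, "need fractions over at least 2 regions")
  stop_if(any(x < 0) || any(!is.finite(x)), "fractions must be finite and >= 0")
  stop_if(sum(x) == 0, "all-zero species: range size undefined")
  stop_if(abs(sum(x) - 1) > 1e-6, "fractions must sum to 1")
  1 - sd(x)
}

#' Range-size index for every species in an abundance table
#'
#' Aggregates TPM by summing within regions, converts to per-species fractions
#' and applies [range_size()]. Species with zero total abundance are excluded
#' and reported in `attr(, "excluded")`.
#'
#' @inheritParams classify_occupancy
#' @return data.frame `species_id`, `range_size`.
#' @export
range_size_table <- function(table) {
  md <- table$metadata
  regions <- sort(unique(md$region))
  by_region <- vapply(regions, function(r)
    rowSums(table$tpm[, md$sample_id[md$region == r], drop = FALSE]),
    numeric(nrow(table$tpm)))
  if (is.null(dim(by_region)))
    by_region <- matrix(by_region, nrow = 1, dimnames = list(rownames(table$tpm), regions))
  tot <- rowSums(by_region)
  keep <- tot > 0
  frac <- by_region[keep, , drop = FALSE] / tot[keep]
  out <- data.frame(species_id = rownames(table$tpm)[keep],
                    range_size = apply(frac, 1, range_size),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- rownames(table$tpm)[!keep]
  out
}

#' Classify functional genes (KOs) by geographic occupancy
#'
#' Singleton KOs -- present in a single genome -- are discarded first (they are
#' prone to assembly and annotation artifacts). Remaining KOs are classified
#' by the set of regions their carrier genomes come from: present in all
#' regions = shared; in exactly one = region-specific; otherwise intermediate.
#'
#' @param genome_ko data.frame with columns `genome_id`, `ko_id` (one row per
#'   genome-KO incidence).
#' @param genome_region_map data.frame with columns `genome_id`, `region`;
#'   every genome maps to exactly one region.
#' @return data.frame of class `gene_occupancy`: `ko_id`, `n_genomes`,
#'   `n_regions`, `regions_present`, `class` in
#'   `{discarded-singleton, region-specific, intermediate, shared}`.
#' @export
classify_gene_occupancy <- function(genome_ko, genome_region_map) {
  stop_if(!all(c("genome_id", "ko_id") %in% names(genome_ko)),
          "genome_ko needs columns genome_id, ko_id")
  stop_if(!all(c("genome_id", "region") %in% names(genome_region_map)),
          "genome_region_map needs columns genome_id, region")
  stop_if(anyDuplicated(genome_region_map$genome_id) > 0,
          "a genome maps to more than one region")
  stop_if(nrow(genome_ko) == 0, "invalid input: empty genome-KO table")
  genome_ko <- unique(genome_ko[, c("genome_id", "ko_id")])
  miss <- setdiff(genome_ko$genome_id, genome_region_map$genome_id)
  stop_if(length(miss) > 0,
          paste("genomes without region:", paste(head(miss, 3), collapse = ", ")))
  reg <- genome_region_map$region[match(genome_ko$genome_id,
                                        genome_region_map$genome_id)]
  regions <- sort(unique(genome_region_map$region))
  K <- length(regions)
  sp <- split(data.frame(g = genome_ko$genome_id, r = reg), genome_ko$ko_id)
  out <- do.call(rbind, lapply(names(sp), function(ko) {
    d <- sp[[ko]]
    ng <- length(unique(d$g))
    rp <- sort(unique(d$r))
    cls <- if (ng == 1) "discarded-singleton"
      else if (length(rp) == K) "shared"
      else if (length(rp) == 1) "region-specific"
      else "intermediate"
    data.frame(ko_id = ko, n_genomes = ng, n_regions = length(rp),
               regions_present = paste(rp, collapse = ","), class = cls,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("gene_occupancy", "data.frame")
  out
}
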