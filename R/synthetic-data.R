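# Synthetic inputs with known ground truth for every pipeline stage.
#
# Defaults emulate the global soda-lake study design: 4 geographic regions
# (East African Rift Valley, Inner Mongolia/China, Kulunda Steppe/Russia,
# Cariboo Plateau/Canada) with 14/18/15/4 samples, so inter-region centroid
# distances span roughly 7,000-16,000 km. Every generator takes an explicit
# seed and seeds its own RNG stream; identical config + seed give
# byte-identical outputs.

#' Default region table for the synthetic generators
#'
#' Four centroids approximating the East African Rift Valley, Inner Mongolia
#' (China), the Kulunda Steppe (Russia) and the Cariboo Plateau (Canada).
#'
#' @return data.frame with columns `region`, `lat`, `lon`.
#' @export
default_regions <- function() {
  data.frame(
    region = c("Africa", "China", "Russia", "Canada"),
    lat = c(-2.5, 41.0, 51.5, 51.8),
    lon = c(36.0, 107.0, 79.5, -121.5),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for community-level inputs
#'
#' @param n_species number of species.
#' @param n_samples_per_region either one count recycled over regions or a
#'   vector with one count per region. The default `c(14, 18, 15, 4)` mirrors
#'   a 51-sample, 4-region design.
#' @param regions data.frame with columns `region`, `lat`, `lon`.
#' @param core_fraction,endemic_fraction proportions of species seeded as core
#'   (all regions) and endemic (one region); remainder intermediate. Defaults
#'   0.163 and 0.345.
#' @param decay_scale_km e-folding distance (km) of the presence probability
#'   between a species' home region and other regions; default 3000.
#' @param lognormal_mu,lognormal_sigma log-scale parameters of the mapped-base
#'   counts of present species (defaults 9 and 2).
#' @param habitat_offset optional multiplicative log-scale shift applied to
#'   sediment samples (default 0 = no habitat effect).
#' @param seed integer seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 400,
                       n_samples_per_region = c(14, 18, 15, 4),
                       regions = default_regions(),
                       core_fraction = 0.163, endemic_fraction = 0.345,
                       decay_scale_km = 3000,
                       lognormal_mu = 9, lognormal_sigma = 2,
                       habitat_offset = 0,
                       seed = 1) {
  stop_if(nrow(regions) < 2, "need at least 2 regions")
  stop_if(!all(c("region", "lat", "lon") %in% names(regions)),
          "regions needs columns region, lat, lon")
  check_number(core_fraction, "core_fraction", 0, 1)
  check_number(endemic_fraction, "endemic_fraction", 0, 1)
  stop_if(core_fraction + endemic_fraction > 1,
          "core_fraction + endemic_fraction must be <= 1")
  stop_if(nrow(regions) == 2 && core_fraction + endemic_fraction < 1,
          "with 2 regions every species is core or endemic; fractions must sum to 1")
  check_number(decay_scale_km, "decay_scale_km", lower = .Machine$double.xmin)
  stop_if(n_species < 1, "need at least one species")
  n_samp <- rep_len(n_samples_per_region, nrow(regions))
  stop_if(any(n_samp < 1), "every region needs at least one sample")
  structure(list(n_species = as.integer(n_species),
                 n_samples_per_region = as.integer(n_samp),
                 regions = regions,
                 core_fraction = core_fraction,
                 endemic_fraction = endemic_fraction,
                 decay_scale_km = decay_scale_km,
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 habitat_offset = habitat_offset,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a private RNG stream, restoring any global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a pure-birth (Yule) species tree
#'
#' @param n_tips number of leaves (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed.
#' @return rooted binary [ape::phylo] tree with positive branch lengths and
#'   unique tip labels `sp1..spN`.
#' @export
generate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  stop_if(n_tips < 2, "n_tips must be >= 2")
  check_number(birth_rate, "birth_rate", lower = .Machine$double.xmin)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    tr$tip.label <- paste0("sp", seq_len(n_tips))
    tr
  })
}

#' Simulate tip states under a continuous-time Markov chain
#'
#' Draws the root state from `root_frequencies`, then evolves the state along
#' every branch with transition matrix `exp(Q t)`. Optionally widens tips into
#' ambiguous multi-state assignments.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param model a [rate_model()] (all rates >= 0).
#' @param seed integer seed.
#' @param ambiguity_prob probability that a tip additionally accepts one
#'   random extra state (post-hoc ambiguity coding); default 0.
#' @return 0/1 tip-state matrix (tips x states) with the simulated true state
#'   in `attr(, "true_state")`.
#' @export
simulate_tip_states <- function(tree, model, seed = 1, ambiguity_prob = 0) {
  stop_if(!inherits(tree, "phylo"), "tree must be a 'phylo' object")
  stop_if(!inherits(model, "rate_model"), "model must be a 'rate_model'")
  check_number(ambiguity_prob, "ambiguity_prob", 0, 1)
  k <- length(model$states)
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_all <- n_tip + tree$Nnode
    state <- integer(n_all)
    root <- n_tip + 1L
    state[root] <- sample.int(k, 1, prob = model$root_frequencies)
    # unique branch lengths share one transition matrix
    po <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(po$edge)))  # preorder: parents before children
    ulen <- unique(po$edge.length)
    Pl <- lapply(ulen, function(t) transition_probabilities(model, t))
    Pidx <- match(po$edge.length, ulen)
    for (e in ord) {
      P <- Pl[[Pidx[e]]]
      state[po$edge[e, 2]] <- sample.int(k, 1, prob = P[state[po$edge[e, 1]], ])
    }
    tip_state <- state[seq_len(n_tip)]
    m <- matrix(0L, n_tip, k, dimnames = list(tree$tip.label, model$states))
    m[cbind(seq_len(n_tip), tip_state)] <- 1L
    if (ambiguity_prob > 0 && k > 1) {
      amb <- runif(n_tip) < ambiguity_prob
      extra <- vapply(tip_state, function(s)
        sample(setdiff(seq_len(k), s), 1), integer(1))
      m[cbind(which(amb), extra[amb])] <- 1L
    }
    attr(m, "true_state") <- setNames(model$states[tip_state], tree$tip.label)
    m
  })
}

#' Generate read-mapping summaries and sample metadata
#'
#' Produces the two tables the profiling stage consumes: a long mapping
#' summary (species, sample, mapped bases, representative-sequence length,
#' sample total bases) and sample metadata (region, habitat, coordinates).
#' Species are seeded with known occupancy classes -- core species occur in at
#' least one sample of every region, endemic species in exactly one region,
#' intermediate species in 2..K-1 regions -- and presence leaks from a species'
#' home region to others with probability `exp(-distance / decay_scale_km)`,
#' which is what creates the distance-decay signal downstream.
#'
#' @param config a [sim_config()].
#' @return list with `mapping` (data.frame: species_id, sample_id,
#'   mapped_bases, ref_length_bp, sample_total_bases), `metadata` (data.frame:
#'   sample_id, region, habitat, lat, lon) and `truth` (data.frame:
#'   species_id, occupancy_class, home_region, regions_present).
#' @export
generate_abundance_inputs <- function(config) {
  stop_if(!inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, {
    rg <- config$regions
    K <- nrow(rg)
    n_samp <- config$n_samples_per_region
    metadata <- data.frame(
      sample_id = paste0("s", seq_len(sum(n_samp))),
      region = rep(rg$region, n_samp),
      habitat = NA_character_,
      lat = rep(rg$lat, n_samp) + rnorm(sum(n_samp), 0, 1),
      lon = rep(rg$lon, n_samp) + rnorm(sum(n_samp), 0, 1),
      stringsAsFactors = FALSE)
    metadata$habitat <- sample(c("water", "sediment"), nrow(metadata), replace = TRUE)

    cent_dist <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
      haversine_km(rg$lat[i], rg$lon[i], rg$lat[j], rg$lon[j])))

    n_sp <- config$n_species
    n_core <- round(config$core_fraction * n_sp)
    n_end <- round(config$endemic_fraction * n_sp)
    if (n_core + n_end > n_sp) n_end <- n_sp - n_core
    classes <- rep(c("core", "endemic", "intermediate"),
                   c(n_core, n_end, n_sp - n_core - n_end))
    species <- paste0("sp", seq_len(n_sp))
    home <- sample.int(K, n_sp, replace = TRUE)

    regions_present <- vector("list", n_sp)
    for (i in seq_len(n_sp)) {
      if (classes[i] == "core") {
        regions_present[[i]] <- seq_len(K)
      } else if (classes[i] == "endemic") {
        regions_present[[i]] <- home[i]
      } else {
        others <- setdiff(seq_len(K), home[i])
        p <- exp(-cent_dist[home[i], others] / config$decay_scale_km)
        inc <- others[runif(length(others)) < p]
        # an intermediate species occupies 2..K-1 regions by construction
        if (length(inc) == 0) inc <- others[which.min(cent_dist[home[i], others])]
        if (length(inc) == K - 1) inc <- inc[-which.max(cent_dist[home[i], inc])]
        regions_present[[i]] <- sort(c(home[i], inc))
      }
    }

    ref_len <- round(runif(n_sp, 1000, 6000))
    rows <- vector("list", n_sp)
    samp_region <- match(metadata$region, rg$region)
    # per-sample distance to each region centroid drives within-region presence
    for (i in seq_len(n_sp)) {
      pres_reg <- regions_present[[i]]
      sel <- logical(nrow(metadata))
      for (r in pres_reg) {
        in_r <- which(samp_region == r)
        d <- haversine_km(metadata$lat[in_r], metadata$lon[in_r],
                          rg$lat[home[i]], rg$lon[home[i]])
        p <- 0.4 + 0.6 * exp(-d / config$decay_scale_km)
        occ <- runif(length(in_r)) < p
        if (!any(occ)) occ[sample.int(length(in_r), 1)] <- TRUE
        sel[in_r[occ]] <- TRUE
      }
      idx <- which(sel)
      mu <- config$lognormal_mu +
        ifelse(metadata$habitat[idx] == "sediment", config$habitat_offset, 0)
      mb <- pmax(1, round(rlnorm(length(idx), mu, config$lognormal_sigma)))
      rows[[i]] <- data.frame(species_id = species[i],
                              sample_id = metadata$sample_id[idx],
                              mapped_bases = mb,
                              ref_length_bp = ref_len[i],
                              stringsAsFactors = FALSE)
    }
    mapping <- do.call(rbind, rows)
    tot <- tapply(mapping$mapped_bases, mapping$sample_id, sum)
    # rpS3 recruitment is a small slice of a metagenome; 5% mapping rate
    sample_total <- setNames(ceiling(as.numeric(tot) / 0.05), names(tot))
    mapping$sample_total_bases <- sample_total[mapping$sample_id]
    rownames(mapping) <- NULL

    truth <- data.frame(
      species_id = species,
      occupancy_class = classes,
      home_region = rg$region[home],
      regions_present = vapply(regions_present, function(r)
        paste(rg$region[r], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    list(mapping = mapping, metadata = metadata, truth = truth)
  })
}

#' Generate pairwise genome-similarity (ANI) records
#'
#' Within-region pairs are drawn `Normal(within_mean, noise_sd)`;
#' between-region pairs `Normal(within_mean - between_decay_per_km *
#' centroid_distance, noise_sd)`. All values are clamped to the meaningful ANI
#' range \[70, 100\].
#'
#' @param within_mean mean within-region ANI (percent), default 97.
#' @param between_decay_per_km ANI decrease per km of centroid distance
#'   (percent/km), default 5e-4.
#' @param noise_sd Gaussian noise SD (percent), default 1.5.
#' @param regions region table as in [default_regions()].
#' @param n_pairs_per_group number of genome pairs per within-region group and
#'   per region-pair group (default 200).
#' @param seed integer seed.
#' @return data.frame of class `ani_records`: genome_a, genome_b, ani_percent,
#'   region_a, region_b.
#' @export
generate_ani_pairs <- function(within_mean = 97, between_decay_per_km = 5e-4,
                               noise_sd = 1.5, regions = default_regions(),
                               n_pairs_per_group = 200, seed = 1) {
  check_number(within_mean, "within_mean", 70, 100)
  check_number(between_decay_per_km, "between_decay_per_km", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  stop_if(n_pairs_per_group < 1, "need at least one pair per group")
  with_seed(seed, {
    K <- nrow(regions)
    out <- list()
    gid <- 0L
    mk_pair <- function(n, mean_ani, ra, rb) {
      a <- paste0("g", gid + seq_len(n)); gid <<- gid + n
      b <- paste0("g", gid + seq_len(n)); gid <<- gid + n
      data.frame(genome_a = a, genome_b = b,
                 ani_percent = pmin(100, pmax(70, rnorm(n, mean_ani, noise_sd))),
                 region_a = ra, region_b = rb, stringsAsFactors = FALSE)
    }
    for (i in seq_len(K)) {
      out[[length(out) + 1L]] <-
        mk_pair(n_pairs_per_group, within_mean, regions$region[i], regions$region[i])
    }
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      d <- haversine_km(regions$lat[i], regions$lon[i],
                        regions$lat[j], regions$lon[j])
      out[[length(out) + 1L]] <-
        mk_pair(n_pairs_per_group, within_mean - between_decay_per_km * d,
                regions$region[i], regions$region[j])
    }
    res <- do.call(rbind, out)
    class(res) <- c("ani_records", "data.frame")
    res
  })
}

#' Generate genome sizes linearly coupled to range size
#'
#' Forward model for the range-size vs genome-size regression:
#' `size = intercept + slope * range + Normal(0, noise_sd)`, floored at
#' 0.5 Mbp.
#'
#' @param range_sizes numeric vector of range-size indices.
#' @param slope Mbp per index unit.
#' @param intercept Mbp.
#' @param noise_sd Mbp.
#' @param seed integer seed.
#' @return numeric vector of genome sizes (Mbp).
#' @export
generate_genome_sizes <- function(range_sizes, slope = 0.8, intercept = 3,
                                  noise_sd = 0.5, seed = 1) {
  stop_if(length(range_sizes) < 1, "range_sizes is empty")
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed,
    pmax(0.5, intercept + slope * range_sizes +
           rnorm(length(range_sizes), 0, noise_sd)))
}
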