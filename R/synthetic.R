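#' Scenario configuration for the synthetic eDNA study generator
#'
#' Bundles every knob of the generator with defaults sized to a single-visit
#' catchment survey: a dendritic network of 4 tributary rivers joining a
#' mainstem (40 sites, close to a typical 39-site campaign), ~250 reference
#' taxa, 6 field replicates per site, two 12S primer sets with unequal
#' reference coverage, and low-level contamination captured by negative
#' controls.
#'
#' Scenario presets control the planted spatial structure:
#' \describe{
#'   \item{`"null"`}{no spatial structure: occupancy independent of position
#'     (flat gradient, infinite niche breadth, no zones). Used for type-I
#'     error checks.}
#'   \item{`"distance_decay"`}{taxa have Gaussian occupancy kernels along the
#'     distance-to-outlet axis plus a downstream-increasing richness
#'     gradient, but no discrete zones: community turnover rises smoothly
#'     with river distance.}
#'   \item{`"two_zone"` / `"four_zone"`}{as `distance_decay`, plus a fraction
#'     `zone_effect` of the taxon pool is private to one biogeographic zone
#'     (a group of rivers), planting discrete community clusters.}
#' }
#'
#' @param scenario One of `"null"`, `"distance_decay"`, `"two_zone"`,
#'   `"four_zone"`.
#' @param seed Integer seed (mandatory); all generator randomness derives
#'   from it through fixed per-stage substreams.
#' @param n_rivers,sites_per_river Network size (river 1 is the mainstem).
#' @param n_taxa Size of the detectable taxon pool.
#' @param edge_meanlog,edge_sdlog Lognormal parameters of inter-site channel
#'   lengths (km); the defaults give a mean spacing of about 60 km.
#' @param outlet_edge_km Channel length from the lowest site to the outlet.
#' @param zone_effect Fraction of the taxon pool private to one zone.
#' @param private_occupancy Within-zone occupancy probability of a
#'   zone-private taxon.
#' @param gradient_per_km Exponential decay rate of occupancy with distance
#'   from the outlet (per km); positive means richer downstream.
#' @param niche_breadth_km SD of each taxon's Gaussian occupancy kernel
#'   along the distance-to-outlet axis (`Inf` disables positional niches).
#' @param base_occupancy Range of per-taxon maximum occupancy probabilities.
#' @param replicates_per_site Field replicates per site (2 per bank
#'   position: left, centre, right).
#' @param n_negatives Number of negative-control samples per primer set.
#' @param depth_meanlog,depth_sdlog Lognormal read depth per replicate.
#' @param abundance_sdlog Lognormal SD of per-site taxon relative abundance.
#' @param efficiency_range Per-taxon, per-primer amplification efficiency
#'   range (uniform).
#' @param kelly_missing_frac,mifish_missing_frac Fractions of the taxon pool
#'   absent from each primer's reference database (disjoint sets), giving
#'   primer-exclusive detections.
#' @param contam_taxa_rate Poisson mean number of contaminant taxa per
#'   sample (field samples and negatives alike).
#' @param contam_reads_mean Poisson mean reads per contaminant taxon.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("four_zone", "two_zone",
                                         "distance_decay", "null"),
                            seed,
                            n_rivers = 4, sites_per_river = 10,
                            n_taxa = 250,
                            edge_meanlog = log(55), edge_sdlog = 0.35,
                            outlet_edge_km = 25,
                            zone_effect = 0.6, private_occupancy = 0.45,
                            gradient_per_km = 0.0015,
                            niche_breadth_km = 250,
                            base_occupancy = c(0.2, 0.9),
                            replicates_per_site = 6, n_negatives = 6,
                            depth_meanlog = log(25000), depth_sdlog = 0.6,
                            abundance_sdlog = 1.2,
                            efficiency_range = c(0.3, 1),
                            kelly_missing_frac = 0.06,
                            mifish_missing_frac = 0.03,
                            contam_taxa_rate = 2, contam_reads_mean = 10) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              n_rivers = n_rivers, sites_per_river = sites_per_river,
              n_taxa = n_taxa, edge_meanlog = edge_meanlog,
              edge_sdlog = edge_sdlog, outlet_edge_km = outlet_edge_km,
              zone_effect = zone_effect,
              private_occupancy = private_occupancy,
              gradient_per_km = gradient_per_km,
              niche_breadth_km = niche_breadth_km,
              base_occupancy = base_occupancy,
              replicates_per_site = replicates_per_site,
              n_negatives = n_negatives,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              abundance_sdlog = abundance_sdlog,
              efficiency_range = efficiency_range,
              kelly_missing_frac = kelly_missing_frac,
              mifish_missing_frac = mifish_missing_frac,
              contam_taxa_rate = contam_taxa_rate,
              contam_reads_mean = contam_reads_mean)
  if (scenario == "null") {
    cfg$zone_effect <- 0
    cfg$gradient_per_km <- 0
    cfg$niche_breadth_km <- Inf
    cfg$n_zones <- 0
  } else if (scenario == "distance_decay") {
    # pure species replacement along the network: the richness trend is kept
    # flat so that distance decay reflects turnover, not richness
    # difference, and ranges span a few inter-site spacings
    cfg$zone_effect <- 0
    cfg$n_zones <- 0
    cfg$gradient_per_km <- 0
    cfg$niche_breadth_km <- 150
  } else {
    cfg$n_zones <- if (scenario == "two_zone") 2L else 4L
  }
  stopifnot(cfg$zone_effect >= 0, cfg$zone_effect <= 1,
            cfg$private_occupancy > 0, cfg$private_occupancy <= 1,
            cfg$n_rivers >= 1, cfg$sites_per_river >= 1,
            all(cfg$base_occupancy > 0), all(cfg$base_occupancy <= 1))
  class(cfg) <- "scenario_config"
  cfg
}

# Zone of each river: rivers are grouped into n_zones contiguous blocks
# (river 1 = mainstem). With zero zones every site is zone 1.
river_zones <- function(cfg) {
  if (cfg$n_zones == 0) return(rep(1L, cfg$n_rivers))
  as.integer(cut(seq_len(cfg$n_rivers), breaks = cfg$n_zones, labels = FALSE))
}

#' Generate a dendritic river network
#'
#' River 1 is the mainstem, running from the outlet upstream; each further
#' river is a tributary chain joining the mainstem at a junction node that
#' splits a mainstem edge. Sites are named `s<river>_<index>` with index 1
#' the most downstream site of its river. Edge lengths are lognormal km.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional seed override (defaults to the config's seed).
#' @return A [river_network()] whose `node_attrs` include each site's river.
#' @export
generate_network <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(stage_seed(seed, 1), {
    R <- cfg$n_rivers; S <- cfg$sites_per_river
    elen <- function(n) stats::rlnorm(n, cfg$edge_meanlog, cfg$edge_sdlog)
    main <- paste0("s1_", seq_len(S))
    edges <- data.frame(from = "outlet", to = main[1],
                        length_km = cfg$outlet_edge_km)
    if (S > 1)
      edges <- rbind(edges, data.frame(from = main[-S], to = main[-1],
                                       length_km = elen(S - 1)))
    rivers <- stats::setNames(rep(1L, S), main)
    if (R > 1) {
      attach_at <- unique(pmax(1L, floor((seq_len(R - 1)) * S / R)))
      attach_at <- rep_len(attach_at, R - 1)
      for (r in 2:R) {
        trib <- paste0("s", r, "_", seq_len(S))
        jn <- paste0("j", r)
        a <- attach_at[r - 1]
        i <- which(edges$from == main[a] & edges$to == main[a + 1])
        if (a < S && length(i) == 1) {
          # split the mainstem edge above site a with the junction
          half <- edges$length_km[i] / 2
          edges <- edges[-i, ]
          edges <- rbind(edges,
                         data.frame(from = c(main[a], jn),
                                    to = c(jn, main[a + 1]),
                                    length_km = c(half, half)))
        } else {
          edges <- rbind(edges, data.frame(from = main[a], to = jn,
                                           length_km = elen(1)))
        }
        edges <- rbind(edges,
                       data.frame(from = c(jn, trib[-S]),
                                  to = trib,
                                  length_km = elen(S))[seq_len(S), ])
        rivers <- c(rivers, stats::setNames(rep(as.integer(r), S), trib))
      }
    }
    sites <- names(rivers)
    attrs <- data.frame(node = sites, river = as.integer(rivers),
                        zone = river_zones(cfg)[rivers])
    river_network(edges, outlet = "outlet", site_ids = sites,
                  node_attrs = attrs)
  })
}

#' Generate a planted community truth object
#'
#' Each taxon is either zone-private (occurs only at sites of its zone, with
#' a flat occupancy probability) or widespread with a Gaussian occupancy
#' kernel centred on a preferred distance-to-outlet, multiplied by a
#' downstream-increasing exponential gradient. Presence is drawn Bernoulli
#' per site and taxon.
#'
#' @param net A [river_network()] from [generate_network()].
#' @param cfg A [scenario_config()].
#' @param seed Optional seed override.
#' @return Object of class `synthetic_truth`: list with `presence` (site x
#'   taxon 0/1 matrix), `occupancy` (probabilities), `zones` (named integer
#'   per site), `site_river`, `dist_outlet`, `cfg`.
#' @export
generate_communities <- function(net, cfg, seed = cfg$seed) {
  stopifnot(inherits(net, "river_network"), inherits(cfg, "scenario_config"))
  sites <- net$site_ids
  d_out <- distance_to_outlet(net, sites)
  attrs <- net$node_attrs
  zone <- stats::setNames(attrs$zone[match(sites, attrs$node)], sites)
  riv <- stats::setNames(attrs$river[match(sites, attrs$node)], sites)
  with_seed(stage_seed(seed, 2), {
    p <- cfg$n_taxa
    n_private <- if (cfg$n_zones > 0) round(cfg$zone_effect * p) else 0L
    taxon_zone <- rep(NA_integer_, p)
    if (n_private > 0)
      taxon_zone[seq_len(n_private)] <-
        rep_len(seq_len(cfg$n_zones), n_private)
    amax <- stats::runif(p, cfg$base_occupancy[1], cfg$base_occupancy[2])
    opt <- stats::runif(p, 0, max(d_out))
    occ <- matrix(0, length(sites), p,
                  dimnames = list(sites, sprintf("tax%03d", seq_len(p))))
    kern <- if (is.finite(cfg$niche_breadth_km)) {
      exp(-outer(d_out, opt, "-")^2 / (2 * cfg$niche_breadth_km^2))
    } else {
      matrix(1, length(sites), p)
    }
    grad <- exp(-cfg$gradient_per_km * d_out)
    for (i in seq_len(p)) {
      if (!is.na(taxon_zone[i])) {
        occ[, i] <- ifelse(zone == taxon_zone[i], cfg$private_occupancy, 0)
      } else {
        occ[, i] <- pmin(0.95, amax[i] * kern[, i] * grad)
      }
    }
    pres <- matrix(stats::rbinom(length(occ), 1, occ), nrow(occ),
                   dimnames = dimnames(occ))
    structure(list(presence = pres, occupancy = occ, zones = zone,
                   site_river = riv, dist_outlet = d_out,
                   taxon_zone = taxon_zone, cfg = cfg),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d sites x %d taxa (%s scenario)\n",
              nrow(x$presence), ncol(x$presence), x$cfg$scenario))
  cat(sprintf("  richness range %d-%d\n", min(rowSums(x$presence)),
              max(rowSums(x$presence))))
  invisible(x)
}

# One primer set's read table for a given truth.
generate_reads_one <- function(truth, cfg, primer, missing_frac, sub) {
  sites <- rownames(truth$presence)
  p <- ncol(truth$presence)
  taxa <- colnames(truth$presence)
  with_seed(sub, {
    # reference-coverage mask: taxa invisible to this primer
    n_miss <- round(missing_frac * p)
    offset <- if (primer == "kelly") 0L else round(cfg$kelly_missing_frac * p)
    masked <- ((offset + seq_len(n_miss) - 1L) %% p) + 1L
    eff <- stats::runif(p, cfg$efficiency_range[1], cfg$efficiency_range[2])
    eff[masked] <- 0
    # per-site relative abundances of the fish actually there (shared
    # biology across replicates; primer efficiency applied on top)
    abund <- matrix(stats::rlnorm(length(truth$presence), 0,
                                  cfg$abundance_sdlog),
                    nrow(truth$presence)) * truth$presence
    reps <- cfg$replicates_per_site
    banks <- rep(c("left", "centre", "right"), length.out = reps,
                 each = max(1, reps %/% 3))
    rows <- list(); meta <- list()
    for (s in sites) {
      w <- abund[s == sites, ] * eff
      for (r in seq_len(reps)) {
        depth <- round(stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog))
        cnt <- if (sum(w) > 0 && depth > 0)
          as.integer(stats::rmultinom(1, depth, w)) else integer(p)
        # field/lab contamination, low-level, any taxon
        n_cont <- stats::rpois(1, cfg$contam_taxa_rate)
        if (n_cont > 0) {
          ct <- sample.int(p, min(n_cont, p))
          cnt[ct] <- cnt[ct] + stats::rpois(length(ct), cfg$contam_reads_mean)
        }
        id <- sprintf("%s_%s_r%d", primer, s, r)
        rows[[id]] <- cnt
        meta[[id]] <- data.frame(sample_id = id, site_id = s, replicate = r,
                                 bank = banks[r], primer = primer,
                                 is_negative = FALSE)
      }
    }
    for (g in seq_len(cfg$n_negatives)) {
      cnt <- integer(p)
      n_cont <- stats::rpois(1, cfg$contam_taxa_rate)
      if (n_cont > 0) {
        ct <- sample.int(p, min(n_cont, p))
        cnt[ct] <- cnt[ct] + stats::rpois(length(ct), cfg$contam_reads_mean)
      }
      id <- sprintf("%s_neg%d", primer, g)
      rows[[id]] <- cnt
      meta[[id]] <- data.frame(sample_id = id, site_id = NA, replicate = g,
                               bank = NA, primer = primer, is_negative = TRUE)
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- taxa
    count_table(counts, do.call(rbind, meta))
  })
}

#' Generate the two primer sets' read-count tables
#'
#' Per replicate, a lognormal read depth is distributed multinomially over
#' the taxa present at the site, with weights = per-site lognormal relative
#' abundance x per-taxon primer efficiency; taxa outside a primer's
#' reference database yield zero counts in that primer's table. Every sample
#' (field and negative control) additionally receives sparse low-count
#' contamination reads.
#'
#' @param truth A [generate_communities()] result.
#' @param cfg A [scenario_config()].
#' @param seed Optional seed override.
#' @return List with elements `kelly` and `mifish`, each a [count_table()].
#' @export
generate_reads <- function(truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "scenario_config"))
  list(kelly = generate_reads_one(truth, cfg, "kelly",
                                  cfg$kelly_missing_frac,
                                  stage_seed(seed, 3)),
       mifish = generate_reads_one(truth, cfg, "mifish",
                                   cfg$mifish_missing_frac,
                                   stage_seed(seed, 4)))
}

# Environmental variables co-varying with position, for the PCA stage.
generate_env <- function(net, cfg, seed = cfg$seed) {
  sites <- net$site_ids
  d <- distance_to_outlet(net, sites)
  with_seed(stage_seed(seed, 5), {
    n <- length(sites)
    env <- cbind(
      width_m = pmax(5, 250 * exp(-0.004 * d) * stats::rlnorm(n, 0, 0.25)),
      altitude_m = pmax(1, 5 + 0.8 * d + stats::rnorm(n, 0, 40)),
      ph = stats::rnorm(n, 7.6, 0.3),
      conductivity_uScm = pmax(30, 150 + 0.3 * d + stats::rnorm(n, 0, 60)),
      tds_mgl = pmax(10, 100 + 0.15 * d + stats::rnorm(n, 0, 40)))
    rownames(env) <- sites
    env
  })
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper chaining [generate_network()],
#' [generate_communities()], [generate_reads()] and the environmental table.
#'
#' @param cfg A [scenario_config()].
#' @return List with `network`, `truth`, `kelly`, `mifish`, `env`, `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  net <- generate_network(cfg)
  truth <- generate_communities(net, cfg)
  reads <- generate_reads(truth, cfg)
  list(network = net, truth = truth, kelly = reads$kelly,
       mifish = reads$mifish, env = generate_env(net, cfg), cfg = cfg)
}
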