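#' Simulate a haplotype genealogy with infinite-sites mutations
#'
#' Draws a random attachment tree over `n_haplotypes` nodes, places
#' `total_mutations` mutations on its edges (every edge gets at least one;
#' the rest are multinomially distributed) at distinct alignment positions
#' (no homoplasy), and derives one sequence per haplotype from a random root
#' sequence.  Under the infinite-sites model the pairwise coded mutation
#' distances equal the genealogy path lengths exactly, which makes the
#' genealogy a usable oracle for the network and distance code.
#'
#' @param n_haplotypes Number of haplotypes (>= 1).
#' @param seq_length Alignment length in bp (default 800).
#' @param total_mutations Total mutations on the tree (default 20); must be
#'   at least `n_haplotypes - 1` and less than `seq_length`.
#' @param n_indels Number of mutations realised as multi-position gap runs
#'   (length 1-3) instead of substitutions (default 0).
#' @param seed Mandatory RNG seed.
#' @return List with `sequences` (named character vector), `edges`
#'   (data.frame parent, child, steps), `D` (true path-length distance
#'   matrix), `ids`.
#' @export
simulate_haplotypes <- function(n_haplotypes, seq_length = 800,
                                total_mutations = 20, n_indels = 0, seed) {
  stopifnot(n_haplotypes >= 1, n_indels >= 0, n_indels <= total_mutations)
  if (total_mutations < n_haplotypes - 1) {
    stop_pg("total_mutations (%d) must be >= n_haplotypes - 1 (%d)",
            total_mutations, n_haplotypes - 1)
  }
  if (seq_length <= 4 * total_mutations) {
    stop_pg("seq_length must comfortably exceed total mutation span")
  }
  with_seed(seed, {
    n <- n_haplotypes
    parent <- c(NA_integer_,
                vapply(seq_len(max(0, n - 1)) + 1,
                       function(i) sample.int(i - 1, 1), integer(1)))
    steps <- if (n > 1) {
      s <- rep(1L, n - 1)
      extra <- total_mutations - (n - 1)
      if (extra > 0) s <- s + tabulate(sample.int(n - 1, extra, TRUE), n - 1)
      s
    } else integer(0)
    genealogy_sequences(parent, steps, seq_length, n_indels)
  })
}

# Build node sequences for an explicit topology.  Assumes an active RNG
# context.  parent[1] is NA (root); steps[i] is the mutation count on the
# edge parent[i+1] -> node i+1.
genealogy_sequences <- function(parent, steps, seq_length, n_indels = 0) {
  n <- length(parent)
  total <- sum(steps)
  ids <- paste0("H", seq_len(n))
  # reserve non-overlapping spans: substitutions need 1 position, indels 1-3
  # plus a 1-position spacer so maximal gap runs stay distinct
  indel_len <- if (n_indels > 0) sample(1:3, n_indels, replace = TRUE) else integer(0)
  # strided site layout: spans cannot collide or merge into one gap run
  stride <- max(4, floor(seq_length / (total + 1)))
  starts <- seq(2, by = stride, length.out = total)
  if (max(starts) + 3 > seq_length) {
    stop_pg("seq_length too short for requested mutations")
  }
  which_indel <- if (n_indels > 0) sort(sample.int(total, n_indels)) else integer(0)
  root <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
  seqs <- matrix(rep(root, each = n), n, seq_length)
  # assign mutation events to edges
  edge_of <- rep.int(seq_len(max(0, n - 1)), steps)
  edge_of <- sample(edge_of)  # shuffle event order across edges
  descendants <- function(v) {
    out <- v
    repeat {
      more <- which(parent %in% out & !(seq_len(n) %in% out))
      if (!length(more)) return(out)
      out <- c(out, more)
    }
  }
  il <- 0
  for (e in seq_len(total)) {
    child <- edge_of[e] + 1L
    dset <- descendants(child)
    pos <- starts[e]
    if (e %in% which_indel) {
      il <- il + 1
      span <- pos:(pos + indel_len[il] - 1)
      seqs[dset, span] <- "-"
    } else {
      old <- seqs[child, pos]  # pre-mutation state inherited from parent
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      seqs[dset, pos] <- new
    }
  }
  # true distances from path additivity
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    adj <- vector("list", n)
    for (i in 2:n) {
      adj[[i]] <- rbind(adj[[i]], c(parent[i], steps[i - 1]))
      adj[[parent[i]]] <- rbind(adj[[parent[i]]], c(i, steps[i - 1]))
    }
    for (src in seq_len(n)) {
      dist <- rep(NA_real_, n)
      dist[src] <- 0
      queue <- src
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- adj[[v]]
        for (q in seq_len(NROW(nb))) {
          u <- nb[q, 1]
          if (is.na(dist[u])) {
            dist[u] <- dist[v] + nb[q, 2]
            queue <- c(queue, u)
          }
        }
      }
      D[src, ] <- dist
    }
  }
  edges <- if (n > 1) {
    data.frame(parent = ids[parent[-1]], child = ids[-1], steps = steps,
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = character(0), child = character(0),
               steps = integer(0))
  }
  list(sequences = stats::setNames(apply(seqs, 1, paste, collapse = ""), ids),
       edges = edges, D = D, ids = ids)
}

#' Configure a phylogeographic simulation scenario
#'
#' The defaults emulate the scale of a Lower Guinean chloroplast-spacer
#' study: an 8-16 degrees E / 6 degrees S - 8 degrees N region, 20 sampling
#' sites of 6 individuals (120 sequences), ~800 bp alignments with ~20
#' mutations, haplotype pools of 8-12 variants with 1-3 steps between
#' network neighbours, and haplogroup separations of 5 steps where the
#' scenario involves differentiated lineages.
#'
#' Scenarios:
#' * `panmixia` — every sample draws its haplotype i.i.d. from one global
#'   frequency vector, regardless of location.
#' * `refugia` — each refuge centre seeds a haplogroup (founder plus
#'   site-local endemic derivatives within `refuge_radius_km`); sites draw
#'   from refuges with distance-decaying admixture.  Refuge centres get two
#'   sampling sites (centre + flank) so the refuge is represented by more
#'   than one locality.
#' * `expansion` — one widespread founder everywhere, plus rare one-step
#'   derivatives confined to sites near the expansion origin.
#' * `contact` — two haplogroups separated by `separation` steps whose
#'   ranges overlap in a longitudinal band of half-width
#'   `contact_halfwidth_deg`; two sites are forced into the band.
#'
#' @param scenario One of `"panmixia"`, `"refugia"`, `"expansion"`,
#'   `"contact"`.
#' @param region Named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param n_sites Number of sampling sites (default 20).
#' @param samples_per_site Individuals per site (default 6).
#' @param seq_length Alignment length (default 800).
#' @param total_mutations Tree-wide mutation count for panmixia (default 20).
#' @param n_haplotypes Haplotype pool size for panmixia (default 12).
#' @param separation Mutation steps between haplogroup founders (default 5).
#' @param n_refugia Number of refugia (default 2).
#' @param refuge_centers Optional matrix/data.frame of refuge `lon`, `lat`;
#'   defaults to well-separated positions inside the region.
#' @param refuge_radius_km Radius within which refuge-local endemics occur
#'   (default 90, so endemic ranges stay below the 200 km threshold).
#' @param n_local Local derived haplotypes per refuge / origin / group
#'   (defaults 5 for refugia, 10 for expansion, 3 per group for contact).
#' @param local_prob Probability that a within-radius sample carries a local
#'   derivative rather than the founder (scenario-specific default).
#' @param admix_decay_km Distance-decay scale of between-refuge admixture
#'   (default 100 km: mixed membership is confined to a fringe of roughly
#'   one 0.75-degree cell around the equidistance line, keeping the
#'   haplogroups geographically segregated as the scenario requires; wider
#'   fringes turn the refugial pattern into a secondary-contact one, which
#'   is a separate scenario).
#' @param contact_halfwidth_deg Half-width of the contact band (default 0.5).
#' @param expansion_radius_km Radius of the derivative-bearing origin area
#'   (default 150 km).
#' @param species_label Species name written into the sample table.
#' @param seed Mandatory RNG seed.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(scenario = c("panmixia", "refugia", "expansion",
                                         "contact"),
                            region = c(lon_min = 8, lon_max = 16,
                                       lat_min = -6, lat_max = 8),
                            n_sites = 20, samples_per_site = 6,
                            seq_length = 800, total_mutations = 20,
                            n_haplotypes = 12, separation = 5,
                            n_refugia = 2, refuge_centers = NULL,
                            refuge_radius_km = 90, n_local = NULL,
                            local_prob = NULL, admix_decay_km = 100,
                            contact_halfwidth_deg = 0.5,
                            expansion_radius_km = 150,
                            species_label = "sp1", seed) {
  scenario <- match.arg(scenario)
  stopifnot(n_sites >= 1, samples_per_site >= 1, separation >= 1,
            n_refugia >= 1, seq_length > total_mutations)
  n_local <- n_local %||% switch(scenario, refugia = 5, expansion = 10,
                                 contact = 3, panmixia = 0)
  local_prob <- local_prob %||% switch(scenario, refugia = 0.65,
                                       expansion = 0.75, contact = 0.4,
                                       panmixia = 0)
  if (is.null(refuge_centers) && scenario %in% c("refugia")) {
    fr <- cbind(lon = c(0.25, 0.75, 0.4, 0.9), lat = c(0.3, 0.75, 0.9, 0.2))
    fr <- fr[seq_len(n_refugia), , drop = FALSE]
    refuge_centers <- cbind(
      lon = region["lon_min"] + fr[, "lon"] * diff(region[c("lon_min", "lon_max")]),
      lat = region["lat_min"] + fr[, "lat"] * diff(region[c("lat_min", "lat_max")]))
  }
  if (!is.null(refuge_centers)) {
    refuge_centers <- as.matrix(refuge_centers)
    if (any(refuge_centers[, 1] < region["lon_min"] |
            refuge_centers[, 1] > region["lon_max"] |
            refuge_centers[, 2] < region["lat_min"] |
            refuge_centers[, 2] > region["lat_max"])) {
      stop_pg("refuge centers outside region")
    }
  }
  structure(list(scenario = scenario, region = region, n_sites = n_sites,
                 samples_per_site = samples_per_site,
                 seq_length = seq_length, total_mutations = total_mutations,
                 n_haplotypes = n_haplotypes, separation = separation,
                 n_refugia = n_refugia, refuge_centers = refuge_centers,
                 refuge_radius_km = refuge_radius_km, n_local = n_local,
                 local_prob = local_prob, admix_decay_km = admix_decay_km,
                 contact_halfwidth_deg = contact_halfwidth_deg,
                 expansion_radius_km = expansion_radius_km,
                 species_label = species_label, seed = seed),
            class = "scenario_config")
}

# offset a lon/lat point by roughly km_east/km_north (equatorial approx.)
offset_deg <- function(lonlat, km_east, km_north) {
  c(lonlat[1] + km_east / (111.195 * cos(lonlat[2] * pi / 180)),
    lonlat[2] + km_north / 111.195)
}

#' Simulate a georeferenced data set under a phylogeographic scenario
#'
#' @param cfg A `"scenario_config"`.
#' @return List with `alignment` (a `"cp_alignment"`), `samples` (sample
#'   table data frame) and `truth` (a `"scenario_truth"`: genealogy,
#'   haplogroup membership, scenario geometry and the qualitative pattern
#'   the scenario is built to produce).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, {
    reg <- cfg$region
    n_sites <- cfg$n_sites
    sites <- data.frame(
      lon = stats::runif(n_sites, reg["lon_min"], reg["lon_max"]),
      lat = stats::runif(n_sites, reg["lat_min"], reg["lat_max"]))

    forced <- NULL
    if (cfg$scenario == "refugia") {
      ctr <- cfg$refuge_centers
      forced <- do.call(rbind, lapply(seq_len(nrow(ctr)), function(r) {
        flank <- offset_deg(ctr[r, ], 25, 25)
        rbind(ctr[r, ], flank)
      }))
    } else if (cfg$scenario == "expansion") {
      origin <- c(mean(reg[c("lon_min", "lon_max")]),
                  mean(reg[c("lat_min", "lat_max")]))
      forced <- rbind(origin,
                      offset_deg(origin, 40, 10),
                      offset_deg(origin, -15, -40),
                      offset_deg(origin, 30, -30))
    } else if (cfg$scenario == "contact") {
      mid <- mean(reg[c("lon_min", "lon_max")])
      forced <- rbind(
        c(mid, reg["lat_min"] + 0.3 * diff(reg[c("lat_min", "lat_max")])),
        c(mid, reg["lat_min"] + 0.7 * diff(reg[c("lat_min", "lat_max")])))
    }
    if (!is.null(forced)) {
      k <- min(nrow(forced), n_sites)
      sites$lon[seq_len(k)] <- forced[seq_len(k), 1]
      sites$lat[seq_len(k)] <- forced[seq_len(k), 2]
    }

    gen <- switch(cfg$scenario,
      panmixia = {
        g <- genealogy_sequences(
          parent = c(NA_integer_,
                     vapply(seq_len(cfg$n_haplotypes - 1) + 1,
                            function(i) sample.int(i - 1, 1), integer(1))),
          steps = {
            s <- rep(1L, cfg$n_haplotypes - 1)
            extra <- cfg$total_mutations - (cfg$n_haplotypes - 1)
            if (extra > 0) {
              s <- s + tabulate(sample.int(cfg$n_haplotypes - 1, extra, TRUE),
                                cfg$n_haplotypes - 1)
            }
            s
          },
          seq_length = cfg$seq_length)
        g$group <- rep(1L, cfg$n_haplotypes)
        g
      },
      refugia = {
        R <- cfg$n_refugia
        nl <- cfg$n_local
        # founders H1..HR in a chain, then nl locals per refuge
        parent <- if (R > 1) c(NA_integer_, seq_len(R - 1)) else NA_integer_
        steps <- rep(cfg$separation, max(0, R - 1))
        for (r in seq_len(R)) {
          parent <- c(parent, rep(r, nl))
          steps <- c(steps, sample(1:2, nl, replace = TRUE))
        }
        g <- genealogy_sequences(parent, steps, cfg$seq_length)
        g$group <- c(seq_len(R), rep(seq_len(R), each = nl))
        g
      },
      expansion = {
        nl <- cfg$n_local
        g <- genealogy_sequences(c(NA_integer_, rep(1L, nl)),
                                 rep(1L, nl), cfg$seq_length)
        g$group <- rep(1L, nl + 1)
        g
      },
      contact = {
        nl <- cfg$n_local
        parent <- c(NA_integer_, 1L, rep(1L, nl), rep(2L, nl))
        steps <- c(cfg$separation, sample(1:2, 2 * nl, replace = TRUE))
        g <- genealogy_sequences(parent, steps, cfg$seq_length)
        g$group <- c(1L, 2L, rep(1L, nl), rep(2L, nl))
        g
      })

    n_hap <- length(gen$ids)
    hap_of_sample <- function(site_lon, site_lat) {
      switch(cfg$scenario,
        panmixia = sample(n_hap, 1, prob = gen$freq),
        refugia = {
          ctr <- cfg$refuge_centers
          dists <- great_circle_km(site_lat, site_lon, ctr[, 2], ctr[, 1])
          w <- exp(-dists / cfg$admix_decay_km)
          r <- sample(nrow(ctr), 1, prob = w)
          if (dists[r] <= cfg$refuge_radius_km &&
              stats::runif(1) < cfg$local_prob) {
            locals <- setdiff(which(gen$group == r), seq_len(cfg$n_refugia))
            sample(c(locals, locals), 1)  # duplication avoids sample()'s scalar rule
          } else {
            r  # the refuge founder
          }
        },
        expansion = {
          origin <- attr(sites, "origin")
          d0 <- great_circle_km(site_lat, site_lon, origin[2], origin[1])
          if (d0 <= cfg$expansion_radius_km &&
              stats::runif(1) < cfg$local_prob) {
            sample(c(2:n_hap, 2:n_hap), 1)
          } else 1L
        },
        contact = {
          mid <- mean(reg[c("lon_min", "lon_max")])
          p1 <- if (site_lon < mid - cfg$contact_halfwidth_deg) 0.98
                else if (site_lon > mid + cfg$contact_halfwidth_deg) 0.02
                else 0.5
          grp <- if (stats::runif(1) < p1) 1L else 2L
          members <- which(gen$group == grp)
          founder <- members[1]
          derived <- members[-1]
          if (stats::runif(1) < cfg$local_prob) {
            sample(c(derived, derived), 1)
          } else founder
        })
    }
    if (cfg$scenario == "panmixia") {
      gen$freq <- stats::rgamma(n_hap, 1)
      gen$freq <- gen$freq / sum(gen$freq)
    }
    if (cfg$scenario == "expansion") {
      attr(sites, "origin") <- c(mean(reg[c("lon_min", "lon_max")]),
                                 mean(reg[c("lat_min", "lat_max")]))
    }

    m <- cfg$samples_per_site
    n_total <- n_sites * m
    samp <- data.frame(
      id = sprintf("s%04d", seq_len(n_total)),
      species = cfg$species_label,
      site = rep(seq_len(n_sites), each = m),
      stringsAsFactors = FALSE)
    samp$lon <- sites$lon[samp$site] + stats::rnorm(n_total, 0, 0.02)
    samp$lat <- sites$lat[samp$site] + stats::rnorm(n_total, 0, 0.02)
    samp$lon <- pmin(pmax(samp$lon, -180), 180)
    samp$lat <- pmin(pmax(samp$lat, -90), 90)
    hap_idx <- vapply(seq_len(n_total), function(i) {
      as.integer(hap_of_sample(samp$lon[i], samp$lat[i]))
    }, integer(1))
    samp$haplotype <- gen$ids[hap_idx]

    seqs <- gen$sequences[hap_idx]
    names(seqs) <- samp$id
    aln <- alignment(seqs)

    truth <- structure(list(
      scenario = cfg$scenario,
      config = cfg,
      genealogy = gen$edges,
      D = gen$D,
      hap_group = stats::setNames(gen$group, gen$ids),
      hap_assignment = stats::setNames(samp$haplotype, samp$id),
      refuge_centers = cfg$refuge_centers,
      origin = if (cfg$scenario == "expansion") attr(sites, "origin") else NULL,
      contact_band = if (cfg$scenario == "contact") {
        mid <- mean(reg[c("lon_min", "lon_max")])
        c(mid - cfg$contact_halfwidth_deg, mid + cfg$contact_halfwidth_deg)
      } else NULL,
      sites = sites), class = "scenario_truth")

    list(alignment = aln,
         samples = sample_table(samp[, c("id", "species", "lat", "lon")]),
         truth = truth)
  })
}

#' Cell id of a point under a grid
#'
#' @param grid A `"grid_spec"`.
#' @param lon,lat Coordinates (vectorised).
#' @return Character cell ids matching [assign_cells()].
#' @export
cell_id <- function(grid, lon, lat) {
  paste0("c", floor((lon - grid$origin[1]) / grid$cell_deg), "_",
         floor((lat - grid$origin[2]) / grid$cell_deg))
}

#' Machine-checkable expectations for a simulated scenario
#'
#' Translates a `"scenario_truth"` into the qualitative signatures the
#' scenario was built to produce, resolved against a grid:
#' * refugia — a significant phylogeographic signal (NST > GST) and refuge
#'   cells in the top quartile of endemism;
#' * contact — contact-band cells in the top quartile of `v` while at or
#'   below the median of `End` (high phylogenetic diversity without
#'   endemism);
#' * expansion — the top-`NAe` cell lies in the origin area;
#' * panmixia — no phylogeographic signal expected (non-rejection).
#'
#' @param truth A `"scenario_truth"`.
#' @param grid Grid used to resolve focal cells (default 0.75 degrees).
#' @return List with `scenario`, `nst_signal_expected` and scenario-specific
#'   focal cells / band coordinates.
#' @export
expected_pattern <- function(truth, grid = grid_spec(0.75)) {
  stopifnot(inherits(truth, "scenario_truth"))
  out <- list(scenario = truth$scenario,
              nst_signal_expected = truth$scenario %in% c("refugia", "contact"),
              grid = grid)
  if (truth$scenario == "refugia") {
    out$refuge_cells <- cell_id(grid, truth$refuge_centers[, 1],
                                truth$refuge_centers[, 2])
  }
  if (truth$scenario == "expansion") {
    # cells of the forced origin-area sites (within the derivative radius)
    ctr <- truth$origin
    s <- truth$sites
    d0 <- great_circle_km(s$lat, s$lon, ctr[2], ctr[1])
    out$origin_cells <- unique(cell_id(grid, s$lon[d0 <= truth$config$expansion_radius_km],
                                       s$lat[d0 <= truth$config$expansion_radius_km]))
  }
  if (truth$scenario == "contact") out$contact_band <- truth$contact_band
  out
}

#' Evaluate expected scenario signatures against pipeline results
#'
#' @param expected Output of [expected_pattern()].
#' @param diff Optional `"differentiation_result"`.
#' @param diversity Optional [cell_diversity()] table.
#' @param endemism Optional [cell_endemism()] `$cells` table.
#' @param assign Optional `"grid_assignment"` (to locate cell centroids for
#'   the contact band).
#' @param alpha Significance level for the NST > GST check (default 0.05).
#' @return Named logical vector of passed checks (NA when not evaluable).
#' @export
evaluate_pattern <- function(expected, diff = NULL, diversity = NULL,
                             endemism = NULL, assign = NULL, alpha = 0.05) {
  out <- c()
  if (!is.null(diff)) {
    out["nst_signal"] <- if (expected$nst_signal_expected) {
      diff$NST > diff$GST && diff$p_nst_gt_gst < alpha
    } else {
      diff$p_nst_gt_gst >= alpha
    }
  }
  if (expected$scenario == "refugia" && !is.null(endemism)) {
    q3 <- stats::quantile(endemism$End, 0.75, names = FALSE)
    idx <- match(expected$refuge_cells, endemism$cell)
    out["refuge_end_top_quartile"] <- !anyNA(idx) &&
      all(endemism$End[idx] >= q3)
  }
  if (expected$scenario == "contact" && !is.null(diversity) &&
      !is.null(endemism) && !is.null(assign)) {
    cells <- assign$cells
    band <- cells$cell[cells$lon >= expected$contact_band[1] &
                         cells$lon <= expected$contact_band[2]]
    vin <- diversity$v[diversity$cell %in% band]
    ein <- endemism$End[endemism$cell %in% band]
    if (length(vin)) {
      out["band_v_top_quartile"] <- stats::median(vin) >=
        stats::quantile(diversity$v, 0.75, names = FALSE)
      out["band_end_at_or_below_median"] <- stats::median(ein) <=
        stats::median(endemism$End)
    } else {
      out["band_v_top_quartile"] <- NA
      out["band_end_at_or_below_median"] <- NA
    }
  }
  if (expected$scenario == "expansion" && !is.null(diversity)) {
    top <- diversity$cell[which.max(diversity$NAe)]
    out["origin_max_nae"] <- top %in% expected$origin_cells
  }
  out
}

#' Write a simulated data set to disk
#'
#' Writes the aligned FASTA, the sample table TSV and the scenario truth as
#' JSON, so simulated data sets can be consumed like real ones.
#'
#' @param cfg A `"scenario_config"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_dataset()] with the
#'   paths used.
#' @export
write_simulated_dataset <- function(cfg, dir) {
  dat <- simulate_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "alignment.fasta")
  lines <- as.vector(rbind(paste0(">", dat$samples$id),
                           unname(apply(dat$alignment$mat, 1, paste,
                                        collapse = ""))))
  writeLines(lines, fa)
  tsv <- file.path(dir, "samples.tsv")
  utils::write.table(dat$samples, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "truth.json")
  truth <- dat$truth
  jsonlite::write_json(list(
    scenario = truth$scenario,
    genealogy = truth$genealogy,
    hap_group = as.list(truth$hap_group),
    hap_assignment = as.list(truth$hap_assignment),
    refuge_centers = truth$refuge_centers,
    origin = truth$origin,
    contact_band = truth$contact_band,
    seed = truth$config$seed), js, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  dat$paths <- c(alignment = fa, samples = tsv, truth = js)
  invisible(dat)
}
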