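#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km.  Vectorised over
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 1, 0)  # one degree of latitude, ~111.195 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Define a degree grid
#'
#' @param cell_deg Cell side in decimal degrees (e.g. 0.75, 1.5, 3).
#' @param origin Grid origin `c(lon0, lat0)`; default `c(0, 0)` so that the
#'   standard cell sizes produce nested grids.
#' @return A `"grid_spec"` object.
#' @export
grid_spec <- function(cell_deg, origin = c(0, 0)) {
  stopifnot(is.numeric(cell_deg), length(cell_deg) == 1, cell_deg > 0,
            length(origin) == 2)
  structure(list(cell_deg = cell_deg, origin = origin), class = "grid_spec")
}

#' Assign samples to grid cells
#'
#' Cell indices use the floor rule on half-open intervals
#' `[edge, edge + side)`: `col = floor((lon - lon0)/side)`,
#' `row = floor((lat - lat0)/side)`.  A cell is *retained* for statistics
#' when it holds at least `min_n` samples (default 3, the minimum needed to
#' compute the diversity indices); smaller cells give higher spatial
#' resolution at the cost of discarding sparsely sampled areas.
#'
#' @param samples Sample table ([sample_table()]).
#' @param grid A `"grid_spec"`.
#' @param min_n Minimum samples per cell for retention (default 3).
#' @return A `"grid_assignment"`: list with `samples` (input plus `cell`,
#'   `col`, `row`) and `cells` (per-cell `n`, centroid `lat`/`lon` of member
#'   coordinates, `retained` flag), plus the `grid` used.
#' @export
assign_cells <- function(samples, grid, min_n = 3) {
  samples <- sample_table(samples)
  stopifnot(inherits(grid, "grid_spec"))
  col <- floor((samples$lon - grid$origin[1]) / grid$cell_deg)
  row <- floor((samples$lat - grid$origin[2]) / grid$cell_deg)
  cell <- paste0("c", col, "_", row)
  samples$cell <- cell
  samples$col <- col
  samples$row <- row
  agg_n <- tapply(samples$id, cell, length)
  cells <- data.frame(
    cell = names(agg_n),
    n = as.integer(agg_n),
    lat = as.numeric(tapply(samples$lat, cell, mean)),
    lon = as.numeric(tapply(samples$lon, cell, mean)),
    stringsAsFactors = FALSE)
  cells$retained <- cells$n >= min_n
  cells <- cells[order(cells$cell), ]
  rownames(cells) <- NULL
  structure(list(samples = samples, cells = cells, grid = grid,
                 min_n = min_n),
            class = "grid_assignment")
}

#' @export
print.grid_assignment <- function(x, ...) {
  cat(sprintf("<grid_assignment> %d samples, %d cells (%d retained, >= %d samples) at %g deg\n",
              nrow(x$samples), nrow(x$cells), sum(x$cells$retained), x$min_n,
              x$grid$cell_deg))
  invisible(x)
}

# counts matrix: retained cells x haplotypes (only samples present in haps)
cell_hap_counts <- function(assign, haps) {
  stopifnot(inherits(assign, "grid_assignment"),
            inherits(haps, "haplotype_set"))
  s <- assign$samples
  hap <- haps$assignment[s$id]
  ok <- !is.na(hap)
  retained <- assign$cells$cell[assign$cells$retained]
  tab <- table(factor(s$cell[ok], levels = retained),
               factor(hap[ok], levels = haps$id))
  X <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  X
}

#' Per-cell diversity statistics
#'
#' For each retained cell (n >= 3) computes, from the haplotype frequencies
#' of its members:
#' * `He` — gene diversity corrected for sample size,
#'   `n/(n-1) * (1 - sum p^2)`;
#' * `v` — ordered-allele gene diversity: the mean mutation-step distance
#'   between two individuals drawn without replacement,
#'   `n/(n-1) * sum_{h,g} p_h p_g pi_hg`;
#' * `NAe` — Nielsen et al.'s bias-corrected effective number of
#'   haplotypes, `(n-1)^2 / ((sum p^2)(n+1)(n-2) + 3 - n)`.
#'
#' @param assign A `"grid_assignment"`.
#' @param haps A `"haplotype_set"`.
#' @param D [mutation_distance_matrix()] of `haps` (computed if omitted).
#' @return Data frame with one row per retained cell: `cell`, `n`, `NAe`,
#'   `He`, `v`.
#' @export
cell_diversity <- function(assign, haps, D = NULL) {
  D <- D %||% mutation_distance_matrix(haps)
  X <- cell_hap_counts(assign, haps)
  n_k <- rowSums(X)
  usable <- n_k >= assign$min_n
  if (any(!usable)) {
    warn_pg("%d retained cell(s) fall below %d genotyped samples and are skipped",
            sum(!usable), assign$min_n)
  }
  X <- X[usable, , drop = FALSE]
  n_k <- n_k[usable]
  P <- X / n_k
  sp2 <- rowSums(P^2)
  he <- n_k / (n_k - 1) * (1 - sp2)
  v <- n_k / (n_k - 1) * rowSums((P %*% D) * P)
  nae <- (n_k - 1)^2 / (sp2 * (n_k + 1) * (n_k - 2) + 3 - n_k)
  data.frame(cell = rownames(X), n = as.integer(n_k), NAe = nae, He = he,
             v = v, row.names = NULL, stringsAsFactors = FALSE)
}

#' Haplotype geographic ranges
#'
#' The range of a haplotype is the maximal great-circle distance between any
#' two individuals carrying it, over the whole data set (not per cell).
#'
#' @param haps A `"haplotype_set"`.
#' @param samples Sample table covering all carriers.
#' @return Data frame `haplotype`, `n_carriers`, `range_km`.
#' @export
haplotype_ranges <- function(haps, samples) {
  samples <- sample_table(samples)
  idx <- stats::setNames(seq_len(nrow(samples)), samples$id)
  rng <- vapply(haps$id, function(h) {
    ii <- idx[haps$carriers[[h]]]
    if (anyNA(ii)) stop_pg("carriers of %s missing from sample table", h)
    if (length(ii) < 2) return(0)
    la <- samples$lat[ii]; lo <- samples$lon[ii]
    m <- length(ii)
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    max(great_circle_km(la[pr[, 1]], lo[pr[, 1]], la[pr[, 2]], lo[pr[, 2]]))
  }, numeric(1))
  data.frame(haplotype = haps$id, n_carriers = as.integer(haps$counts),
             range_km = unname(rng), stringsAsFactors = FALSE)
}

#' Per-cell haplotypic endemism
#'
#' `End` for a cell is the proportion of its members carrying haplotypes
#' whose total geographic range (maximal distance among all carriers,
#' data-set wide) is at most `threshold_km`.
#'
#' @param assign A `"grid_assignment"`.
#' @param haps A `"haplotype_set"`.
#' @param samples Sample table (for carrier coordinates).
#' @param threshold_km Endemism range threshold in km (default 200).
#' @return List with `cells` (data frame `cell`, `n`, `End`) and `ranges`
#'   (the per-haplotype range table).
#' @export
cell_endemism <- function(assign, haps, samples, threshold_km = 200) {
  ranges <- haplotype_ranges(haps, samples)
  endemic <- stats::setNames(ranges$range_km <= threshold_km, ranges$haplotype)
  s <- assign$samples
  hap <- haps$assignment[s$id]
  ok <- !is.na(hap) & s$cell %in% assign$cells$cell[assign$cells$retained]
  e <- tapply(endemic[hap[ok]], s$cell[ok], mean)
  n <- tapply(hap[ok], s$cell[ok], length)
  cells <- data.frame(cell = names(e), n = as.integer(n),
                      End = as.numeric(e), stringsAsFactors = FALSE)
  cells <- cells[order(cells$cell), ]
  rownames(cells) <- NULL
  list(cells = cells, ranges = ranges)
}

# Pons & Petit (1995, 1996) haploid diversity/differentiation estimators on
# a counts matrix X (populations x haplotypes).  PI = NULL gives the
# frequency-only statistics; with PI, the ordered-allele versions too.
pons_petit_stats <- function(X, PI = NULL, weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  n_k <- rowSums(X)
  C <- nrow(X)
  if (C < 2) stop_pg("differentiation needs >= 2 populations (retained cells)")
  if (any(n_k < 2)) stop_pg("every population needs >= 2 individuals")
  P <- X / n_k
  hk <- n_k / (n_k - 1) * (1 - rowSums(P^2))
  if (weighting == "equal") {
    w <- rep(1 / C, C)
  } else {
    w <- n_k / sum(n_k)
  }
  hS <- sum(w * hk)
  xbar <- colSums(w * P)
  n_harm <- 1 / mean(1 / n_k)  # harmonic mean sample size
  hT <- 1 - sum(xbar^2) + hS / (n_harm * C)
  out <- list(hS = hS, hT = hT,
              GST = if (hT > 0) (hT - hS) / hT else NA_real_)
  if (!is.null(PI)) {
    vk <- n_k / (n_k - 1) * rowSums((P %*% PI) * P)
    vS <- sum(w * vk)
    vT <- drop(xbar %*% PI %*% xbar) + vS / (n_harm * C)
    out$vS <- vS
    out$vT <- vT
    out$NST <- if (vT > 0) (vT - vS) / vT else NA_real_
  }
  out
}

#' Global differentiation and the phylogeographic-signal test
#'
#' Computes the Pons & Petit estimators of haplotype-frequency
#' differentiation `GST = (hT - hS)/hT` and ordered-allele differentiation
#' `NST = (vT - vS)/vT` among retained grid cells, where `hS`/`vS` average
#' the bias-corrected within-cell diversities (equal weight per cell by
#' default, matching the estimator's convention) and `hT`/`vT` use the mean
#' cell frequencies with the published small-sample correction
#' `+ hS/(n_harm * C)`.
#'
#' A phylogeographic signal (related haplotypes co-occurring geographically)
#' is tested by permuting haplotype identities on the rows/columns of the
#' mutation-distance matrix, leaving frequencies untouched, and recomputing
#' `NST`; the one-sided p-value uses the add-one convention
#' `p = (1 + #\{NST_perm >= NST_obs\}) / (1 + n_perm)`.
#'
#' @param assign A `"grid_assignment"`.
#' @param haps A `"haplotype_set"`.
#' @param D [mutation_distance_matrix()] (computed if omitted).
#' @param n_perm Number of permutations (default 999).
#' @param seed Mandatory RNG seed for the permutation test.
#' @param weighting `"equal"` (default) or `"size"` weighting of cells.
#' @return A `"differentiation_result"` list: `GST`, `NST`, components `hS`,
#'   `hT`, `vS`, `vT`, `p_nst_gt_gst`, `n_perm`, `n_cells`, `seed`.
#' @export
global_differentiation <- function(assign, haps, D = NULL, n_perm = 999,
                                   seed, weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  D <- D %||% mutation_distance_matrix(haps)
  X <- cell_hap_counts(assign, haps)
  X <- X[rowSums(X) >= assign$min_n, , drop = FALSE]
  obs <- pons_petit_stats(X, D, weighting)
  if (!is.finite(obs$GST %||% NA_real_) || obs$hT <= 0) {
    stop_pg("total gene diversity hT is zero (global monomorphism): GST/NST undefined")
  }
  H <- ncol(X)
  perm_nst <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(H)
      pons_petit_stats(X, D[pr, pr], weighting)$NST
    }, numeric(1))
  })
  p <- (1 + sum(perm_nst >= obs$NST)) / (1 + n_perm)
  structure(list(GST = obs$GST, NST = obs$NST, hS = obs$hS, hT = obs$hT,
                 vS = obs$vS, vT = obs$vT, p_nst_gt_gst = p,
                 n_perm = n_perm, n_cells = nrow(X), seed = seed,
                 weighting = weighting),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("<differentiation> %d cells: GST = %.4f, NST = %.4f, P(NST > GST) = %.4g (%d perms)\n",
              x$n_cells, x$GST, x$NST, x$p_nst_gt_gst, x$n_perm))
  invisible(x)
}
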