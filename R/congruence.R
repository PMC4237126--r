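#' Standardize per-cell metrics within species
#'
#' Centres and reduces each metric within each species (z-scores over that
#' species' retained cells, sample standard deviation), so that spatial
#' patterns can be compared across species with very different absolute
#' diversity levels.  Species with fewer than two cells, or zero variance in
#' a metric, are flagged and excluded for that metric.
#'
#' @param stats Data frame with columns `species`, `cell` and one or more
#'   metric columns (e.g. `NAe`, `He`, `v`, `End`, `S_i`).
#' @param metrics Metric column names to standardize (default: all numeric
#'   columns other than `n`).
#' @return A `"standardized_metrics"` object: data frame `species`, `cell`,
#'   `metric`, `value`, `z` plus attribute `excluded` (data frame of
#'   species x metric exclusions with reasons).
#' @export
standardize_metrics <- function(stats, metrics = NULL) {
  stopifnot(all(c("species", "cell") %in% names(stats)))
  if (is.null(metrics)) {
    num <- vapply(stats, is.numeric, logical(1))
    metrics <- setdiff(names(stats)[num], "n")
  }
  out <- list()
  excl <- list()
  for (m in metrics) {
    for (sp in unique(stats$species)) {
      rows <- stats[stats$species == sp & !is.na(stats[[m]]), ]
      x <- rows[[m]]
      if (nrow(rows) < 2) {
        excl[[length(excl) + 1]] <- data.frame(species = sp, metric = m,
                                               reason = "fewer than 2 cells")
        next
      }
      s <- stats::sd(x)
      if (s == 0) {
        excl[[length(excl) + 1]] <- data.frame(species = sp, metric = m,
                                               reason = "zero variance")
        next
      }
      out[[length(out) + 1]] <- data.frame(
        species = sp, cell = rows$cell, metric = m, value = x,
        z = (x - mean(x)) / s, stringsAsFactors = FALSE)
    }
  }
  z <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), cell = character(0),
               metric = character(0), value = numeric(0), z = numeric(0))
  rownames(z) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(species = character(0), metric = character(0),
               reason = character(0))
  if (nrow(excluded)) {
    warn_pg("standardization excluded %d species x metric combination(s)",
            nrow(excluded))
  }
  structure(z, excluded = excluded, class = c("standardized_metrics",
                                              "data.frame"))
}

#' Pairwise between-species correlation of a standardized metric
#'
#' Pearson correlation (two-sided test) of a metric's z-scores between every
#' pair of species, evaluated only on cells retained for *both* species.
#' Pairs with fewer than `min_shared` shared cells, or zero variance on the
#' shared subset, are reported as untested with the reason and the shared
#' count.
#'
#' @param z A `"standardized_metrics"` object.
#' @param metric Metric name.
#' @param min_shared Minimum shared cells to run the test (default 5).
#' @return Data frame per species pair: `species1`, `species2`, `n_shared`,
#'   `r`, `p`, `tested`, `reason`.
#' @export
species_pair_correlation <- function(z, metric, min_shared = 5) {
  zm <- z[z$metric == metric, ]
  sps <- sort(unique(zm$species))
  res <- list()
  if (length(sps) >= 2) {
    prs <- utils::combn(sps, 2)
    for (q in seq_len(ncol(prs))) {
      s1 <- prs[1, q]; s2 <- prs[2, q]
      z1 <- zm[zm$species == s1, ]
      z2 <- zm[zm$species == s2, ]
      shared <- intersect(z1$cell, z2$cell)
      x <- z1$z[match(shared, z1$cell)]
      y <- z2$z[match(shared, z2$cell)]
      row <- data.frame(species1 = s1, species2 = s2,
                        n_shared = length(shared), r = NA_real_,
                        p = NA_real_, tested = FALSE, reason = "",
                        stringsAsFactors = FALSE)
      if (length(shared) < min_shared) {
        row$reason <- sprintf("fewer than %d shared cells", min_shared)
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        row$reason <- "zero variance on shared cells"
      } else {
        ct <- stats::cor.test(x, y)
        row$r <- unname(ct$estimate)
        row$p <- ct$p.value
        row$tested <- TRUE
      }
      res[[q]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multi-species ANOVA of a standardized metric across grid cells
#'
#' One-way fixed-effects ANOVA with grid cells as the factor and species'
#' z-scores as the observations (species cannot be crossed as a second
#' factor because of missing cells).  Cells contributing a single
#' observation carry no within-group information and are excluded from the
#' ANOVA, but reported.
#'
#' @param z A `"standardized_metrics"` object.
#' @param metric Metric name.
#' @return List with `F`, `p`, `df_between`, `df_within`, `n_groups`,
#'   `n_obs`, `singleton_cells`.
#' @export
multispecies_anova <- function(z, metric) {
  zm <- z[z$metric == metric & !is.na(z$z), ]
  counts <- table(zm$cell)
  singles <- names(counts)[counts < 2]
  zm <- zm[!(zm$cell %in% singles), ]
  groups <- unique(zm$cell)
  if (length(groups) < 2) {
    stop_pg("ANOVA needs >= 2 cells with >= 2 species values each (have %d)",
            length(groups))
  }
  g <- factor(zm$cell)
  x <- zm$z
  grand <- mean(x)
  gm <- tapply(x, g, mean)
  gn <- tapply(x, g, length)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((x - gm[g])^2)
  dfb <- length(groups) - 1
  dfw <- length(x) - length(groups)
  f <- if (ssb == 0) 0 else (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, n_groups = length(groups),
       n_obs = length(x), singleton_cells = singles)
}

#' Between-species Mantel test on pairwise distinctiveness
#'
#' For each species pair, restricts both `S'_ij` matrices to the cells
#' retained in both species and runs a two-sided Mantel test (congruence of
#' spatial genetic structure could be of either sign).  Pairs with fewer
#' than `min_shared` shared cells are reported untested with the count.
#'
#' @param sij_list Named list (per species) of `S'_ij` matrices (as returned
#'   in `distinctiveness_scores()$S_ij`).
#' @param n_perm Permutations (default 999).
#' @param seed Mandatory RNG seed.
#' @param min_shared Minimum shared cells (default 4).
#' @return Data frame per pair: `species1`, `species2`, `n_shared`, `r`,
#'   `p`, `tested`, `reason`.
#' @export
congruence_mantel <- function(sij_list, n_perm = 999, seed, min_shared = 4) {
  sps <- sort(names(sij_list))
  stopifnot(length(sps) >= 2)
  prs <- utils::combn(sps, 2)
  res <- list()
  for (q in seq_len(ncol(prs))) {
    s1 <- prs[1, q]; s2 <- prs[2, q]
    m1 <- sij_list[[s1]]; m2 <- sij_list[[s2]]
    shared <- intersect(rownames(m1), rownames(m2))
    row <- data.frame(species1 = s1, species2 = s2, n_shared = length(shared),
                      r = NA_real_, p = NA_real_, tested = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (length(shared) < min_shared) {
      row$reason <- sprintf("fewer than %d shared cells", min_shared)
    } else {
      A <- m1[shared, shared]; B <- m2[shared, shared]
      diag(A) <- 0; diag(B) <- 0
      mt <- tryCatch(mantel_test(A, B, n_perm = n_perm, seed = seed + q,
                                 alternative = "two.sided"),
                     error = function(e) NULL)
      if (is.null(mt)) {
        row$reason <- "zero variance on shared cells"
      } else {
        row$r <- mt$r; row$p <- mt$p; row$tested <- TRUE
      }
    }
    res[[q]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multi-species mean of a standardized metric per cell
#'
#' Averages the available species' z-scores in each cell to map
#' multi-species trends; the number of contributing species is reported so
#' sparsely informed cells can be down-weighted or masked in maps.
#'
#' @param z A `"standardized_metrics"` object.
#' @param metric Metric name.
#' @return Data frame `cell`, `mean_z`, `n_species`.
#' @export
multispecies_cell_means <- function(z, metric) {
  zm <- z[z$metric == metric & !is.na(z$z), ]
  if (!nrow(zm)) {
    return(data.frame(cell = character(0), mean_z = numeric(0),
                      n_species = integer(0)))
  }
  mean_z <- tapply(zm$z, zm$cell, mean)
  n_sp <- tapply(zm$species, zm$cell, function(s) length(unique(s)))
  out <- data.frame(cell = names(mean_z), mean_z = as.numeric(mean_z),
                    n_species = as.integer(n_sp), stringsAsFactors = FALSE)
  out <- out[order(out$cell), ]
  rownames(out) <- NULL
  out
}
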