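#' Analyze one species at one grid size
#'
#' Runs the single-species chain: indel coding, haplotype collapsing,
#' mutation distances, polymorphism summary, grid assignment, per-cell
#' diversity and endemism, global GST/NST with the phylogeographic-signal
#' permutation test, and (when at least three cells are retained)
#' distance-decay distinctiveness.
#'
#' @param aln A `"cp_alignment"`.
#' @param samples Sample table covering the aligned ids.
#' @param grid A `"grid_spec"`.
#' @param threshold_km Endemism range threshold (default 200).
#' @param n_perm Permutations for NST and Mantel tests (default 999).
#' @param seed Mandatory RNG seed.
#' @param mask_cols Alignment columns to exclude from substitution
#'   characters (default none).
#' @return List with `haps`, `D`, `poly`, `assign`, `cellstats` (cell, n,
#'   NAe, He, v, End), `diff`, `distinct` (or `NULL` with
#'   `distinct_skipped` reason), `pairs`.
#' @export
analyze_species <- function(aln, samples, grid, threshold_km = 200,
                            n_perm = 999, seed, mask_cols = integer(0)) {
  coded <- code_indels(aln, mask_cols = mask_cols)
  haps <- collapse_haplotypes(coded, samples)
  D <- mutation_distance_matrix(haps)
  poly <- summarize_polymorphism(haps, D)
  assign <- assign_cells(samples, grid)
  div <- cell_diversity(assign, haps, D)
  end <- cell_endemism(assign, haps, samples, threshold_km = threshold_km)
  cellstats <- merge(div, end$cells[, c("cell", "End")], by = "cell",
                     sort = TRUE)
  diff <- tryCatch(
    global_differentiation(assign, haps, D, n_perm = n_perm, seed = seed),
    error = function(e) e)
  distinct <- NULL
  distinct_skipped <- NA_character_
  prs <- tryCatch(between_cell_matrices(assign, haps, D),
                  error = function(e) e)
  if (inherits(prs, "error")) {
    distinct_skipped <- conditionMessage(prs)
    prs <- NULL
  } else {
    distinct <- tryCatch(
      distinctiveness_scores(prs, n_perm = n_perm, seed = seed + 1),
      error = function(e) {
        distinct_skipped <<- conditionMessage(e)
        NULL
      })
  }
  list(haps = haps, D = D, poly = poly, assign = assign,
       cellstats = cellstats,
       diff = if (inherits(diff, "error")) NULL else diff,
       diff_skipped = if (inherits(diff, "error")) conditionMessage(diff)
                      else NA_character_,
       pairs = prs, distinct = distinct, distinct_skipped = distinct_skipped,
       grid = grid, ranges = end$ranges)
}

#' Run the comparative multi-species pipeline
#'
#' Analyzes each species at each grid size and assembles the comparative
#' outputs: the polymorphism table, the per-cell statistics table, the
#' differentiation (GST/NST) table, the per-cell distinctiveness table, and
#' per grid size the congruence report (pairwise Pearson correlations,
#' multi-species ANOVA per metric, between-species Mantel on pairwise
#' distinctiveness, and multi-species mean z per cell).
#'
#' @param datasets Named list (per species) of lists with elements `aln`
#'   (`"cp_alignment"`) and `samples` (sample table).
#' @param grid_sizes Grid cell sides in degrees (default `c(0.75, 1.5, 3)`).
#' @param grid_origin Grid origin (default `c(0, 0)`).
#' @param threshold_km Endemism threshold (default 200).
#' @param n_perm Permutations (default 999).
#' @param seed Mandatory RNG seed; per species/grid seeds are derived
#'   deterministically.
#' @param metrics Metrics entering standardization and congruence (default
#'   `NAe`, `He`, `v`, `End`, `S_i`).
#' @return A `"phylogrid_result"` list of tables (see
#'   [write_pipeline_tables()]).
#' @export
run_comparative_pipeline <- function(datasets,
                                     grid_sizes = c(0.75, 1.5, 3),
                                     grid_origin = c(0, 0),
                                     threshold_km = 200, n_perm = 999, seed,
                                     metrics = c("NAe", "He", "v", "End",
                                                 "S_i")) {
  stopifnot(length(names(datasets)) == length(datasets),
            all(nzchar(names(datasets))))
  species <- names(datasets)
  poly_tab <- list()
  cell_tab <- list()
  diff_tab <- list()
  si_tab <- list()
  congruence <- list()
  analyses <- list()

  for (gi in seq_along(grid_sizes)) {
    g <- grid_sizes[gi]
    grid <- grid_spec(g, grid_origin)
    per_species <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      res <- analyze_species(datasets[[sp]]$aln, datasets[[sp]]$samples,
                             grid, threshold_km = threshold_km,
                             n_perm = n_perm,
                             seed = seed + 1000 * gi + 10 * si)
      per_species[[sp]] <- res
      if (gi == 1) {
        poly_tab[[sp]] <- data.frame(
          species = sp, n = res$poly$n, snps = res$poly$snps,
          pi = res$poly$pi, pi_sd = res$poly$pi_sd,
          n_haplotypes = res$poly$n_haplotypes, stringsAsFactors = FALSE)
      }
      cs <- res$cellstats
      if (!is.null(res$distinct)) {
        cs$S_i <- res$distinct$S_i[cs$cell]
      } else {
        cs$S_i <- NA_real_
      }
      cell_tab[[length(cell_tab) + 1]] <-
        cbind(data.frame(species = sp, grid = g), cs)
      if (!is.null(res$diff)) {
        d <- res$diff
        diff_tab[[length(diff_tab) + 1]] <- data.frame(
          species = sp, grid = g, n_cells = d$n_cells, GST = d$GST,
          NST = d$NST, p_nst_gt_gst = d$p_nst_gt_gst,
          stringsAsFactors = FALSE)
      }
      if (!is.null(res$distinct)) {
        si_tab[[length(si_tab) + 1]] <- data.frame(
          species = sp, grid = g, cell = names(res$distinct$S_i),
          S_i = unname(res$distinct$S_i), branch = res$distinct$branch,
          stringsAsFactors = FALSE)
      }
    }

    stats_g <- do.call(rbind, lapply(species, function(sp) {
      cs <- per_species[[sp]]$cellstats
      cs$S_i <- if (!is.null(per_species[[sp]]$distinct)) {
        per_species[[sp]]$distinct$S_i[cs$cell]
      } else NA_real_
      cbind(data.frame(species = sp), cs)
    }))
    z <- suppressWarnings(
      standardize_metrics(stats_g, metrics = intersect(metrics,
                                                       names(stats_g))))
    pearson <- do.call(rbind, lapply(intersect(metrics, unique(z$metric)),
                                     function(m) {
      out <- species_pair_correlation(z, m)
      if (is.null(out)) return(NULL)
      cbind(data.frame(metric = m), out)
    }))
    anova_tab <- do.call(rbind, lapply(intersect(metrics, unique(z$metric)),
                                       function(m) {
      a <- tryCatch(multispecies_anova(z, m), error = function(e) NULL)
      if (is.null(a)) return(NULL)
      data.frame(metric = m, F = a$F, p = a$p, df_between = a$df_between,
                 df_within = a$df_within, n_obs = a$n_obs,
                 stringsAsFactors = FALSE)
    }))
    sij <- Filter(Negate(is.null),
                  lapply(per_species, function(r) {
                    if (is.null(r$distinct)) NULL else r$distinct$S_ij
                  }))
    mantel_tab <- if (length(sij) >= 2) {
      congruence_mantel(sij, n_perm = n_perm, seed = seed + 5000 * gi)
    } else NULL
    means_tab <- do.call(rbind, lapply(intersect(metrics, unique(z$metric)),
                                       function(m) {
      cbind(data.frame(metric = m), multispecies_cell_means(z, m))
    }))
    congruence[[as.character(g)]] <- list(
      grid = g, z = as.data.frame(z), pearson = pearson, anova = anova_tab,
      mantel = mantel_tab, cell_means = means_tab,
      excluded = attr(z, "excluded"))
    analyses[[as.character(g)]] <- per_species
  }

  structure(list(
    polymorphism = do.call(rbind, poly_tab),
    cellstats = do.call(rbind, cell_tab),
    differentiation = do.call(rbind, diff_tab),
    distinctiveness = do.call(rbind, si_tab),
    congruence = congruence,
    analyses = analyses,
    grid_sizes = grid_sizes, seed = seed),
    class = "phylogrid_result")
}

#' @export
print.phylogrid_result <- function(x, ...) {
  cat(sprintf("<phylogrid_result> %d species x %d grid size(s); tables: polymorphism, cellstats, differentiation, distinctiveness, congruence\n",
              nrow(x$polymorphism), length(x$grid_sizes)))
  invisible(x)
}

fmt_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- sprintf("%.10g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all pipeline tables to a directory
#'
#' Writes `polymorphism.tsv`, `cellstats.tsv`, `differentiation.tsv`,
#' `distinctiveness.tsv` and, per grid size, `congruence_<g>_pearson.tsv`,
#' `..._anova.tsv`, `..._mantel.tsv`, `..._cellmeans.tsv`.  Numbers are
#' formatted with 10 significant digits so identical analyses produce
#' byte-identical files.
#'
#' @param res A `"phylogrid_result"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_tables <- function(res, dir) {
  stopifnot(inherits(res, "phylogrid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(dir, name)
    fmt_tsv(df, p)
    files <<- c(files, p)
  }
  wr(res$polymorphism, "polymorphism.tsv")
  wr(res$cellstats, "cellstats.tsv")
  wr(res$differentiation, "differentiation.tsv")
  wr(res$distinctiveness, "distinctiveness.tsv")
  for (g in names(res$congruence)) {
    cg <- res$congruence[[g]]
    tag <- gsub("[.]", "p", g)
    wr(cg$pearson, sprintf("congruence_%s_pearson.tsv", tag))
    wr(cg$anova, sprintf("congruence_%s_anova.tsv", tag))
    wr(cg$mantel, sprintf("congruence_%s_mantel.tsv", tag))
    wr(cg$cell_means, sprintf("congruence_%s_cellmeans.tsv", tag))
  }
  invisible(files)
}
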