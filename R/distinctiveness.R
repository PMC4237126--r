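#' Between-cell phylogenetic and geographic distance matrices
#'
#' For every pair of retained cells computes `v_ij`, the mean mutation-step
#' distance between one individual drawn from cell `i` and one from cell `j`
#' (`sum_{h,g} p_ih p_jg pi_hg`; no self-pair correction since the draws
#' come from different cells), and `d_ij`, the great-circle distance between
#' the centroids of the cells' members.  The diagonal of `v` holds the
#' uncorrected within-cell mean distance.
#'
#' @param assign A `"grid_assignment"`.
#' @param haps A `"haplotype_set"`.
#' @param D [mutation_distance_matrix()] (computed if omitted).
#' @return A `"cell_pair_matrix"`: list with `cells`, `v`, `d`.
#' @export
between_cell_matrices <- function(assign, haps, D = NULL) {
  D <- D %||% mutation_distance_matrix(haps)
  X <- cell_hap_counts(assign, haps)
  X <- X[rowSums(X) >= assign$min_n, , drop = FALSE]
  cells <- assign$cells[match(rownames(X), assign$cells$cell), ]
  P <- X / rowSums(X)
  V <- P %*% D %*% t(P)
  dmat <- outer(seq_len(nrow(cells)), seq_len(nrow(cells)),
                function(i, j) great_circle_km(cells$lat[i], cells$lon[i],
                                               cells$lat[j], cells$lon[j]))
  dimnames(V) <- list(cells$cell, cells$cell)
  dimnames(dmat) <- dimnames(V)
  cell_pair_matrix(V, dmat)
}

#' Construct a cell-pair matrix object
#'
#' @param v Symmetric matrix of mean between-cell mutation distances.
#' @param d Symmetric matrix of between-centroid distances in km.
#' @return A `"cell_pair_matrix"`.
#' @export
cell_pair_matrix <- function(v, d) {
  v <- as.matrix(v); d <- as.matrix(d)
  stopifnot(nrow(v) == ncol(v), all(dim(v) == dim(d)))
  if (nrow(v) < 3) stop_pg("need >= 3 retained cells for between-cell analyses")
  if (any(upper_vals(d) <= 0)) {
    stop_pg("co-located cell centroids (d_ij = 0): degenerate geography")
  }
  ids <- rownames(v) %||% paste0("cell", seq_len(nrow(v)))
  dimnames(v) <- list(ids, ids); dimnames(d) <- list(ids, ids)
  structure(list(cells = ids, v = v, d = d), class = "cell_pair_matrix")
}

#' Mantel test
#'
#' Pearson correlation between the upper-triangle entries of two symmetric
#' matrices, with significance from simultaneous row/column permutations of
#' the first matrix (add-one p-value convention).
#'
#' @param A,B Symmetric numeric matrices over the same units.
#' @param n_perm Number of permutations (default 999).
#' @param seed Mandatory RNG seed.
#' @param alternative `"greater"` for a one-sided test of positive
#'   association (the distance-decay decision), or `"two.sided"`.
#' @return List with `r`, `p`, `n_perm`, `alternative`, `n` (matrix order).
#' @export
mantel_test <- function(A, B, n_perm = 999, seed,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)), nrow(A) == ncol(A), nrow(A) >= 3)
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_pg("zero variance among pairwise values: Mantel r undefined")
  }
  r_obs <- stats::cor(a, b)
  n <- nrow(A)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(n)
      Ap <- A[pr, pr]
      stats::cor(Ap[ut], b)
    }, numeric(1))
  })
  hits <- if (alternative == "greater") sum(r_perm >= r_obs)
          else sum(abs(r_perm) >= abs(r_obs))
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
       alternative = alternative, n = n)
}

#' Standardized phylogenetic distinctiveness of grid cells
#'
#' Tests for distance decay with a one-sided Mantel test of `v_ij` against
#' `ln(d_ij)`.  If the positive correlation is significant (`p < alpha`),
#' `S'_ij` are the ordinary-least-squares residuals of the regression of
#' `v_ij` on `ln(d_ij)` over unique unordered cell pairs; otherwise `S'_ij`
#' are the centred `v_ij`.  Either way the mean over all pairs is zero.  The
#' per-cell distinctiveness `S'_i` is the mean of `S'_ij` over all pairs
#' involving cell `i`: cells holding haplotypes divergent from the rest of
#' the study area — beyond what geographic distance explains — score high.
#'
#' @param M A `"cell_pair_matrix"` from [between_cell_matrices()].
#' @param n_perm Mantel permutations (default 999).
#' @param seed Mandatory RNG seed.
#' @param alpha Significance level for the Mantel branch decision
#'   (default 0.05).
#' @return A `"distinctiveness_result"`: list with `S_ij` (matrix, `NA`
#'   diagonal), `S_i` (named vector), `mantel` (r, p), `branch`
#'   (`"residuals"` or `"centered"`), and the regression coefficients when
#'   the residual branch is taken.
#' @export
distinctiveness_scores <- function(M, n_perm = 999, seed, alpha = 0.05) {
  stopifnot(inherits(M, "cell_pair_matrix"))
  ld <- log(M$d)
  diag(ld) <- 0
  mt <- mantel_test(M$v, ld, n_perm = n_perm, seed = seed,
                    alternative = "greater")
  ut <- upper.tri(M$v)
  y <- M$v[ut]; x <- ld[ut]
  k <- nrow(M$v)
  S <- matrix(NA_real_, k, k, dimnames = dimnames(M$v))
  if (mt$p < alpha) {
    fit <- stats::lm(y ~ x)
    res <- stats::resid(fit)
    branch <- "residuals"
    coefs <- stats::coef(fit)
  } else {
    res <- y - mean(y)
    branch <- "centered"
    coefs <- NULL
  }
  S[ut] <- res
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S_i <- rowMeans(S, na.rm = TRUE)
  structure(list(S_ij = S, S_i = S_i, mantel = mt, branch = branch,
                 coefficients = coefs, alpha = alpha),
            class = "distinctiveness_result")
}

#' @export
print.distinctiveness_result <- function(x, ...) {
  cat(sprintf("<distinctiveness> %d cells, branch = %s (Mantel r = %.3f, p = %.4g)\n",
              length(x$S_i), x$branch, x$mantel$r, x$mantel$p))
  invisible(x)
}
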