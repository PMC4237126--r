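# Brute-force oracles, deliberately coded by direct enumeration over
# individuals/pairs rather than the frequency algebra the package uses.

# unbiased gene diversity: fraction of ordered pairs of distinct
# individuals carrying different haplotypes
bf_he <- function(hap) {
  n <- length(hap)
  diff <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && hap[i] != hap[j]) diff <- diff + 1
  }
  diff / (n * (n - 1))
}

# ordered-allele diversity: mean mutation distance over ordered pairs of
# distinct individuals
bf_v <- function(hap, D) {
  n <- length(hap)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) tot <- tot + D[hap[i], hap[j]]
  }
  tot / (n * (n - 1))
}

# Nielsen et al. bias-corrected effective number of haplotypes, written
# directly from counts
bf_nae <- function(hap) {
  n <- length(hap)
  sp2 <- sum((table(hap) / n)^2)
  (n - 1)^2 / (sp2 * (n + 1) * (n - 2) + 3 - n)
}

# Pons & Petit estimators from explicit loops; cells = list of per-cell
# haplotype vectors (character), PI = named distance matrix
bf_pons_petit <- function(cells, PI) {
  C <- length(cells)
  haps <- rownames(PI)
  hk <- vapply(cells, bf_he, numeric(1))
  vk <- vapply(cells, bf_v, numeric(1), D = PI)
  hS <- mean(hk)
  vS <- mean(vk)
  xbar <- rep(0, length(haps))
  names(xbar) <- haps
  for (cell in cells) {
    for (h in haps) xbar[h] <- xbar[h] + mean(cell == h) / C
  }
  n_harm <- C / sum(1 / lengths(cells))
  hT <- 1 - sum(xbar^2) + hS / (n_harm * C)
  vT <- vS / (n_harm * C)
  for (a in haps) for (b in haps) vT <- vT + xbar[a] * xbar[b] * PI[a, b]
  list(hS = hS, hT = hT, GST = (hT - hS) / hT,
       vS = vS, vT = unname(vT), NST = (unname(vT) - vS) / unname(vT))
}

# mean distance between one individual from cell i and one from cell j
bf_vij <- function(cell_i, cell_j, PI) {
  tot <- 0
  for (a in cell_i) for (b in cell_j) tot <- tot + PI[a, b]
  tot / (length(cell_i) * length(cell_j))
}

# random small instance: C cells of sizes 3..6 over H haplotypes with a
# random symmetric integer distance matrix (zero diagonal, >=1 off)
random_instance <- function(C = 4, H = 5, seed) {
  set.seed(seed)
  haps <- paste0("H", seq_len(H))
  PI <- matrix(0, H, H, dimnames = list(haps, haps))
  PI[upper.tri(PI)] <- sample(1:6, H * (H - 1) / 2, replace = TRUE)
  PI[lower.tri(PI)] <- t(PI)[lower.tri(PI)]
  cells <- lapply(seq_len(C), function(i) {
    sample(haps, sample(3:6, 1), replace = TRUE)
  })
  # ensure overall polymorphism so hT > 0
  if (length(unique(unlist(cells))) < 2) cells[[1]][1] <- setdiff(haps, unlist(cells))[1]
  names(cells) <- paste0("cell", seq_len(C))
  list(cells = cells, PI = PI, haps = haps)
}

# package-facing view of an instance: haplotype_set + grid_assignment built
# so that cell_hap_counts reproduces `cells` exactly (each cell placed at
# its own location)
instance_to_objects <- function(inst, min_n = 3) {
  cells <- inst$cells
  H <- length(inst$haps)
  ids <- unlist(lapply(seq_along(cells), function(i) {
    paste0("c", i, "_s", seq_along(cells[[i]]))
  }))
  hap <- unlist(cells)
  counts <- table(factor(hap, levels = inst$haps))
  keep <- counts > 0
  # coded matrix is irrelevant for the estimators; build distinct dummy rows
  sub <- matrix("A", H, H)
  sub[cbind(seq_len(H), seq_len(H))] <- "C"
  carriers <- split(ids, factor(hap, levels = inst$haps))
  hs <- haplotype_set(sub = sub[keep, , drop = FALSE],
                      counts = as.integer(counts[keep]),
                      ids = inst$haps[keep],
                      carriers = carriers[keep], L = 100)
  lon <- rep(seq_along(cells), lengths(cells)) * 2
  lat <- rep(seq_along(cells), lengths(cells))
  st <- data.frame(id = ids, species = "sp", lat = lat, lon = lon)
  assign <- assign_cells(st, grid_spec(1), min_n = min_n)
  list(haps = hs, assign = assign, samples = st,
       PI = inst$PI[inst$haps[keep], inst$haps[keep]])
}

# textbook Pearson r from the summation formula
bf_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# write a FASTA fixture
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

make_samples <- function(ids, lon = NULL, lat = NULL, species = "sp1") {
  if (is.null(lat)) lat <- rep(0, length(ids))
  if (is.null(lon)) lon <- seq_along(ids) * 0.1
  data.frame(id = ids, species = species, lat = lat, lon = lon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
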