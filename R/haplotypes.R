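# per-row character-vector key; safe for zero-character (monomorphic) input
coded_key <- function(sub, indel) {
  if (ncol(sub) + ncol(indel) == 0) return(rep("", nrow(sub)))
  apply(cbind(sub, indel), 1, paste, collapse = "\r")
}

#' Collapse coded sequences into haplotypes
#'
#' Samples with identical coded character vectors (substitution states plus
#' indel presence/absence) are merged into haplotypes.  Haplotype ids `H1,
#' H2, ...` are assigned by decreasing carrier count, ties broken by order of
#' first appearance.  Samples carrying an ambiguous state (`N`) at any
#' varying character cannot be placed and are dropped with a warning.
#'
#' @param coded A `"cp_coded"` object from [code_indels()].
#' @param samples Optional sample table ([sample_table()]); when given, every
#'   coded sample id must be present in it.
#' @return An object of class `"haplotype_set"`: list with `id`, `counts`,
#'   `carriers` (list of sample ids per haplotype), `assignment` (named
#'   vector sample id -> haplotype id), representative coded matrices `sub`
#'   and `indel`, `n` (samples retained), `L` and `dropped`.
#' @examples
#' aln <- alignment(c(a = "ACGTA", b = "ACGTA", c = "ACGTT"))
#' hs <- collapse_haplotypes(code_indels(aln))
#' hs$counts
#' @export
collapse_haplotypes <- function(coded, samples = NULL) {
  stopifnot(inherits(coded, "cp_coded"))
  if (!is.null(samples)) {
    samples <- sample_table(samples)
    missing_ids <- setdiff(coded$ids, samples$id)
    if (length(missing_ids)) {
      stop_pg("coded samples absent from sample table: %s",
              paste(missing_ids, collapse = ", "))
    }
  }
  amb <- rowSums(is.na(coded$sub)) > 0
  if (any(amb)) {
    warn_pg("dropping %d sample(s) with ambiguous states at varying characters: %s",
            sum(amb), paste(coded$ids[amb], collapse = ", "))
  }
  keep <- which(!amb)
  if (!length(keep)) stop_pg("all samples dropped; no unambiguous sequences left")

  sub <- coded$sub[keep, , drop = FALSE]
  indel <- coded$indel[keep, , drop = FALSE]
  ids <- coded$ids[keep]
  key <- coded_key(sub, indel)
  ukey0 <- unique(key)
  first_seen <- match(ukey0, key)
  counts <- tabulate(match(key, ukey0), length(ukey0))
  ord <- order(-counts, first_seen)
  ukey <- ukey0[ord]
  counts <- counts[ord]
  hap_of <- match(key, ukey)
  hid <- paste0("H", seq_along(ukey))
  rep_rows <- match(ukey, key)

  hap_sub <- sub[rep_rows, , drop = FALSE]
  hap_indel <- indel[rep_rows, , drop = FALSE]
  rownames(hap_sub) <- hid
  rownames(hap_indel) <- hid
  carriers <- split(ids, hid[hap_of])[hid]
  assignment <- stats::setNames(hid[hap_of], ids)

  structure(list(id = hid, counts = stats::setNames(counts, hid),
                 carriers = carriers, assignment = assignment,
                 sub = hap_sub, indel = hap_indel,
                 n = length(ids), L = coded$L,
                 dropped = coded$ids[amb]),
            class = "haplotype_set")
}

#' Construct a haplotype set directly from coded matrices
#'
#' Low-level constructor used by the simulator and in tests, when haplotype
#' character vectors and carrier counts are already known.
#'
#' @param sub Character matrix (haplotypes x substitution characters) over
#'   `A,C,G,T,-`; may have zero columns.
#' @param indel 0/1 integer matrix (haplotypes x indel characters); may have
#'   zero columns.
#' @param counts Integer vector of carrier counts (one per haplotype).
#' @param ids Haplotype ids; default `H1..Hk`.
#' @param carriers Optional list of carrier sample ids per haplotype.
#' @param L Alignment length backing the characters (used by per-site
#'   nucleotide diversity); defaults to the number of characters.
#' @return A `"haplotype_set"`.
#' @export
haplotype_set <- function(sub = NULL, indel = NULL, counts,
                          ids = NULL, carriers = NULL, L = NULL) {
  k <- length(counts)
  if (is.null(sub)) sub <- matrix(character(0), k, 0)
  if (is.null(indel)) indel <- matrix(integer(0), k, 0)
  if (!is.matrix(sub)) sub <- as.matrix(sub)
  if (!is.matrix(indel)) indel <- as.matrix(indel)
  stopifnot(nrow(sub) == k, nrow(indel) == k, all(counts >= 1))
  ids <- ids %||% paste0("H", seq_len(k))
  rownames(sub) <- ids
  rownames(indel) <- ids
  key <- coded_key(sub, indel)
  if (anyDuplicated(key)) stop_pg("distinct haplotypes must differ in >= 1 character")
  if (is.null(carriers)) {
    carriers <- lapply(seq_len(k), function(i) {
      paste0(ids[i], "_", seq_len(counts[i]))
    })
    names(carriers) <- ids
  }
  assignment <- stats::setNames(rep(ids, counts), unlist(carriers))
  structure(list(id = ids, counts = stats::setNames(as.integer(counts), ids),
                 carriers = carriers, assignment = assignment,
                 sub = sub, indel = indel, n = sum(counts),
                 L = L %||% (ncol(sub) + ncol(indel)), dropped = character(0)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes, %d samples, %d characters (%d sub + %d indel)\n",
              length(x$id), x$n, ncol(x$sub) + ncol(x$indel),
              ncol(x$sub), ncol(x$indel)))
  invisible(x)
}

#' Expand a haplotype set back to per-sample coded vectors
#'
#' Inverse of [collapse_haplotypes()] for the retained samples; used to
#' verify the collapse round trip.
#'
#' @param haps A `"haplotype_set"`.
#' @return List with per-sample `sub` and `indel` matrices (rownames =
#'   sample ids, in the haplotype-set carrier order).
#' @export
expand_haplotypes <- function(haps) {
  idx <- match(haps$assignment, haps$id)
  sub <- haps$sub[idx, , drop = FALSE]
  indel <- haps$indel[idx, , drop = FALSE]
  rownames(sub) <- names(haps$assignment)
  rownames(indel) <- names(haps$assignment)
  list(sub = sub, indel = indel)
}

#' Summarize sequence polymorphism
#'
#' Reports the number of segregating characters (substitutions plus indels,
#' counting each indel as a single mutation) and per-site nucleotide
#' diversity: the average number of differences per site between two
#' sequences,
#' \deqn{\pi = \frac{n}{n-1} \sum_{h,g} p_h p_g d_{hg} / L,}
#' with `d` the coded mutation distance between haplotypes, together with
#' its standard deviation from the classical total-variance formula
#' (stochastic plus sampling variance) used by the standard population
#' genetics packages.
#'
#' @param haps A `"haplotype_set"` (carries haplotype frequencies and the
#'   alignment length `L`).
#' @param D Optional precomputed [mutation_distance_matrix()].
#' @return List with `snps`, `pi`, `pi_sd`, `n`, `L`, `n_haplotypes`.
#' @examples
#' aln <- alignment(c(a = "ACGTA", b = "ACGTT"))
#' summarize_polymorphism(collapse_haplotypes(code_indels(aln)))$snps
#' @export
summarize_polymorphism <- function(haps, D = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  n <- haps$n
  if (n < 2) stop_pg("polymorphism summary needs at least 2 sequences")
  D <- D %||% mutation_distance_matrix(haps)
  p <- haps$counts / n
  pi <- (n / (n - 1)) * sum(outer(p, p) * D) / haps$L
  # Nei (1987) eq. 10.7 total variance of nucleotide diversity
  v <- (n + 1) / (3 * (n - 1) * haps$L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  snps <- ncol(haps$sub) + ncol(haps$indel)
  list(snps = snps, pi = pi, pi_sd = sqrt(v), n = n, L = haps$L,
       n_haplotypes = length(haps$id))
}

#' Write haplotype outputs
#'
#' Writes the haplotype membership table (sample id -> haplotype id) as TSV
#' and one representative sequence per haplotype as FASTA.
#'
#' @param haps A `"haplotype_set"`.
#' @param aln The source `"cp_alignment"` (for representative sequences).
#' @param membership_path,fasta_path Output file paths (`NULL` to skip one).
#' @return Invisibly, the membership data frame.
#' @export
write_haplotypes <- function(haps, aln = NULL, membership_path = NULL,
                             fasta_path = NULL) {
  mem <- data.frame(id = names(haps$assignment),
                    haplotype = unname(haps$assignment))
  if (!is.null(membership_path)) {
    utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    stopifnot(inherits(aln, "cp_alignment"))
    reps <- vapply(haps$carriers, `[[`, character(1), 1)
    lines <- character(0)
    for (i in seq_along(haps$id)) {
      lines <- c(lines, paste0(">", haps$id[i]),
                 paste(aln$mat[reps[i], ], collapse = ""))
    }
    writeLines(lines, fasta_path)
  }
  invisible(mem)
}
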