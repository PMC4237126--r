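#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment of a non-recombining locus (for
#' example a chloroplast inter-genic spacer) from FASTA.  Residues are
#' uppercased and restricted to the alphabet `A, C, G, T, -, N`; any other
#' IUPAC ambiguity code is converted to `N` with a warning.  Sequence ids are
#' the first whitespace-delimited token of each header line.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `"cp_alignment"`: a list with elements
#'   `mat` (character matrix, samples x positions, rownames = sample ids),
#'   `ids` and `L` (alignment length).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGTA", ">b", "ACG-A"), fa)
#' aln <- read_alignment(fa)
#' aln$L
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_pg("alignment file not found: %s", path)
  x <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(x) || length(x) == 0) {
    stop_pg("not a readable FASTA file (or empty): %s", path)
  }
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1)
  seqs <- lapply(as.character(x), toupper)
  new_alignment(seqs, ids)
}

#' Construct an alignment from in-memory sequences
#'
#' Mostly used by the simulator and in tests; performs the same validation
#' as [read_alignment()].
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   list of per-sample character vectors.
#' @param ids Optional ids overriding `names(seqs)`.
#' @return A `"cp_alignment"` object.
#' @export
alignment <- function(seqs, ids = NULL) {
  if (is.character(seqs)) seqs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  new_alignment(lapply(seqs, toupper), ids %||% names(seqs))
}

new_alignment <- function(seqs, ids) {
  if (length(seqs) < 1) stop_pg("alignment must contain at least one record")
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop_pg("unequal sequence lengths in alignment (%s)",
            paste(unique(lens), collapse = ", "))
  }
  if (lens[1] < 1) stop_pg("alignment length must be >= 1")
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop_pg("every alignment record needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop_pg("duplicated sequence ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- ids
  bad <- !(mat %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warn_pg("%d residue(s) outside {A,C,G,T,-,N} converted to N", sum(bad))
    mat[bad] <- "N"
  }
  structure(list(mat = mat, ids = ids, L = ncol(mat)), class = "cp_alignment")
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat(sprintf("<cp_alignment> %d sequences x %d positions\n",
              length(x$ids), x$L))
  invisible(x)
}

#' Read a georeferenced sample table
#'
#' Tab-delimited file with a header containing at least the columns
#' `id`, `species`, `lat`, `lon` (decimal degrees, WGS84).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with columns `id`, `species`, `lat`, `lon`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_pg("sample table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df)
}

#' Validate a sample table held in a data frame
#'
#' @param df Data frame with columns `id`, `species`, `lat`, `lon`.
#' @return The validated data frame (coordinates numeric).
#' @export
sample_table <- function(df) {
  need <- c("id", "species", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_pg("sample table missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  df$id <- as.character(df$id)
  df$species <- as.character(df$species)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  if (anyNA(df$lat) || anyNA(df$lon)) stop_pg("non-numeric coordinates in sample table")
  if (any(abs(df$lat) > 90)) stop_pg("latitude out of range [-90, 90]")
  if (any(abs(df$lon) > 180)) stop_pg("longitude out of range [-180, 180]")
  if (anyDuplicated(df$id)) {
    stop_pg("duplicated sample ids: %s",
            paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Code an alignment into substitution and indel characters
#'
#' Applies simple indel coding: each maximal gap run (identical start and end
#' positions across the samples that share it) becomes one binary
#' presence/absence character, so a multi-position insertion or deletion
#' counts as a single mutation.  Overlapping but non-identical runs become
#' separate characters.  Substitution characters are taken from alignment
#' columns with at least two distinct non-gap, non-ambiguous states; `N` is
#' recorded as missing (`NA`), and a gap at a substitution column is carried
#' as the state `"-"` (its mutational cost is carried by the indel character
#' covering it, never counted twice).
#'
#' @param aln A `"cp_alignment"`.
#' @param mask_cols Optional integer vector of 1-based alignment columns to
#'   exclude from substitution characters (e.g. user-identified unreliable
#'   sites such as suspected reverse mutations).
#' @return An object of class `"cp_coded"`: list with `sub` (samples x S
#'   character matrix), `sub_cols` (source columns), `indel` (samples x I 0/1
#'   matrix), `indel_spans` (data.frame start/end), `ids`, `L`.
#' @examples
#' aln <- alignment(c(a = "ACGTA", b = "AC--A", c = "ACGTA"))
#' cd <- code_indels(aln)
#' ncol(cd$indel)  # 1 indel character
#' ncol(cd$sub)    # 0 substitution characters
#' @export
code_indels <- function(aln, mask_cols = integer(0)) {
  stopifnot(inherits(aln, "cp_alignment"))
  m <- aln$mat
  n <- nrow(m)

  # maximal gap runs per sample
  spans <- list()  # key "start:end" -> span
  span_members <- list()
  for (i in seq_len(n)) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      key <- paste0(starts[j], ":", ends[j])
      spans[[key]] <- c(starts[j], ends[j])
      span_members[[key]] <- c(span_members[[key]], i)
    }
  }
  if (length(spans)) {
    sp <- do.call(rbind, spans)
    ord <- order(sp[, 1], sp[, 2])
    keys <- names(spans)[ord]
    indel <- matrix(0L, n, length(keys),
                    dimnames = list(aln$ids, paste0("indel_", keys)))
    for (k in seq_along(keys)) indel[span_members[[keys[k]]], k] <- 1L
    indel_spans <- data.frame(start = sp[ord, 1], end = sp[ord, 2],
                              row.names = NULL)
  } else {
    indel <- matrix(0L, n, 0, dimnames = list(aln$ids, NULL))
    indel_spans <- data.frame(start = integer(0), end = integer(0))
  }

  # substitution characters: >= 2 distinct states among {A,C,G,T} per column
  cand <- setdiff(seq_len(aln$L), mask_cols)
  is_poly <- vapply(cand, function(j) {
    s <- m[, j]
    length(unique(s[s %in% c("A", "C", "G", "T")])) >= 2
  }, logical(1))
  sub_cols <- cand[is_poly]
  sub <- m[, sub_cols, drop = FALSE]
  sub[sub == "N"] <- NA_character_
  if (length(sub_cols)) colnames(sub) <- paste0("pos_", sub_cols)
  rownames(sub) <- aln$ids

  structure(list(sub = sub, sub_cols = sub_cols, indel = indel,
                 indel_spans = indel_spans, ids = aln$ids, L = aln$L),
            class = "cp_coded")
}

#' Concatenate coded alignments over shared samples
#'
#' Joins the coded characters of several loci by sample id (intersection of
#' ids), so that haplotypes are defined on the concatenated character
#' vectors — the usual treatment when a second spacer is added to increase
#' resolution.
#'
#' @param ... Two or more `"cp_coded"` objects.
#' @return A `"cp_coded"` object over the shared samples; `L` is the summed
#'   alignment length.
#' @export
concat_coded <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !inherits(lst[[1]], "cp_coded")) {
    lst <- lst[[1]]
  }
  stopifnot(length(lst) >= 2, all(vapply(lst, inherits, logical(1), "cp_coded")))
  ids <- Reduce(intersect, lapply(lst, `[[`, "ids"))
  if (length(ids) < 1) stop_pg("no shared sample ids across loci")
  sub <- do.call(cbind, lapply(lst, function(cd) cd$sub[ids, , drop = FALSE]))
  indel <- do.call(cbind, lapply(lst, function(cd) cd$indel[ids, , drop = FALSE]))
  structure(list(sub = sub,
                 sub_cols = unlist(lapply(lst, `[[`, "sub_cols")),
                 indel = indel,
                 indel_spans = do.call(rbind, lapply(lst, `[[`, "indel_spans")),
                 ids = ids,
                 L = sum(vapply(lst, `[[`, numeric(1), "L"))),
            class = "cp_coded")
}
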