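#' Pairwise mutation-step distances between haplotypes
#'
#' Hamming distance over the coded characters: one step per differing
#' substitution character (both states in `A,C,G,T`; a gap state contributes
#' nothing, its cost being carried by the indel character covering it) plus
#' one step per differing indel character.
#'
#' @param haps A `"haplotype_set"`.
#' @return Symmetric integer matrix of mutation steps with zero diagonal,
#'   dimnames = haplotype ids.
#' @export
mutation_distance_matrix <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  coded_distance(haps$sub, haps$indel)
}

# shared distance kernel, also used on networks' node matrices
coded_distance <- function(sub, indel) {
  k <- nrow(sub)
  D <- matrix(0L, k, k)
  for (j in seq_len(ncol(sub))) {
    s <- sub[, j]
    ok <- s %in% c("A", "C", "G", "T")
    D <- D + (outer(s, s, "!=") & outer(ok, ok, "&"))
  }
  for (j in seq_len(ncol(indel))) {
    x <- indel[, j]
    D <- D + outer(x, x, "!=")
  }
  storage.mode(D) <- "integer"
  dimnames(D) <- list(rownames(sub), rownames(sub))
  D
}

# Minimax ("widest path") distances between all node pairs, computed as the
# maximum edge weight along minimum-spanning-tree paths.  An edge belongs to
# some minimum spanning tree iff its weight equals the minimax distance of
# its endpoints (cycle property), which makes the epsilon-relaxed
# minimum-spanning network easy to characterise.
minimax_distances <- function(D) {
  k <- nrow(D)
  if (k == 1) return(matrix(0, 1, 1))
  # deterministic Prim from node 1
  in_tree <- rep(FALSE, k)
  in_tree[1] <- TRUE
  best_w <- D[, 1]
  best_from <- rep(1L, k)
  parent <- rep(NA_integer_, k)
  parent_w <- rep(NA_real_, k)
  for (step in seq_len(k - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]  # which.min ties -> lowest index
    in_tree[v] <- TRUE
    parent[v] <- best_from[v]
    parent_w[v] <- best_w[v]
    upd <- !in_tree & D[, v] < best_w
    best_w[upd] <- D[upd, v]
    best_from[upd] <- v
  }
  # minimax by propagating along the tree from node 1 outwards
  mm <- matrix(0, k, k)
  order_added <- order(!is.na(parent))  # node 1 first, rest in any order
  done <- 1L
  todo <- setdiff(seq_len(k), 1L)
  # process children only after their parent: repeat sweeps
  while (length(todo)) {
    for (v in todo) {
      p <- parent[v]
      if (p %in% done) {
        mm[v, ] <- pmax(mm[p, ], parent_w[v])
        mm[, v] <- mm[v, ]
        mm[v, v] <- 0
        done <- c(done, v)
      }
    }
    todo <- setdiff(todo, done)
  }
  mm
}

mst_edges_weight <- function(D) {
  k <- nrow(D)
  if (k <= 1) return(0)
  in_tree <- rep(FALSE, k); in_tree[1] <- TRUE
  best_w <- D[, 1]
  total <- 0
  for (step in seq_len(k - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    total <- total + unname(best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & D[, v] < best_w
    best_w[upd] <- D[upd, v]
  }
  total
}

#' Length of a minimum spanning tree over a distance matrix
#'
#' The parsimony length of the most parsimonious tree connecting the
#' haplotypes directly; useful as a baseline when judging how much a
#' median-joining network shortens the connection.
#'
#' @param D Symmetric distance matrix.
#' @return Total weight of a minimum spanning tree.
#' @export
mst_length <- function(D) mst_edges_weight(as.matrix(D))

msn_edge_df <- function(D, epsilon = 0) {
  ids <- rownames(D) %||% paste0("n", seq_len(nrow(D)))
  k <- nrow(D)
  if (k == 1) {
    return(data.frame(from = character(0), to = character(0),
                      steps = numeric(0)))
  }
  mm <- minimax_distances(D)
  keep <- which(upper.tri(D) & D <= mm + epsilon, arr.ind = TRUE)
  data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
             steps = D[keep], stringsAsFactors = FALSE)
}

new_haplo_network <- function(ids, counts, is_median, edges, D, epsilon) {
  ord <- order(ids)
  nodes <- data.frame(id = ids, count = counts, is_median = is_median,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 total_length = sum(edges$steps), distances = D,
                 epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes (%d median vectors), %d edges, total length %g\n",
              nrow(x$nodes), sum(x$nodes$is_median), nrow(x$edges),
              x$total_length))
  invisible(x)
}

#' Minimum-spanning network of haplotypes
#'
#' The union of all minimum spanning trees over the mutation-step distance
#' matrix, optionally relaxed: with `epsilon > 0`, links are kept whenever
#' their length is within `epsilon` of the threshold at which their
#' endpoints' components merge.  Deterministic given the distance matrix.
#'
#' @param D A symmetric mutation-step distance matrix (from
#'   [mutation_distance_matrix()]), or a `"haplotype_set"`.
#' @param epsilon Non-negative relaxation parameter (default 0).
#' @param counts Optional named carrier counts for the nodes.
#' @return A `"haplo_network"`: list with `nodes` (id, count, is_median),
#'   `edges` (from, to, steps), `total_length` and `epsilon`.
#' @examples
#' hs <- haplotype_set(sub = matrix(c("A", "A", "G",
#'                                    "C", "T", "T"), 3, 2), counts = c(2, 1, 1))
#' minimum_spanning_network(mutation_distance_matrix(hs))
#' @export
minimum_spanning_network <- function(D, epsilon = 0, counts = NULL) {
  if (inherits(D, "haplotype_set")) {
    counts <- counts %||% D$counts
    D <- mutation_distance_matrix(D)
  }
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0), epsilon >= 0)
  ids <- rownames(D) %||% paste0("n", seq_len(nrow(D)))
  dimnames(D) <- list(ids, ids)
  if (nrow(D) > 1 && any(D[upper.tri(D)] < 1)) {
    stop_pg("zero distance between distinct haplotypes; collapse first")
  }
  # deterministic: process in lexicographic id order
  ord <- order(ids)
  D <- D[ord, ord, drop = FALSE]
  edges <- msn_edge_df(D, epsilon)
  new_haplo_network(rownames(D),
                    counts = if (is.null(counts)) rep(NA_integer_, nrow(D))
                             else unname(counts[rownames(D)]),
                    is_median = rep(FALSE, nrow(D)),
                    edges = edges, D = D, epsilon = epsilon)
}

# strict per-character majority of three coded vectors; NULL when any
# character has three distinct states (cannot happen for binary characters)
triplet_median <- function(sub3, indel3) {
  med_sub <- character(ncol(sub3))
  for (j in seq_len(ncol(sub3))) {
    tab <- table(sub3[, j])
    if (max(tab) < 2) return(NULL)
    med_sub[j] <- names(tab)[which.max(tab)]
  }
  med_indel <- integer(ncol(indel3))
  for (j in seq_len(ncol(indel3))) {
    med_indel[j] <- as.integer(sum(indel3[, j]) >= 2)
  }
  list(sub = med_sub, indel = med_indel)
}

#' Median-joining haplotype network
#'
#' Iteratively augments the epsilon-relaxed minimum-spanning network with
#' median vectors (inferred, unsampled haplotypes): for every connected
#' triplet of current nodes, the per-character strict-majority consensus is
#' added as a new node if it is not already present.  When no more vectors
#' can be added, median vectors whose removal leaves the network connected
#' at no greater total length are pruned, so all retained median vectors
#' have degree at least two.
#'
#' @param haps A `"haplotype_set"` (coded characters are required to compute
#'   medians).
#' @param epsilon Non-negative relaxation parameter (default 0).
#' @param max_iter Safety cap on augmentation sweeps.
#' @return A `"haplo_network"`; median vectors are named `mv1, mv2, ...` and
#'   flagged `is_median = TRUE` with `count = 0`.
#' @examples
#' hs <- haplotype_set(indel = rbind(c(1,1,0), c(0,1,1), c(1,0,1)),
#'                     counts = c(1, 1, 1))
#' net <- median_joining_network(hs)
#' net$total_length  # 3: a star around one median vector
#' @export
median_joining_network <- function(haps, epsilon = 0, max_iter = 25) {
  stopifnot(inherits(haps, "haplotype_set"))
  sub <- haps$sub
  indel <- haps$indel
  ids <- haps$id
  is_median <- rep(FALSE, length(ids))
  node_cap <- 10 * length(ids) + 50
  mv_counter <- 0

  repeat {
    ord <- order(ids)
    sub <- sub[ord, , drop = FALSE]
    indel <- indel[ord, , drop = FALSE]
    ids <- ids[ord]
    is_median <- is_median[ord]
    D <- coded_distance(sub, indel)
    edges <- msn_edge_df(D, epsilon)
    k <- length(ids)
    if (k >= 3 && max_iter > 0 && k < node_cap) {
      adj <- matrix(FALSE, k, k, dimnames = list(ids, ids))
      adj[cbind(edges$from, edges$to)] <- TRUE
      adj <- adj | t(adj)
      keys <- apply(cbind(sub, indel), 1, paste, collapse = "\r")
      new_sub <- list(); new_indel <- list(); new_keys <- character(0)
      trip <- utils::combn(k, 3)
      for (t in seq_len(ncol(trip))) {
        i <- trip[1, t]; j <- trip[2, t]; l <- trip[3, t]
        if (adj[i, j] + adj[i, l] + adj[j, l] < 2) next  # not connected
        med <- triplet_median(sub[c(i, j, l), , drop = FALSE],
                              indel[c(i, j, l), , drop = FALSE])
        if (is.null(med)) next
        key <- paste(c(med$sub, med$indel), collapse = "\r")
        if (key %in% keys || key %in% new_keys) next
        new_keys <- c(new_keys, key)
        new_sub[[length(new_sub) + 1]] <- med$sub
        new_indel[[length(new_indel) + 1]] <- med$indel
      }
      if (length(new_keys)) {
        m <- length(new_keys)
        mv_ids <- paste0("zz_mv", mv_counter + seq_len(m))  # sorts after H*
        mv_counter <- mv_counter + m
        sub <- rbind(sub, matrix(unlist(new_sub), m, ncol(sub), byrow = TRUE))
        indel <- rbind(indel,
                       matrix(unlist(new_indel), m, ncol(indel), byrow = TRUE))
        ids <- c(ids, mv_ids)
        rownames(sub) <- ids
        rownames(indel) <- ids
        is_median <- c(is_median, rep(TRUE, m))
        max_iter <- max_iter - 1
        next
      }
    }
    break
  }

  # prune median vectors that do not shorten the network
  repeat {
    removed <- FALSE
    cur_total <- sum(msn_edge_df(coded_distance(sub, indel), epsilon)$steps)
    for (v in ids[is_median]) {
      keep <- ids != v
      D2 <- coded_distance(sub[keep, , drop = FALSE],
                           indel[keep, , drop = FALSE])
      if (sum(msn_edge_df(D2, epsilon)$steps) <= cur_total) {
        sub <- sub[keep, , drop = FALSE]
        indel <- indel[keep, , drop = FALSE]
        is_median <- is_median[keep]
        ids <- ids[keep]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  # final naming: mv1..mvK in sorted order
  mv_new <- paste0("mv", seq_len(sum(is_median)))
  ids[is_median] <- mv_new
  rownames(sub) <- ids
  rownames(indel) <- ids
  ord <- order(ids)
  sub <- sub[ord, , drop = FALSE]; indel <- indel[ord, , drop = FALSE]
  ids <- ids[ord]; is_median <- is_median[ord]
  D <- coded_distance(sub, indel)
  edges <- msn_edge_df(D, epsilon)
  counts <- ifelse(is_median, 0L, haps$counts[ids])
  new_haplo_network(ids, counts, is_median, edges, D, epsilon)
}

#' Convert a haplotype network to igraph
#'
#' @param net A `"haplo_network"`.
#' @return An undirected `igraph` graph with node attributes `count`,
#'   `is_median` and edge attribute `steps` (also copied to `weight`).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- igraph::E(g)$steps
  g
}

#' Write a haplotype network to GraphML and/or edge-list TSV
#'
#' @param net A `"haplo_network"`.
#' @param graphml_path,edgelist_path Output paths (`NULL` to skip either).
#' @return Invisibly `net`.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(net, "haplo_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    utils::write.table(net$edges, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Edge-list TSV with columns from, to, steps.
#' @return Data frame of edges.
#' @export
read_network_edgelist <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Plot a haplotype network
#'
#' Simple plotting hook: node area proportional to haplotype frequency,
#' median vectors drawn as small squares, edges labelled with mutation
#' steps.
#'
#' @param x A `"haplo_network"`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.haplo_network <- function(x, ...) {
  g <- as_igraph(x)
  cnt <- igraph::V(g)$count
  cnt[is.na(cnt)] <- 1
  size <- 8 * sqrt(pmax(cnt, 0.25) / max(cnt, 1)) + 4
  igraph::plot.igraph(
    g,
    vertex.size = size,
    vertex.shape = ifelse(igraph::V(g)$is_median, "square", "circle"),
    vertex.color = ifelse(igraph::V(g)$is_median, "grey70", "tomato"),
    edge.label = igraph::E(g)$steps, ...)
  invisible(x)
}
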