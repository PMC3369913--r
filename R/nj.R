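# Neighbor joining with deterministic tie-breaking, returning an ape "phylo"
# object. Q-matrix ties are broken by the lexicographically lowest label
# pair; negative branch lengths are clamped to 0 with the deficit moved to
# the sister branch (common convention).

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (m - 2) d(i,j) - R(i) - R(j)` (R = row sums over the current
#' matrix of m nodes), with pendant lengths
#' `li = d(i,j)/2 + (R(i) - R(j)) / (2(m - 2))` and reduced distances
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. The three-node remainder is
#' resolved by the closed form `la = (dAB + dAC - dBC) / 2` (and rotations);
#' for two taxa the result is a single path of the given total length.
#'
#' @param d Symmetric numeric matrix with dimnames (taxon labels), zero
#'   diagonal, finite non-negative entries.
#' @return An unrooted `ape::phylo` tree. Additive input distances are
#'   recovered exactly (up to floating point).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (anyNA(d) || any(!is.finite(d))) stop("undefined or non-finite distances")
  if (any(d < 0)) stop("negative input distance")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(d)

  active <- seq_len(n)                    # current node ids
  min_leaf <- c(labels, rep(NA_character_, n))  # per node id: smallest leaf label
  next_id <- n + 1L
  edges <- matrix(numeric(0), ncol = 3L)  # (node_a, node_b, length)
  D <- unname(d)

  while (length(active) > 3L) {
    m <- length(active)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    cand <- which(Q - min(Q) < 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(ij) {
        paste(sort(c(min_leaf[active[ij[1L]]], min_leaf[active[ij[2L]]])),
              collapse = "\r")
      })
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(active[i], u, li), c(active[j], u, lj))
    min_leaf[u] <- min(min_leaf[active[i]], min_leaf[active[j]])
    duk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    active <- c(active[keep], u)
  }

  if (length(active) == 3L) {
    dAB <- D[1L, 2L]; dAC <- D[1L, 3L]; dBC <- D[2L, 3L]
    lens <- c((dAB + dAC - dBC) / 2,
              (dAB + dBC - dAC) / 2,
              (dAC + dBC - dAB) / 2)
    lens[lens < 0] <- 0
    hub <- next_id
    edges <- rbind(edges,
                   c(active[1L], hub, lens[1L]),
                   c(active[2L], hub, lens[2L]),
                   c(active[3L], hub, lens[3L]))
  } else {
    hub <- next_id
    edges <- rbind(edges,
                   c(active[1L], hub, D[1L, 2L] / 2),
                   c(active[2L], hub, D[1L, 2L] / 2))
  }

  build_phylo(edges, n, labels, hub)
}

# Convert the (node_a, node_b, length) edge accumulation into a phylo object
# rooted (arbitrarily) at `hub`; the tree is semantically unrooted.
build_phylo <- function(edges, n_tips, labels, hub) {
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  inc <- vector("list", max(nodes))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    inc[[a]] <- c(inc[[a]], e)
    inc[[b]] <- c(inc[[b]], e)
  }
  newid <- integer(max(nodes))
  newid[seq_len(n_tips)] <- seq_len(n_tips)
  nxt <- n_tips + 1L
  newid[hub] <- nxt; nxt <- nxt + 1L
  out_parent <- integer(0); out_child <- integer(0); out_len <- numeric(0)
  seen <- logical(nrow(edges))
  queue <- hub
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (e in inc[[v]]) {
      if (seen[e]) next
      seen[e] <- TRUE
      w <- if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
      if (w > n_tips) { newid[w] <- nxt; nxt <- nxt + 1L }
      out_parent <- c(out_parent, newid[v])
      out_child <- c(out_child, newid[w])
      out_len <- c(out_len, edges[e, 3L])
      if (w > n_tips) queue <- c(queue, w)
    }
  }
  tr <- list(edge = cbind(out_parent, out_child),
             edge.length = out_len,
             tip.label = labels,
             Nnode = nxt - 1L - n_tips)
  dimnames(tr$edge) <- NULL
  storage.mode(tr$edge) <- "integer"
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

newick_quote <- function(lab) {
  unsafe <- grepl("[][ \t():;,']", lab)
  lab[unsafe] <- paste0("'", gsub("'", "''", lab[unsafe]), "'")
  lab
}

#' Serialize a tree to Newick
#'
#' Wraps `ape::write.tree`, additionally single-quoting labels containing
#' spaces or other Newick-reserved characters (which ape leaves unquoted).
#'
#' @param tree An `ape::phylo` tree.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  orig <- tree$tip.label
  safe <- paste0("hoxTIP", seq_along(orig), "X")
  tree$tip.label <- safe
  s <- ape::write.tree(tree)
  quoted <- newick_quote(orig)
  for (i in seq_along(orig)) s <- sub(safe[[i]], quoted[[i]], s, fixed = TRUE)
  s
}

#' Parse a Newick string
#'
#' Inverse of [to_newick()]; handles single-quoted labels.
#'
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  m <- gregexpr("'(?:[^']|'')*'", text)[[1L]]
  if (m[[1L]] != -1L) {
    labs <- regmatches(text, list(m))[[1L]]
    plain <- gsub("''", "'", substr(labs, 2L, nchar(labs) - 1L))
    safe <- paste0("hoxTIP", seq_along(labs), "X")
    for (i in seq_along(labs)) text <- sub(labs[[i]], safe[[i]], text, fixed = TRUE)
    tr <- ape::read.tree(text = text)
    idx <- match(safe, tr$tip.label)
    tr$tip.label[idx[!is.na(idx)]] <- plain[!is.na(idx)]
    tr
  } else {
    ape::read.tree(text = text)
  }
}

#' Unrooted monophyly of a leaf subset
#'
#' TRUE iff some edge bipartition of the (unrooted) tree isolates exactly
#' the given leaves. The full leaf set and singletons are trivially
#' monophyletic.
#'
#' @param tree An `ape::phylo` tree.
#' @param leaf_subset Non-empty character vector of tip labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, leaf_subset) {
  stopifnot(inherits(tree, "phylo"), length(leaf_subset) >= 1L)
  tips <- tree$tip.label
  unknown <- setdiff(leaf_subset, tips)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  target <- sort(unique(leaf_subset))
  if (length(target) == length(tips) || length(target) == 1L) return(TRUE)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tips)
  below <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) below[[i]] <- tips[[i]]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  for (e in seq_len(nrow(tr$edge))) {
    side <- sort(below[[tr$edge[e, 2L]]])
    if (identical(side, target)) return(TRUE)
    if (identical(sort(setdiff(tips, side)), target)) return(TRUE)
  }
  FALSE
}
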