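#' Jukes-Cantor distance matrix from an alignment
#'
#' Generalized k-state Jukes-Cantor distances between all row pairs:
#' `d = -((k-1)/k) * ln(1 - (k/(k-1)) * p)` where `p` is the mismatch
#' fraction over columns in which both rows are ungapped
#' (pairwise deletion). `p = 0` gives 0; a saturated pair
#' (`p >= (k-1)/k`) gets the configured cap and raises a warning, with the
#' affected pairs recorded in the `"saturated"` attribute.
#'
#' @param alignment An `msa` or named character vector of gapped rows.
#' @param alphabet_size States in the model (20 for protein, 4 for DNA).
#' @param cap Distance assigned to saturated pairs (default 10).
#' @return Symmetric numeric matrix with zero diagonal and ids as dimnames.
#' @export
jc_distance <- function(alignment, alphabet_size = 20L, cap = 10) {
  m <- msa_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 aligned sequences")
  k <- alphabet_size
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= (k - 1) / k) {
        d[i, j] <- d[j, i] <- cap
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -((k - 1) / k) * log(1 - (k / (k - 1)) * p)
      }
    }
  }
  if (any(sat)) {
    warning(sum(sat) / 2, " sequence pair(s) saturated; capped at ", cap)
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Classic neighbor joining: repeated Q-matrix minimization with the
#' standard branch-length formulas. A negative branch length is clamped to
#' zero with the deficit moved to its sister edge (preserving the joined
#' pair's path length). Ties in Q are broken by the lexicographically
#' smallest pair of subtree representative labels, making the topology
#' deterministic.
#'
#' @param dist Symmetric distance matrix with id dimnames (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs id dimnames")
  r <- nrow(d)
  if (r < 3L) stop("neighbor joining needs >= 3 taxa")
  if (any(is.na(d))) stop("distance matrix contains NA")
  # working labels are placeholders; map back at the end
  ph <- sprintf("t%06d", seq_len(r))
  leaf_map <- stats::setNames(ids, ph)
  dimnames(d) <- list(ph, ph)
  newick <- stats::setNames(ph, ph)         # growing subtree strings
  repkey <- stats::setNames(ids, ph)        # min leaf id per subtree, for ties
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(idx) {
      reps <- sort(c(repkey[rownames(d)[idx[1]]], repkey[rownames(d)[idx[2]]]))
      paste(reps, collapse = "\r")
    })
    pickrow <- cand[order(keys)[1], ]
    i <- pickrow[1]; j <- pickrow[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    ni <- rownames(d)[i]; nj <- rownames(d)[j]
    new_lab <- sprintf("n%06d", nrow(d))
    newick[new_lab] <- sprintf("(%s:%.12g,%s:%.12g)",
                               newick[ni], li, newick[nj], lj)
    repkey[new_lab] <- min(repkey[ni], repkey[nj])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_lab
  }
  # final three: star join with the three-point formulas
  labs <- rownames(d)
  la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 newick[labs[1]], la, newick[labs[2]], lb,
                 newick[labs[3]], lc)
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- unname(leaf_map[tree$tip.label])
  tree
}

# Canonical bipartition strings for the internal edges of an unrooted tree:
# each split is represented by the side NOT containing the alphabetically
# first taxon, sorted and collapsed.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it. Deterministic given
#' `seed`.
#'
#' @param alignment An `msa` or named character vector of gapped rows.
#' @param n_replicates Number of bootstrap replicates (the published
#'   analyses use 1000).
#' @param seed Integer RNG seed.
#' @param alphabet_size,cap Passed to [jc_distance()].
#' @return The full-data NJ tree with supports (percentages) in
#'   `node.label` (empty for the basal node and tips' parent edges without a
#'   defined split side).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              alphabet_size = 20L, cap = 10) {
  stopifnot(n_replicates >= 1L)
  m <- msa_matrix(alignment)
  full <- neighbor_joining(suppressWarnings(jc_distance(m_rows(m),
                                                        alphabet_size, cap)))
  target <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, length(target)), target)
  with_local_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      db <- suppressWarnings(jc_distance(m_rows(mb), alphabet_size, cap))
      tb <- tryCatch(neighbor_joining(db), error = function(e) NULL)
      if (is.null(tb)) next
      found <- tree_bipartitions(tb)
      hit <- target %in% found
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / n_replicates
  # attach to internal nodes of the full tree
  parts <- ape::prop.part(full)
  labs <- attr(parts, "labels")
  anchor <- sort(full$tip.label)[1]
  node_lab <- character(full$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (anchor %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(support)) {
      node_lab[k] <- format(round(support[key], 1), trim = TRUE)
    }
  }
  full$node.label <- node_lab
  attr(full, "supports") <- support
  full
}

m_rows <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Root a tree with an outgroup
#'
#' Checks that the outgroup taxa form one side of a bipartition of the
#' unrooted tree (are monophyletic), then places the root at the midpoint of
#' the edge separating the outgroup from the ingroup.
#'
#' @param tree Unrooted `ape::phylo`.
#' @param outgroup_ids Character vector of leaf labels.
#' @return Rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  tips <- tree$tip.label
  if (!all(outgroup_ids %in% tips)) {
    stop("outgroup id(s) not in tree: ",
         paste(setdiff(outgroup_ids, tips), collapse = ", "))
  }
  if (length(outgroup_ids) >= length(tips)) {
    stop("outgroup must be a proper subset of the leaves")
  }
  og <- sort(outgroup_ids)
  if (length(og) == length(tips) - 1L) {
    # complement is a single tip: same separating edge as that tip's pendant
    return(root_with_outgroup(tree, setdiff(tips, og)))
  }
  if (length(og) == 1L) {
    node <- which(tips == og)
    edge_row <- which(tree$edge[, 2] == node)
    return(phytools::reroot(tree, node,
                            position = tree$edge.length[edge_row] / 2))
  }
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  node <- NA_integer_
  for (k in seq_along(parts)) {
    side <- sort(labs[parts[[k]]])
    comp <- sort(setdiff(tips, side))
    if (identical(side, og) || identical(comp, og)) {
      node <- length(tips) + k
      break
    }
  }
  if (is.na(node)) {
    stop("outgroup {", paste(og, collapse = ", "),
         "} is not monophyletic in the unrooted tree")
  }
  edge_row <- which(tree$edge[, 2] == node)
  if (!length(edge_row)) stop("outgroup spans the basal node; cannot root")
  phytools::reroot(tree, node, position = tree$edge.length[edge_row] / 2)
}
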