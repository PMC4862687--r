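#' Build a similarity graph from an edge list or protein set
#'
#' Edges are retained only when `p_value < p_threshold` (strict, i.e. more
#' significant than the threshold); each stored edge carries an attraction
#' weight `-log10(p) + log10(p_threshold)`, which is positive by
#' construction. Duplicate / symmetric pairs collapse to the smaller p.
#' When proteins are supplied instead of an edge list, all-against-all local
#' alignments (see [search_seeds()]) provide the p-values via
#' `p = 1 - exp(-E)`.
#'
#' @param x Edge-list data frame (`node_i`, `node_j`, `p_value`) or named
#'   protein sequences.
#' @param p_threshold Significance threshold (default 1e-9; the cross-species
#'   analyses use 1e-6).
#' @param nodes Optional character vector of node ids (so isolated nodes are
#'   kept); inferred from the input otherwise.
#' @return List of class `similarity_graph`: `nodes`, `edges` (with
#'   `attraction`), `p_threshold`.
#' @export
build_graph <- function(x, p_threshold = 1e-9, nodes = NULL) {
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  if (!is.data.frame(x)) {
    prots <- as_named_chr(x)
    hits <- search_seeds(prots, prots, stats::setNames(
      rep("other", length(prots)), names(prots)))
    hits <- hits[hits$query_id < hits$target_id, , drop = FALSE]
    x <- data.frame(node_i = hits$query_id, node_j = hits$target_id,
                    p_value = pmax(-expm1(-hits$e_value), 1e-300),
                    stringsAsFactors = FALSE)
    if (is.null(nodes)) nodes <- names(prots)
  }
  stopifnot(all(c("node_i", "node_j", "p_value") %in% names(x)))
  x <- x[x$node_i != x$node_j, , drop = FALSE]
  a <- pmin(x$node_i, x$node_j); b <- pmax(x$node_i, x$node_j)
  x <- data.frame(node_i = a, node_j = b, p_value = x$p_value,
                  stringsAsFactors = FALSE)
  x <- x[order(x$node_i, x$node_j, x$p_value), , drop = FALSE]
  x <- x[!duplicated(paste(x$node_i, x$node_j, sep = "\r")), , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(x$node_i, x$node_j)))
  edges <- x[x$p_value < p_threshold, , drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("no edge is more significant than the threshold ", p_threshold)
  }
  edges$attraction <- -log10(edges$p_value) + log10(p_threshold)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, p_threshold = p_threshold),
            class = "similarity_graph")
}

#' Force-directed layout of a similarity graph
#'
#' CLANS-style iterative layout: nodes attract along stored edges with force
#' proportional to the edge's attraction weight times the current distance,
#' and all node pairs repel with force proportional to the inverse distance.
#' Per-step displacements are capped by a linearly cooling step limit, so
#' late iterations make vanishingly small moves. Initial coordinates are
#' uniform in the unit cube drawn from `seed`; the result is fully
#' deterministic given `(graph, dims, iterations, seed)`.
#'
#' @param graph A `similarity_graph`.
#' @param dims 2 or 3.
#' @param iterations Number of optimization cycles (the published analyses
#'   use about 20,000).
#' @param seed Integer RNG seed.
#' @param attract,repulse Force constants.
#' @param max_step Initial per-node displacement cap.
#' @return List of class `clans_layout`: `coordinates` (nodes x dims matrix),
#'   `rng_seed`, `iterations_run`.
#' @export
force_layout <- function(graph, dims = 3L, iterations = 20000L, seed = 1L,
                         attract = 0.05, repulse = 0.05, max_step = 0.1) {
  stopifnot(inherits(graph, "similarity_graph"), dims %in% c(2L, 3L),
            iterations >= 1L)
  n <- length(graph$nodes)
  X <- with_local_seed(seed, matrix(stats::runif(n * dims), nrow = n))
  rownames(X) <- graph$nodes
  if (n > 1L) {
    W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
    if (nrow(graph$edges)) {
      ii <- match(graph$edges$node_i, graph$nodes)
      jj <- match(graph$edges$node_j, graph$nodes)
      W[cbind(ii, jj)] <- graph$edges$attraction
      W[cbind(jj, ii)] <- graph$edges$attraction
    }
    wsum <- rowSums(W)
    for (t in seq_len(iterations)) {
      d2 <- as.matrix(stats::dist(X))^2
      diag(d2) <- Inf
      d2[d2 < 1e-12] <- 1e-12
      K <- 1 / d2
      # attraction: sum_j w_ij (x_j - x_i); repulsion: sum_j (x_i - x_j)/d^2
      force <- attract * (W %*% X - wsum * X) +
        repulse * (rowSums(K) * X - K %*% X)
      cap <- max_step * (1 - (t - 1) / iterations)
      norms <- sqrt(rowSums(force^2))
      scale <- pmin(1, cap / pmax(norms, 1e-12))
      X <- X + force * scale
    }
  }
  structure(list(coordinates = X, rng_seed = seed,
                 iterations_run = iterations), class = "clans_layout")
}

#' Layout energy
#'
#' Sum of attraction-weighted squared edge lengths (over stored edges) minus
#' the pairwise repulsion potential (`-log` distance, whose gradient is the
#' inverse-distance repulsion force).
#'
#' @param graph A `similarity_graph`.
#' @param layout A `clans_layout` (or a coordinate matrix).
#' @param attract,repulse Force constants matching [force_layout()].
#' @return Scalar energy.
#' @export
layout_energy <- function(graph, layout, attract = 0.05, repulse = 0.05) {
  X <- if (inherits(layout, "clans_layout")) layout$coordinates else layout
  e <- 0
  if (nrow(graph$edges)) {
    ii <- match(graph$edges$node_i, rownames(X))
    jj <- match(graph$edges$node_j, rownames(X))
    d2 <- rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2)
    e <- e + attract * sum(graph$edges$attraction * d2) / 2
  }
  if (nrow(X) > 1L) {
    d <- as.matrix(stats::dist(X))
    d[d < 1e-12] <- 1e-12
    e <- e - repulse * sum(log(d[upper.tri(d)]))
  }
  e
}

#' Extract convex clusters from a laid-out similarity graph
#'
#' Edges whose attraction reaches the limit `sd_limit` standard deviations
#' (computed over all stored attraction values) are kept; clusters are the
#' connected components of the kept-edge subgraph with at least `min_size`
#' members, and every other node is reported unclustered. Each cluster is
#' annotated with a convexity score: the fraction of nodes inside the
#' cluster's convex hull (in the first two layout dimensions) that are
#' cluster members. Convexity is reported, not enforced.
#'
#' @param graph A `similarity_graph`.
#' @param layout A `clans_layout` over the same nodes (used only for the
#'   convexity annotation; may be `NULL` to skip it).
#' @param min_size Minimum cluster size (default 4).
#' @param sd_limit Attraction limit in standard deviations (default 0.5).
#' @return List of class `cluster_set`: `clusters` (named list of node-id
#'   vectors), `unclustered`, `convexity` (named numeric),
#'   `attraction_limit`.
#' @export
extract_clusters <- function(graph, layout = NULL, min_size = 4L,
                             sd_limit = 0.5) {
  stopifnot(inherits(graph, "similarity_graph"))
  nodes <- graph$nodes
  if (!length(nodes)) {
    return(structure(list(clusters = list(), unclustered = character(0),
                          convexity = numeric(0), attraction_limit = NA_real_),
                     class = "cluster_set"))
  }
  edges <- graph$edges
  limit <- if (nrow(edges) >= 2L) sd_limit * stats::sd(edges$attraction) else 0
  kept <- edges[edges$attraction >= limit, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[c("node_i", "node_j")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  members <- split(nodes, comp$membership)
  big <- members[lengths(members) >= min_size]
  ord <- order(-lengths(big), vapply(big, min, character(1)))
  big <- big[ord]
  names(big) <- sprintf("C%02d", seq_along(big))
  unclustered <- setdiff(nodes, unlist(big))
  convexity <- stats::setNames(rep(NA_real_, length(big)), names(big))
  if (!is.null(layout)) {
    X <- if (inherits(layout, "clans_layout")) layout$coordinates else layout
    for (nm in names(big)) {
      convexity[nm] <- cluster_convexity(X, big[[nm]])
    }
  }
  structure(list(clusters = big, unclustered = unclustered,
                 convexity = convexity, attraction_limit = limit),
            class = "cluster_set")
}

cluster_convexity <- function(X, members) {
  pts <- X[members, 1:2, drop = FALSE]
  others <- setdiff(rownames(X), members)
  if (!length(others)) return(1)
  hull <- tryCatch(grDevices::chull(pts), error = function(e) NULL)
  if (is.null(hull) || length(hull) < 3L) return(NA_real_)
  boundary <- pts[hull, , drop = FALSE]
  inside <- tryCatch(
    mgcv::in.out(rbind(boundary, boundary[1, ]),
                 X[others, 1:2, drop = FALSE]),
    error = function(e) rep(FALSE, length(others)))
  length(members) / (length(members) + sum(inside))
}

#' Cross-species co-clustering family labels
#'
#' Builds clusters on a joint graph containing both query (e.g. planarian)
#' and reference (e.g. human) receptors, then labels every query node with
#' the majority family among the reference nodes sharing its cluster. Query
#' nodes in clusters containing no reference node are labelled
#' `"phylum-specific"`; ties between reference families give `"ambiguous"`
#' (all tied families recorded); unclustered nodes get `NA`.
#'
#' @param graph Joint `similarity_graph` (built at the cross-species
#'   threshold, conventionally 1e-6).
#' @param reference_families Named character vector: family per reference
#'   node id.
#' @param layout,min_size,sd_limit Passed to [extract_clusters()].
#' @return Data frame `node`, `cluster`, `family`, `tied_families` for every
#'   non-reference node.
#' @export
co_cluster_label <- function(graph, reference_families, layout = NULL,
                             min_size = 4L, sd_limit = 0.5) {
  cs <- extract_clusters(graph, layout, min_size = min_size,
                         sd_limit = sd_limit)
  ref_ids <- names(reference_families)
  query <- setdiff(graph$nodes, ref_ids)
  rows <- lapply(query, function(q) {
    cl <- names(cs$clusters)[vapply(cs$clusters, function(m) q %in% m,
                                    logical(1))]
    if (!length(cl)) {
      return(data.frame(node = q, cluster = NA_character_,
                        family = NA_character_, tied_families = NA_character_,
                        stringsAsFactors = FALSE))
    }
    refs <- intersect(cs$clusters[[cl]], ref_ids)
    if (!length(refs)) {
      fam <- "phylum-specific"; tied <- NA_character_
    } else {
      tab <- sort(table(reference_families[refs]), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) {
        fam <- top; tied <- NA_character_
      } else {
        fam <- "ambiguous"; tied <- paste(sort(top), collapse = ",")
      }
    }
    data.frame(node = q, cluster = cl, family = fam, tied_families = tied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply manual curation directives to a cluster set
#'
#' The published cluster map was adjusted by hand (merging and splitting a
#' few clusters guided by the phylogeny); such adjustments are accepted here
#' only as explicit directives, never automated. `merge A B` combines two
#' clusters under the first label; `split C` dissolves a cluster into the
#' unclustered pool. Every applied directive is recorded in the returned
#' object's `curation_log`.
#'
#' @param cluster_set A `cluster_set`.
#' @param directives Data frame with columns `action` (`"merge"`/`"split"`),
#'   `target`, `other` (second cluster for `merge`, `NA` otherwise).
#' @return The curated `cluster_set` with a `curation_log` element.
#' @export
apply_curation <- function(cluster_set, directives) {
  log <- character(0)
  for (i in seq_len(nrow(directives))) {
    act <- directives$action[i]; tgt <- directives$target[i]
    if (act == "merge") {
      oth <- directives$other[i]
      if (!tgt %in% names(cluster_set$clusters) ||
          !oth %in% names(cluster_set$clusters)) {
        stop("merge directive names unknown cluster: ", tgt, " / ", oth)
      }
      cluster_set$clusters[[tgt]] <- c(cluster_set$clusters[[tgt]],
                                       cluster_set$clusters[[oth]])
      cluster_set$clusters[[oth]] <- NULL
      cluster_set$convexity <- cluster_set$convexity[
        names(cluster_set$convexity) != oth]
      cluster_set$convexity[tgt] <- NA_real_
      log <- c(log, sprintf("merged %s into %s", oth, tgt))
    } else if (act == "split") {
      if (!tgt %in% names(cluster_set$clusters)) {
        stop("split directive names unknown cluster: ", tgt)
      }
      cluster_set$unclustered <- c(cluster_set$unclustered,
                                   cluster_set$clusters[[tgt]])
      cluster_set$clusters[[tgt]] <- NULL
      cluster_set$convexity <- cluster_set$convexity[
        names(cluster_set$convexity) != tgt]
      log <- c(log, sprintf("split %s to unclustered", tgt))
    } else {
      stop("unknown curation action: ", act)
    }
  }
  cluster_set$curation_log <- c(cluster_set$curation_log, log)
  cluster_set
}

# Run expr with a temporary RNG state seeded from `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
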