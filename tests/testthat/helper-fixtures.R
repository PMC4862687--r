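# Shared fixtures built in code: tiny deterministic sequences and an exact
# permutation oracle for the proportions test.

# idealized 7TM protein: Ser tail, 7 x 21-Leu helices, charged inner loops
toy_7tm <- function(n_tm = 7L) {
  inner <- "SSKKRSSKKS"
  outer <- "SSTNGSSTNG"
  parts <- paste(rep("S", 25), collapse = "")
  for (k in seq_len(n_tm)) {
    parts <- c(parts, paste(rep("L", 21), collapse = ""))
    if (k < n_tm) parts <- c(parts, if (k %% 2L == 1L) inner else outer)
  }
  paste(c(parts, "SKKRKSSTNGSS"), collapse = "")
}

# exact two-sample permutation p-value for one gene's proportions (all
# label reassignments of equal group sizes; statistic = |difference of
# library-size-weighted mean proportions|)
perm_test_gene <- function(counts, totals, group) {
  p <- counts / totals
  idx <- seq_along(p)
  g1 <- which(group == unique(group)[1])
  obs <- abs(weighted.mean(p[g1], totals[g1]) -
               weighted.mean(p[-g1], totals[-g1]))
  combs <- utils::combn(idx, length(g1))
  stats <- apply(combs, 2, function(s) {
    abs(weighted.mean(p[s], totals[s]) - weighted.mean(p[-s], totals[-s]))
  })
  mean(stats >= obs - 1e-15)
}

# random additive (tree-metric) distance matrix from a random topology
random_additive_matrix <- function(n_taxa, seed) {
  tr <- gpcrmine:::with_local_seed(seed, {
    t0 <- ape::rtree(n_taxa, br = NULL)
    t0$edge.length <- stats::runif(nrow(t0$edge), 0.05, 1)
    t0
  })
  list(d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label], tree = tr)
}
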