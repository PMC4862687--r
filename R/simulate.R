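# Seeded generators for every input the pipeline consumes. Each returns its
# ground truth alongside the data, and each is byte-deterministic under its
# seed (the RNG state is saved and restored around every call).

# Separate hydrophobic pools keep receptor and decoy helices from looking
# alike to a local aligner, while both still read as strongly hydrophobic.
RECEPTOR_TM_POOL <- c("L", "F", "M")
DECOY_TM_POOL <- c("I", "V", "A")
LOOP_POOL <- c("S", "T", "N", "Q", "G", "D", "E")

# Codon choices per amino acid (stopless reverse translation).
CODON_CHOICES <- split(names(Biostrings::GENETIC_CODE),
                       Biostrings::GENETIC_CODE)

random_seq <- function(pool, n) paste(sample(pool, n, replace = TRUE),
                                      collapse = "")

# Point substitutions that respect the residue's pool, so helices stay
# hydrophobic and family boundaries stay put.
mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) {
    pool <- if (aa[i] %in% RECEPTOR_TM_POOL) RECEPTOR_TM_POOL
    else if (aa[i] %in% DECOY_TM_POOL) DECOY_TM_POOL
    else if (aa[i] %in% c("K", "R")) c("K", "R")
    else if (aa[i] == "P") "P"
    else LOOP_POOL
    repl <- setdiff(pool, aa[i])
    if (!length(repl)) next
    aa[i] <- sample(repl, 1)
  }
  paste(aa, collapse = "")
}

# 7TM receptor scaffold: hydrophilic N-tail, seven 21-residue hydrophobic
# helices, K/R-rich loops on the cytoplasmic side only (loops 1, 3, 5, 7
# counting the C-tail), so the hydropathy/positive-inside stand-in calls
# N-out / C-in. The first 20 N-tail residues double as the family "anchor"
# fragment that decoys carry to trip a naive similarity search.
receptor_scaffold <- function() {
  tail_n <- paste0(random_seq(LOOP_POOL, 20), random_seq(LOOP_POOL, 5))
  inner_loop <- function() paste0("SS", random_seq(c("K", "R"), 3), "SS",
                                  random_seq(c("K", "R"), 2), "S")
  outer_loop <- function() random_seq(c("S", "T", "N", "G", "Q"), 10)
  parts <- tail_n
  for (k in 1:7) {
    parts <- c(parts, random_seq(RECEPTOR_TM_POOL, 21))
    if (k < 7) {
      parts <- c(parts, if (k %% 2L == 1L) inner_loop() else outer_loop())
    }
  }
  c_tail <- paste0("S", random_seq(c("K", "R"), 4),
                   random_seq(c("S", "T", "N", "G"), 7))
  paste(c(parts, c_tail), collapse = "")
}

# Multi-TM non-receptor decoy (ion-channel-like): carries a lightly mutated
# copy of the receptor anchor fragment behind a proline-rich spacer (so
# seed searches pick it up at moderate significance but alignments cannot
# extend), then ten decoy-pool helices with proline/acidic loops.
decoy_scaffold <- function(anchor) {
  parts <- c(mutate_protein(anchor, 0.10), "PPGPPNPP")
  for (k in 1:10) {
    parts <- c(parts, random_seq(DECOY_TM_POOL, 21))
    if (k < 10) {
      parts <- c(parts, paste0("PP", random_seq(c("D", "E", "K"), 3),
                               "PP", random_seq(c("D", "E"), 2), "P"))
    }
  }
  paste(c(parts, "PDEDKNPSTG"), collapse = "")
}

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(CODON_CHOICES[[a]], 1), character(1)),
        collapse = "")
}

# 5' UTR whose reading frame (relative to the ATG that follows) is stopless
# except for a terminal in-frame TAA when `with_stop`.
make_utr5 <- function(n_codons = 10L, with_stop = TRUE) {
  safe <- setdiff(names(Biostrings::GENETIC_CODE),
                  c(STOP_CODONS, "ATG"))
  body <- paste(sample(safe, n_codons, replace = TRUE), collapse = "")
  if (with_stop) paste0(body, "TAA") else paste0(body, sample(safe, 1))
}

#' Embed a protein in a synthetic transcript
#'
#' Reverse-translates a protein with random synonymous codons and flanks it
#' with untranslated regions: optionally an in-frame stop immediately
#' upstream of the ATG (so the amino end curates as trusted) and a stop
#' codon plus 3' UTR downstream.
#'
#' @param protein Protein string (no start methionine required; one is
#'   prepended).
#' @param complete_5p Include the upstream in-frame stop.
#' @param complete_3p Include the terminal stop codon and 3' UTR.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return Single transcript string.
#' @export
protein_to_transcript <- function(protein, complete_5p = TRUE,
                                  complete_3p = TRUE, seed = NULL) {
  run <- function() {
    cds <- paste0("ATG", reverse_translate(protein))
    utr5 <- make_utr5(10L, with_stop = complete_5p)
    if (complete_3p) {
      utr3 <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                   STOP_CODONS), 10, replace = TRUE),
                    collapse = "")
      paste0(utr5, cds, "TAA", utr3)
    } else {
      paste0(utr5, cds)
    }
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Synthetic transcriptome with planted receptors and decoys
#'
#' Emulates a de novo transcriptome as the mining stage sees it: planted
#' seven-transmembrane receptors (hydrophobic 21-residue helices, positive-
#' inside loop charge, recognizable by the seed family), multi-TM non-GPCR
#' decoys (ten helices, ion-channel-like, similar enough to trip a naive
#' similarity search and strongly similar to the non-GPCR seed class), and
#' ORF-free background transcripts. The completeness mix controls the
#' fraction of receptor transcripts lacking the 5' upstream stop or the 3'
#' stop codon, which drives the end-curation flag space.
#'
#' @param n_receptors,n_decoys,n_background Counts of each transcript class.
#' @param orf_completeness_mix Named numeric (`complete`, `no5`, `no3`)
#'   summing to 1; receptor transcripts are assigned deterministically in
#'   proportion.
#' @param seed Integer seed.
#' @return List: `transcripts` (named character), `seeds` (named proteins),
#'   `seed_classes`, `truth` (data frame: id, class, completeness,
#'   tm segment count of the encoded protein).
#' @export
make_transcriptome <- function(n_receptors = 12L, n_decoys = 8L,
                               n_background = 50L,
                               orf_completeness_mix = c(complete = 0.8,
                                                        no5 = 0.1, no3 = 0.1),
                               seed = 1L) {
  stopifnot(n_receptors >= 0, n_decoys >= 0, n_background >= 0)
  mix <- orf_completeness_mix / sum(orf_completeness_mix)
  with_local_seed(seed, {
    receptor_base <- receptor_scaffold()
    decoy_base <- decoy_scaffold(substr(receptor_base, 1, 20))
    n5 <- floor(mix[["no5"]] * n_receptors)
    n3 <- floor(mix[["no3"]] * n_receptors)
    completeness <- c(rep("no5", n5), rep("no3", n3),
                      rep("complete", n_receptors - n5 - n3))
    transcripts <- character(0)
    truth <- list()
    for (i in seq_len(n_receptors)) {
      prot <- mutate_protein(receptor_base, 0.10)
      id <- sprintf("receptor%02d", i)
      transcripts[id] <- protein_to_transcript(
        prot, complete_5p = completeness[i] != "no5",
        complete_3p = completeness[i] != "no3")
      truth[[id]] <- data.frame(id = id, class = "receptor",
                                completeness = completeness[i],
                                n_tm_true = 7L, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_decoys)) {
      prot <- mutate_protein(decoy_base, 0.10)
      id <- sprintf("decoy%02d", i)
      transcripts[id] <- protein_to_transcript(prot)
      truth[[id]] <- data.frame(id = id, class = "decoy",
                                completeness = "complete", n_tm_true = 10L,
                                stringsAsFactors = FALSE)
    }
    bg <- 0L
    while (bg < n_background) {
      cand <- random_seq(c("A", "C", "G", "T"), sample(500:1200, 1))
      id <- sprintf("background%02d", bg + 1L)
      if (nrow(find_orfs(stats::setNames(cand, id), min_aa_len = 150L)) > 0L) {
        next  # reject the rare background transcript with a long ORF
      }
      transcripts[id] <- cand
      truth[[id]] <- data.frame(id = id, class = "background",
                                completeness = NA_character_,
                                n_tm_true = 0L, stringsAsFactors = FALSE)
      bg <- bg + 1L
    }
    seeds <- character(0)
    for (i in 1:4) {
      seeds[sprintf("gpcr_seed%02d", i)] <-
        paste0("M", mutate_protein(receptor_base, 0.12))
    }
    for (i in 1:6) {
      seeds[sprintf("channel_seed%02d", i)] <-
        paste0("M", mutate_protein(decoy_base, 0.12))
    }
    seed_classes <- stats::setNames(
      ifelse(startsWith(names(seeds), "gpcr"), "gpcr_seed", "non_gpcr_tm"),
      names(seeds))
    list(transcripts = transcripts, seeds = seeds,
         seed_classes = seed_classes,
         truth = do.call(rbind, truth))
  })
}

# log-uniform draw over [lo, hi]
runif_log <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

#' Block-structured similarity edge list
#'
#' Emulates an all-against-all similarity matrix with planted families:
#' within-block p-values are drawn far below the graph threshold and
#' between-block p-values above it (both log-uniform by default).
#'
#' @param block_sizes Integer vector of planted family sizes.
#' @param within_p_law,between_p_law Length-2 bounds of the log-uniform
#'   p-value laws.
#' @param seed Integer seed.
#' @return List: `edges` (complete edge list), `truth` (node, block).
#' @export
make_similarity_blocks <- function(block_sizes = c(6L, 5L, 4L),
                                   within_p_law = c(1e-40, 1e-15),
                                   between_p_law = c(1e-8, 1),
                                   seed = 1L) {
  with_local_seed(seed, {
    nodes <- unlist(lapply(seq_along(block_sizes), function(b) {
      sprintf("B%d_%02d", b, seq_len(block_sizes[b]))
    }))
    block <- rep(seq_along(block_sizes), block_sizes)
    pairs <- utils::combn(seq_along(nodes), 2)
    same <- block[pairs[1, ]] == block[pairs[2, ]]
    p <- numeric(ncol(pairs))
    p[same] <- runif_log(sum(same), within_p_law[1], within_p_law[2])
    p[!same] <- runif_log(sum(!same), between_p_law[1], between_p_law[2])
    list(edges = data.frame(node_i = nodes[pairs[1, ]],
                            node_j = nodes[pairs[2, ]],
                            p_value = p, stringsAsFactors = FALSE),
         truth = data.frame(node = nodes, block = block,
                            stringsAsFactors = FALSE))
  })
}

#' Replicate count table with planted enrichment and abundance bias
#'
#' Emulates the biotype-comparison RNA-seq design: negative-binomial counts
#' for two groups of worms (default six sexual, six asexual, with library
#' sizes around 33,000 reads — roughly 400,000 reads over 12 samples),
#' lognormal baseline abundances, a planted `fold`-enrichment in the sexual
#' group for chosen genes, and an abundance-correlated log2 fold-change bias
#' with slope `bias_slope` on log10 expression (centred, so it leaves the
#' global mean fold change untouched but gives the trend normalization
#' structure to remove).
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group.
#' @param baseline_law `c(meanlog, sdlog)` of the lognormal baseline.
#' @param enriched_ids Indices or names of planted enriched genes (default:
#'   10 genes drawn from the middle abundance tertile).
#' @param fold Planted fold enrichment (sexual over asexual).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param bias_slope Slope of the abundance-correlated bias.
#' @param biol_sd SD of the per-gene biological log2 difference between the
#'   strains, applied to non-enriched genes only (pervasive small true
#'   differences, which is what makes a large fraction of genes
#'   statistically significant in deep designs); planted enrichments are
#'   exactly `fold`. 0 gives exact nulls.
#' @param library_size Mean reads per sample.
#' @param seed Integer seed.
#' @return List: `count_table` (a `count_table`), `truth` (gene, enriched,
#'   true_log2fc, bias, biol, baseline).
#' @export
make_counts <- function(n_genes = 200L, n_per_group = 6L,
                        baseline_law = c(log(100), 2.0),
                        enriched_ids = NULL, fold = 8, dispersion = 0.01,
                        bias_slope = 0.411, biol_sd = 0.5,
                        library_size = 33000L, seed = 1L) {
  stopifnot(fold >= 1, dispersion >= 0)
  with_local_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    lens <- sample(500:3000, n_genes, replace = TRUE)
    mu <- stats::rlnorm(n_genes, baseline_law[1], baseline_law[2])
    if (is.null(enriched_ids)) {
      enriched_ids <- sort(sample(n_genes, min(10L, n_genes)))
    } else if (is.character(enriched_ids)) {
      enriched_ids <- match(enriched_ids, genes)
    }
    enriched <- seq_len(n_genes) %in% enriched_ids
    lmu10 <- log10(mu)
    bias <- bias_slope * (lmu10 - mean(lmu10))
    # background biological strain differences affect the null genes only;
    # the planted enrichment is exactly `fold`
    biol <- stats::rnorm(n_genes, 0, biol_sd) * !enriched
    lfc <- log2(fold) * enriched
    pi_base <- mu * lens
    pi_asex <- pi_base / sum(pi_base)
    w_sex <- pi_base * 2^(lfc + biol + bias)
    pi_sex <- w_sex / sum(w_sex)
    n_samp <- 2L * n_per_group
    group <- rep(c("sexual", "asexual"), each = n_per_group)
    totals <- round(stats::rnorm(n_samp, library_size, library_size * 0.05))
    counts <- matrix(0, n_genes, n_samp,
                     dimnames = list(genes,
                                     sprintf("%s_%d", group,
                                             rep(seq_len(n_per_group), 2))))
    size <- if (dispersion > 0) 1 / dispersion else Inf
    for (j in seq_len(n_samp)) {
      lambda <- totals[j] * if (group[j] == "sexual") pi_sex else pi_asex
      counts[, j] <- if (is.finite(size)) {
        stats::rnbinom(n_genes, mu = lambda, size = size)
      } else stats::rpois(n_genes, lambda)
    }
    ct <- structure(list(genes = genes, lengths = lens,
                         samples = colnames(counts), group = group,
                         counts = counts,
                         total_mapped = stats::setNames(totals,
                                                        colnames(counts))),
                    class = "count_table")
    list(count_table = ct,
         truth = data.frame(gene = genes, enriched = enriched,
                            true_log2fc = lfc, bias = bias, biol = biol,
                            baseline = mu, stringsAsFactors = FALSE))
  })
}

#' Simulate reads from reference transcripts
#'
#' Uniformly positioned substitution-noise reads from a weighted mixture of
#' reference transcripts; a minimal read-level emulation for exercising the
#' mapper.
#'
#' @param references Named reference sequences.
#' @param n_reads Total reads.
#' @param weights Sampling weight per reference (default uniform).
#' @param read_len Read length.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of reads (names record the source gene).
#' @export
make_reads <- function(references, n_reads = 1000L, weights = NULL,
                       read_len = 100L, error_rate = 0.005, seed = 1L) {
  refs <- as_named_chr(references)
  if (is.null(weights)) weights <- rep(1, length(refs))
  with_local_seed(seed, {
    src <- sample(seq_along(refs), n_reads, replace = TRUE,
                  prob = weights / sum(weights))
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- refs[[src[i]]]
      maxs <- max(1L, nchar(s) - read_len + 1L)
      a <- sample.int(maxs, 1)
      rd <- substr(s, a, min(nchar(s), a + read_len - 1L))
      ch <- strsplit(rd, "")[[1]]
      err <- which(stats::runif(length(ch)) < error_rate)
      for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
    names(reads) <- sprintf("read%05d_%s", seq_len(n_reads),
                            names(refs)[src])
    reads
  })
}

#' Sigmoidal dose-response series with additive noise
#'
#' Four-parameter logistic evaluations over a concentration grid (default:
#' eight half-log steps spanning the published nanomolar EC50) plus additive
#' Gaussian noise, clipped to the unit interval as normalized responses are.
#'
#' @param ec50 True EC50 in molar (default 36.7 nM).
#' @param hill Hill slope.
#' @param top,bottom Response asymptotes (fractions of the total calcium
#'   response).
#' @param concentrations Molar concentration grid (>= 4 levels).
#' @param noise_sd Additive Gaussian noise SD.
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return List: `series` (data frame `concentration`, `response`,
#'   `replicate`), `truth` (the generating parameters).
#' @export
make_dose_response <- function(ec50 = 36.7e-9, hill = 1, top = 0.6,
                               bottom = 0.02,
                               concentrations = 10^seq(-10, -6.5, by = 0.5),
                               noise_sd = 0.02, n_replicates = 4L,
                               seed = 1L) {
  stopifnot(all(concentrations > 0), length(unique(concentrations)) >= 4L)
  with_local_seed(seed, {
    grid <- expand.grid(concentration = concentrations,
                        replicate = seq_len(n_replicates))
    mu <- bottom + (top - bottom) /
      (1 + 10^(hill * (log10(ec50) - log10(grid$concentration))))
    resp <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    resp <- pmin(1, pmax(0, resp))
    list(series = data.frame(concentration = grid$concentration,
                             response = resp, replicate = grid$replicate),
         truth = list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
                      noise_sd = noise_sd))
  })
}
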