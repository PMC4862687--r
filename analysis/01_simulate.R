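#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume,
# with ground truth serialized alongside. All stages write under results/.

suppressMessages(library(gpcrmine))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tx <- make_transcriptome(n_receptors = 12, n_decoys = 8, n_background = 50,
                         seed = 101)
write_fasta(tx$transcripts, file.path(out, "transcriptome.fa"))
write_fasta(tx$seeds, file.path(out, "seeds.fa"))
write.table(data.frame(id = names(tx$seed_classes), class = tx$seed_classes),
            file.path(out, "seed_classes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tx$truth, file.path(out, "transcriptome_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("transcriptome: ", length(tx$transcripts), " transcripts (",
        sum(tx$truth$class == "receptor"), " receptors, ",
        sum(tx$truth$class == "decoy"), " decoys)")

bl <- make_similarity_blocks(c(6, 5, 4), seed = 102)
write_edge_list(bl$edges, file.path(out, "similarity_edges.tsv"))
write.table(bl$truth, file.path(out, "similarity_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("similarity blocks: ", nrow(bl$edges), " edges over ",
        nrow(bl$truth), " nodes")

mc <- make_counts(seed = 103)
ctab <- data.frame(gene = mc$count_table$genes,
                   length = mc$count_table$lengths,
                   mc$count_table$counts, check.names = FALSE)
write.table(ctab, file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample = mc$count_table$samples,
                       group = mc$count_table$group,
                       total = mc$count_table$total_mapped),
            file.path(out, "design.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mc$truth, file.path(out, "counts_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("counts: ", nrow(ctab), " genes x ", length(mc$count_table$samples),
        " samples; ", sum(mc$truth$enriched), " planted 8-fold genes")

dr <- make_dose_response(seed = 104)
write.table(dr$series, file.path(out, "dose_response.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("dose-response: ", nrow(dr$series), " points, true EC50 ",
        format(dr$truth$ec50 * 1e9), " nM")
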