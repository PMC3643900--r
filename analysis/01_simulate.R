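#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A mock bone community of four taxa spanning several bacterial phyla, with
# rRNA genes (SSU 1500 bp, LSU 2900 bp) diverged ~10% between taxa. The
# most abundant taxon is simulated as ancient DNA (elevated C->T class rate
# 1e-2/site with 55-fold 5'-terminal enhancement); the remaining taxa are
# modern (error floor only). Reads carry 454-style artifacts: bimodal
# lengths (44/255 bp peaks), emulsion-PCR duplicates, 4-bp key and 44-bp
# end adaptors, homopolymer indels, mean Phred ~27.

suppressMessages(library(bonemeta))
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42

comm <- simulate_community(seed, n_taxa = 4,
                           gene_lengths = c(SSU = 1500, LSU = 2900),
                           divergence = 0.10)
write_reference_table(community_as_reference(comm),
                      file.path(out, "reference.tsv"))

lm <- read_length_model()        # 44/255 bp peaks, 80% short
ad <- adaptor_config()

ancient <- comm[comm$accession %in% comm$accession[grepl("SYN001", comm$accession)], ]
ancient$weight <- ancient$weight / sum(ancient$weight)
modern <- comm[!grepl("SYN001", comm$accession), ]
modern$weight <- modern$weight / sum(modern$weight)

sim_a <- simulate_reads(ancient, 250, length_model = lm, adaptors = ad,
                        damage = damage_model(ct_interior = 1e-2,
                                              terminal_factor = 55),
                        duplication_mean = 2, seed = seed + 1)
sim_m <- simulate_reads(modern, 350, length_model = lm, adaptors = ad,
                        damage = damage_model(ct_interior = 0,
                                              terminal_factor = 1),
                        duplication_mean = 2, seed = seed + 2)
sim_m$reads$id <- sub("^R", "M", sim_m$reads$id)
sim_m$truth$read_id <- sub("^R", "M", sim_m$truth$read_id)

reads <- rbind(sim_a$reads, sim_m$reads)
truth <- rbind(sim_a$truth, sim_m$truth)

write_reads_fastq(reads, file.path(out, "reads_raw.fastq"))
write.table(reads[c("id", "emulsion_set")],
            file.path(out, "reads_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth_table(truth, file.path(out, "truth.tsv"))

cat(sprintf("community: %d taxa / %d reference entries, %d phyla\n",
            4, nrow(comm),
            length(unique(path_at_rank(comm$taxonomy, "phylum")))))
cat(sprintf("simulated %d reads (%d ancient, %d modern), %d duplicate groups\n",
            nrow(reads), nrow(sim_a$reads), nrow(sim_m$reads),
            length(unique(truth$dup_group))))
cat(sprintf("read lengths: median %d bp, range %d-%d\n",
            as.integer(median(nchar(reads$sequence))),
            min(nchar(reads$sequence)), max(nchar(reads$sequence))))
cat("adaptor states (truth):",
    paste(names(table(truth$adaptor_state)), table(truth$adaptor_state),
          collapse = ", "), "\n")
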