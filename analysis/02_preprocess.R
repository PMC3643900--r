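#!/usr/bin/env Rscript
# Stage 2: quality filtering, duplicate removal, adaptor trimming.
#
# Mean-quality filter at 20, strict per-emulsion single-linkage duplicate
# clustering at normalized edit distance 0.03, then removal of the 4-bp
# key adaptor and of full/partial 44-bp end adaptors.

suppressMessages(library(bonemeta))
out <- "results/analysis"
seed <- 42

reads <- read_reads_fastq(file.path(out, "reads_raw.fastq"))
meta <- read.table(file.path(out, "reads_meta.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
reads$emulsion_set <- meta$emulsion_set[match(reads$id, meta$id)]
truth <- read.table(file.path(out, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

n0 <- nrow(reads)
reads <- filter_mean_quality(reads, 20)
cat(sprintf("quality filter (mean >= 20): %d -> %d reads\n", n0, nrow(reads)))

cl <- cluster_duplicates(reads, "linkage", cutoff = 0.03)
write_clusters(cl, file.path(out, "clusters.tsv"))
n1 <- nrow(reads)
reads <- deduplicate(reads, cl)
cat(sprintf("deduplication (single linkage, cutoff 0.03): %d -> %d reads\n",
            n1, nrow(reads)))

ad <- adaptor_config()
reads <- trim_key_adaptor(reads, ad$key_adaptor)
reads <- trim_end_adaptor(reads, ad, min_overlap = 6, max_mismatch_frac = 0.1)
states <- table(reads$adaptor_state)
cat("end-adaptor trimming:",
    paste(names(states), states, collapse = ", "), "\n")

# how well did detection match the simulated adaptor state?
truth_state <- truth$adaptor_state[match(reads$id, truth$read_id)]
agree <- mean(reads$adaptor_state == truth_state)
cat(sprintf("adaptor state agrees with truth for %.1f%% of retained reads\n",
            100 * agree))

write_reads_fastq(reads, file.path(out, "reads_clean.fastq"))
write.table(reads[c("id", "emulsion_set", "adaptor_state")],
            file.path(out, "reads_clean_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
stage_tab <- data.frame(stage = c("input", "quality_filter", "deduplicate"),
                        retained = c(n0, n1, nrow(reads)))
write.table(stage_tab, file.path(out, "stage_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
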