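#!/usr/bin/env Rscript
# Stage 3: rRNA identification and taxonomic assignment.
#
# The reference table is curated (alignment quality >= 75, pintail = 100,
# domain-consistent annotations, informative entries only), reads are
# searched against it at E <= 1e-10 on both strands, and each read with
# hits is classified by the majority (>= 50%) lowest-common-ancestor rule
# over its tied best hits, truncating cross-phylum hit sets to the domain.

suppressMessages(library(bonemeta))
out <- "results/analysis"

reads <- read_reads_fastq(file.path(out, "reads_clean.fastq"))
meta <- read.table(file.path(out, "reads_clean_meta.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
reads$emulsion_set <- meta$emulsion_set[match(reads$id, meta$id)]
ref_raw <- read_reference_table(file.path(out, "reference.tsv"))

# two corrupted entries exercise the curation rules
junk <- ref_raw[1:2, ]
junk$accession <- c("JUNK_LOWQ", "JUNK_CHIMERA")
junk$align_quality <- c(60L, 95L)
junk$pintail <- c(100L, 80L)
ref <- curate_reference_db(rbind(ref_raw, junk))
cat(sprintf("reference curation: %d entries in, %d retained\n",
            nrow(ref_raw) + 2, nrow(ref)))

hits <- search_local(reads, ref, evalue_cutoff = 1e-10)
write_hits_table(hits, file.path(out, "hits.tsv"))
cat(sprintf("similarity search: %d hits, %d/%d reads with >= 1 hit\n",
            nrow(hits), length(unique(hits$qseqid)), nrow(reads)))

asn <- assign_taxonomy_mlca(hits, ref, majority = 0.5, strict_phylum = TRUE)
write.table(asn, file.path(out, "assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("assignment depth:",
    paste(names(table(asn$rank)), table(asn$rank), collapse = ", "), "\n")

for (lvl in c("domain", "phylum", "genus")) {
  prof <- compose_profile(asn, lvl)
  write.table(prof, file.path(out, paste0("profile_", lvl, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
prof <- compose_profile(asn, "phylum")
cat("phylum-level composition:\n")
for (i in seq_len(nrow(prof)))
  cat(sprintf("  %-20s %4d reads  %6.2f%%\n",
              prof$taxon[i], prof$count[i], prof$percent[i]))

# accuracy against simulation truth
truth <- read.table(file.path(out, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
truth_phy <- path_at_rank(truth$taxonomy[match(asn$read_id, truth$read_id)],
                          "phylum")
got_phy <- path_at_rank(asn$taxonomy, "phylum")
cat(sprintf("true phylum recovered for %.1f%% of classified reads\n",
            100 * mean(!is.na(got_phy) & got_phy == truth_phy)))
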