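# Shared synthetic fixtures built in code at test time.

quality_string <- function(n, q = 30L) phred_encode(rep(q, n))

simple_reads <- function(seqs, q = 30L, ids = NULL, emulsion = "set1") {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  read_set(ids, seqs, vapply(nchar(seqs), quality_string, "", q = q),
           emulsion_set = emulsion)
}

# Mutate a sequence at k distinct positions (always to a different base).
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Duplicate-rich synthetic read set with truth for de-duplication tests:
# low error, no adaptors, no damage.
duplicate_fixture <- function(seed, n_reads = 180) {
  comm <- simulate_community(seed, n_taxa = 3,
                             gene_lengths = c(SSU = 1500, LSU = 2900),
                             divergence = 0.1)
  simulate_reads(comm, n_reads,
                 length_model = read_length_model(short_mode = 120,
                                                  long_mode = 220,
                                                  short_fraction = 0.6,
                                                  short_sd = 15, long_sd = 20),
                 adaptors = NULL,
                 damage = damage_model(baseline_error = 5e-3, ct_interior = 0,
                                       terminal_factor = 1,
                                       homopolymer_indel_rate = 2e-3),
                 duplication_mean = 3, seed = seed + 1)
}

# Two-phylum community where only the first taxon's DNA is ancient
# (damaged): the end-to-end contrast fixture.
pipeline_fixture <- function(seed, n_per_taxon = 120) {
  comm <- simulate_community(seed, n_taxa = 2, gene_lengths = c(SSU = 1400),
                             divergence = 0.12)
  lm <- read_length_model(short_mode = 90, long_mode = 180,
                          short_fraction = 0.5, short_sd = 10, long_sd = 20)
  damaged <- comm[1, , drop = FALSE]; damaged$weight <- 1
  modern <- comm[2, , drop = FALSE]; modern$weight <- 1
  s1 <- simulate_reads(damaged, n_per_taxon, length_model = lm,
                       damage = damage_model(ct_interior = 1e-2,
                                             terminal_factor = 1),
                       duplication_mean = 1.3, seed = seed + 1)
  s2 <- simulate_reads(modern, n_per_taxon, length_model = lm,
                       damage = damage_model(ct_interior = 0,
                                             terminal_factor = 1),
                       duplication_mean = 1.3, seed = seed + 2)
  s2$reads$id <- sub("^R", "M", s2$reads$id)
  s2$truth$read_id <- sub("^R", "M", s2$truth$read_id)
  reads <- as_read_set_public(rbind(s1$reads, s2$reads))
  truth <- rbind(s1$truth, s2$truth)
  list(reads = reads, truth = truth, community = comm,
       reference = community_as_reference(comm))
}

# Single-taxon contig simulation for damage parameter recovery: 2000 reads
# of roughly 100-250 bp from one rRNA gene, assembled against the source
# reference, spectrum under the default skip-5 / discard->5 rules.
damage_recovery_spectrum <- function(seed, ct_interior, n_reads = 2000) {
  comm <- simulate_community(seed, n_taxa = 1, gene_lengths = c(SSU = 1500),
                             divergence = 0)
  dm <- damage_model(baseline_error = 4e-4, ct_interior = ct_interior,
                     terminal_factor = 1)
  lm <- read_length_model(short_mode = 130, long_mode = 220,
                          short_fraction = 0.5, short_sd = 15, long_sd = 15)
  sim <- simulate_reads(comm, n_reads, length_model = lm, adaptors = NULL,
                        damage = dm, seed = seed + 1)
  ctg <- build_consensus(sim$reads, seed_reference = comm$sequence)
  substitution_spectrum(ctg)
}

mk_hits <- function(accs, evalues = NULL, read = "q1") {
  n <- length(accs)
  if (is.null(evalues)) evalues <- rep(1e-30, n)
  data.frame(qseqid = read, sseqid = accs, pident = 100, length = 100,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = evalues, bitscore = 200,
             strand = "+", stringsAsFactors = FALSE)
}

mk_ref2 <- function(accs, paths, gene = "SSU", seqs = "ACGT") {
  data.frame(accession = accs, gene = gene, align_quality = 100, pintail = 100,
             taxonomy_silva = paths, informative = TRUE,
             sequence = seqs, stringsAsFactors = FALSE)
}

as_read_set_public <- function(df) {
  read_set(df$id, df$sequence, df$quality, df$emulsion_set, df$adaptor_state)
}
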