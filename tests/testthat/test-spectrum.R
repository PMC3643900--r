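test_that("an identical read contributes no changes and post-skip bases only", {
  cons <- paste(rep("ACGTT", 20), collapse = "")  # 100 bp
  plc <- list(list(read_aln = cons, cons_aln = cons, start_col = 1))
  sp <- substitution_spectrum(make_contig(cons, plc))
  expect_equal(sum(sp$counts), 0)
  expect_equal(sp$bases, 95)  # 100 minus the 5-base anchor run
  expect_equal(sp$n_used, 1)
})

test_that("leading mismatches before the anchor run are ignored (hand trace)", {
  # read: mismatches at positions 1-3, matches 4-8, then consensus C read
  # as T at position 20; exactly one C>T/G>A change must be counted
  cons <- paste0("AAATTGGGGGGGGGGGGGGCGGGGGGGGGG")  # C at position 20
  read <- paste0("CCCTTGGGGGGGGGGGGGGTGGGGGGGGGG")  # pos 1-3 wrong, pos 20 C->T
  plc <- list(list(read_aln = read, cons_aln = cons, start_col = 1))
  sp <- substitution_spectrum(make_contig(cons, plc), skip_run = 5)
  expect_equal(unname(sp$counts["C>T/G>A"]), 1)
  expect_equal(sum(sp$counts), 1)
  # the anchor run is positions 4-8; denominator = positions 9..30
  expect_equal(sp$bases, 22)
})

test_that("reads exceeding max_changes are discarded entirely", {
  cons <- paste(rep("A", 60), collapse = "")
  read <- paste0(paste(rep("A", 10), collapse = ""),
                 paste(rep(c("G", "A", "A", "A", "A", "A", "A"), 7), collapse = ""),
                 "A")
  # 7 G mismatches after the anchor
  plc <- list(list(read_aln = substr(read, 1, 60), cons_aln = cons, start_col = 1))
  sp <- substitution_spectrum(make_contig(cons, plc), skip_run = 5, max_changes = 5)
  expect_equal(sp$n_used, 0)
  expect_equal(sp$n_discarded, 1)
  expect_equal(sum(sp$counts), 0)
  expect_equal(sp$bases, 0)
  sp2 <- substitution_spectrum(make_contig(cons, plc), skip_run = 5,
                               max_changes = Inf)
  expect_equal(sp2$n_used, 1)
  expect_equal(sum(sp2$counts), 7)
})

test_that("a read with no qualifying anchor run is discarded with reason", {
  cons <- paste(rep("ACGT", 3), collapse = "")
  read <- "AGGTACCTAGGT"  # never 5 consecutive matches
  plc <- list(list(read_aln = read, cons_aln = cons, start_col = 1))
  sp <- substitution_spectrum(make_contig(cons, plc), skip_run = 5)
  expect_equal(sp$n_used, 0)
  expect_equal(names(sp$discard_reasons), "no_anchor")
})

test_that("skip-rule spectrum equals the literal brute-force oracle", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:5) {
    cons <- paste(sample(bases, 300, TRUE), collapse = "")
    plc <- lapply(1:30, function(k) {
      start <- sample(1:200, 1)
      len <- sample(50:100, 1)
      frag <- substr(cons, start, start + len - 1)
      frag <- mutate_seq(frag, sample(0:7, 1))
      list(read_aln = frag, cons_aln = substr(cons, start, start + len - 1),
           start_col = start, strand = sample(c("+", "-"), 1))
    })
    for (sr in c(0, 3, 5)) {
      for (mc in c(2, 5, Inf)) {
        sp <- substitution_spectrum(make_contig(cons, plc),
                                    skip_run = sr, max_changes = mc)
        orc <- oracle_skip_spectrum(plc, skip_run = sr, max_changes = mc)
        expect_equal(unname(sp$counts), unname(orc$counts))
        expect_equal(sp$bases, orc$bases)
        expect_equal(sp$n_used, orc$n_used)
      }
    }
  }
})

test_that("with skip 0 and unlimited changes the statistic is plain mismatch counting", {
  set.seed(72)
  cons <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  plc <- lapply(1:40, function(k) {
    start <- sample(1:300, 1)
    len <- sample(40:100, 1)
    frag <- mutate_seq(substr(cons, start, start + len - 1), sample(0:4, 1))
    list(read_aln = frag, cons_aln = substr(cons, start, start + len - 1),
         start_col = start)
  })
  sp <- substitution_spectrum(make_contig(cons, plc), skip_run = 0,
                              max_changes = Inf)
  orc <- oracle_plain_counts(plc)
  expect_equal(unname(sp$counts), unname(orc$counts))
  expect_equal(sp$bases, orc$bases)
})

test_that("the six classes are invariant under reverse-complement relabelling", {
  set.seed(73)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  seqs <- vapply(1:25, function(k) {
    s <- sample(1:400, 1)
    mutate_seq(substr(ref, s, s + sample(60:100, 1)), sample(0:3, 1))
  }, "")
  fwd <- build_consensus(simple_reads(seqs), seed_reference = ref)
  rev <- build_consensus(simple_reads(revcomp(seqs)), seed_reference = ref)
  sp_f <- substitution_spectrum(fwd, skip_run = 0, max_changes = Inf)
  sp_r <- substitution_spectrum(rev, skip_run = 0, max_changes = Inf)
  expect_equal(sp_f$counts, sp_r$counts)
  expect_equal(sp_f$bases, sp_r$bases)
})

test_that("raising max_changes never decreases the counted bases", {
  set.seed(74)
  cons <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  plc <- lapply(1:20, function(k) {
    start <- sample(1:200, 1)
    frag <- mutate_seq(substr(cons, start, start + 79), sample(0:8, 1))
    list(read_aln = frag, cons_aln = substr(cons, start, start + 79),
         start_col = start)
  })
  ctg <- make_contig(cons, plc)
  b <- vapply(c(0, 1, 3, 5, 10, Inf), function(mc)
    substitution_spectrum(ctg, skip_run = 5, max_changes = mc)$bases, numeric(1))
  expect_true(all(diff(b) >= 0))
})

test_that("indel columns are excluded from counts but reported", {
  cons <- paste(rep("ACGTG", 8), collapse = "")                # 40 bp
  # read with a deletion at column 11 and an insertion after column 20
  read_aln <- paste0(substr(cons, 1, 10), "-", substr(cons, 12, 20), "TT",
                     substr(cons, 21, 40))
  cons_aln <- paste0(substr(cons, 1, 20), "--", substr(cons, 21, 40))
  plc <- list(list(read_aln = read_aln, cons_aln = cons_aln, start_col = 1))
  sp <- substitution_spectrum(make_contig(cons, plc), skip_run = 5)
  expect_equal(sum(sp$counts), 0)
  expect_equal(sp$n_indels, 3)  # one deletion column + two insertion columns
  # denominator: 40 aligned matches minus the 5-base anchor, minus deletion
  expect_equal(sp$bases, 34)
})
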