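noise_free <- function() damage_model(baseline_error = 0, ct_interior = 0,
                                      terminal_factor = 1,
                                      homopolymer_indel_rate = 0)

test_that("noise-free reads are exact substrings of their source", {
  comm <- simulate_community(2, n_taxa = 2, gene_lengths = c(SSU = 800),
                             divergence = 0.1)
  sim <- simulate_reads(comm, 50, adaptors = NULL, damage = noise_free(),
                        duplication_mean = 1, seed = 9)
  expect_equal(nrow(sim$reads), 50)
  expect_equal(nrow(sim$truth), 50)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    src <- comm$sequence[comm$accession == tr$accession]
    frag <- substr(src, tr$start, tr$end)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(sim$reads$sequence[i], frag)
    expect_identical(tr$error_positions, "")
    expect_identical(tr$damaged_positions, "")
  }
})

test_that("interior damage rate recovers the per-base class rate (binomial oracle)", {
  comm <- simulate_community(4, n_taxa = 1, gene_lengths = c(SSU = 2000),
                             divergence = 0)
  dm <- damage_model(baseline_error = 0, ct_interior = 0.01,
                     terminal_factor = 1, homopolymer_indel_rate = 0)
  sim <- simulate_reads(comm, 1500,
                        length_model = read_length_model(short_mode = 150,
                                                         long_mode = 150,
                                                         short_fraction = 1,
                                                         short_sd = 10),
                        adaptors = NULL, damage = dm, seed = 21)
  total_bases <- sum(sim$truth$end - sim$truth$start + 1)
  n_damaged <- sum(vapply(strsplit(sim$truth$damaged_positions, ","),
                          function(x) sum(nzchar(x)), numeric(1)))
  expect_gt(total_bases, 1e5)
  sd3 <- 3 * sqrt(0.01 * 0.99 * total_bases)
  expect_lt(abs(n_damaged - 0.01 * total_bases), sd3)
})

test_that("read lengths are bimodal with peaks at 44 and 255 bp", {
  comm <- simulate_community(6, n_taxa = 1, gene_lengths = c(SSU = 2000),
                             divergence = 0)
  sim <- simulate_reads(comm, 1e4, adaptors = NULL, damage = noise_free(),
                        length_model = read_length_model(short_mode = 44,
                                                         long_mode = 255,
                                                         short_fraction = 0.8),
                        seed = 31)
  len <- sim$truth$end - sim$truth$start + 1
  h <- tabulate(len, nbins = 400)
  # each mode must dominate a window around it and beat the inter-modal valley
  expect_gt(h[44], max(h[60:80]))
  win255 <- sum(h[250:260])
  expect_gt(win255, sum(h[150:160]))
  expect_gt(win255, sum(h[390:400]))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  comm <- simulate_community(8, n_taxa = 2, gene_lengths = c(SSU = 400),
                             divergence = 0.1)
  s1 <- simulate_reads(comm, 40, duplication_mean = 2, seed = 77)
  s2 <- simulate_reads(comm, 40, duplication_mean = 2, seed = 77)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("duplicate-group sizes sum to the number of emitted reads", {
  comm <- simulate_community(8, n_taxa = 2, gene_lengths = c(SSU = 400),
                             divergence = 0.1)
  sim <- simulate_reads(comm, 123, duplication_mean = 3, seed = 5)
  expect_equal(sum(table(sim$truth$dup_group)), 123)
  expect_equal(nrow(sim$reads), 123)
  # duplicates share the emulsion set of their group
  per_group_sets <- tapply(sim$reads$emulsion_set, sim$truth$dup_group,
                           function(x) length(unique(x)))
  expect_true(all(per_group_sets == 1))
})

test_that("terminal enhancement elevates position-1 deamination 30-70x", {
  L <- 1000
  comm <- simulate_community(12, n_taxa = 1, gene_lengths = c(SSU = L),
                             divergence = 0)
  dm <- damage_model(baseline_error = 0, ct_interior = 2e-3,
                     terminal_factor = 50, decay_length = 3,
                     homopolymer_indel_rate = 0)
  sim <- simulate_reads(comm, 1.2e4,
                        length_model = read_length_model(short_mode = 120,
                                                         long_mode = 120,
                                                         short_fraction = 1,
                                                         short_sd = 5),
                        adaptors = NULL, damage = dm, seed = 13)
  # per-position damage opportunity and outcome from the truth table
  tmpl <- substr(rep(comm$sequence, nrow(sim$truth)), sim$truth$start, sim$truth$end)
  minus <- sim$truth$strand == "-"
  tmpl[minus] <- revcomp(tmpl[minus])
  dmg_list <- lapply(strsplit(sim$truth$damaged_positions, ","),
                     function(x) as.integer(x[nzchar(x)]))
  opp1 <- hit1 <- opp_int <- hit_int <- 0
  for (i in seq_along(tmpl)) {
    tc <- strsplit(tmpl[i], "")[[1]]
    dmg <- dmg_list[[i]]
    if (tc[1] == "C") { opp1 <- opp1 + 1; hit1 <- hit1 + (1 %in% dmg) }
    interior <- which(tc == "C")
    opp_int <- opp_int + sum(interior > 30)
    hit_int <- hit_int + sum(dmg > 30)
  }
  ratio <- (hit1 / opp1) / (hit_int / opp_int)
  expect_gt(ratio, 30)
  expect_lt(ratio, 70)
})

test_that("adaptor states follow the configured presence model", {
  comm <- simulate_community(2, n_taxa = 1, gene_lengths = c(SSU = 500),
                             divergence = 0)
  ad <- adaptor_config(p_full = 1, p_partial = 0, p_absent = 0)
  sim <- simulate_reads(comm, 30, adaptors = ad, damage = noise_free(), seed = 3)
  expect_true(all(sim$truth$adaptor_state == "full"))
  expect_true(all(startsWith(sim$reads$sequence, ad$key_adaptor)))
  expect_true(all(endsWith(sim$reads$sequence, ad$end_adaptor)))
})

test_that("empty community and bad parameters are rejected", {
  comm <- simulate_community(2, n_taxa = 1, gene_lengths = c(SSU = 100),
                             divergence = 0)
  expect_error(simulate_reads(comm[0, ], 10), "empty")
  expect_error(simulate_reads(comm, 0), "n_reads")
  expect_error(simulate_reads(comm, 10, duplication_mean = 0.5), "duplication_mean")
  expect_error(damage_model(terminal_factor = 0.5), "terminal_factor")
  expect_error(adaptor_config(key_adaptor = "TCAGG"), "key_adaptor")
})
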