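ref_row <- function(acc = "A1", aq = 100, pin = 100,
                    tax = "Bacteria;Actinobacteria;C;O;F;G",
                    tax2 = NULL, informative = TRUE, seq = "ACGT") {
  data.frame(accession = acc, gene = "SSU", align_quality = aq, pintail = pin,
             taxonomy_silva = tax,
             taxonomy_embl = if (is.null(tax2)) tax else tax2,
             informative = informative, sequence = seq,
             stringsAsFactors = FALSE)
}

test_that("reference curation applies the quality, chimera and domain rules", {
  entries <- rbind(
    ref_row("keep", 90, 100),
    ref_row("aq74", 74, 100),          # poorly aligned
    ref_row("aq75", 75, 100),          # boundary: kept
    ref_row("pin99", 90, 99),          # potential chimera
    ref_row("pin100", 90, 100),        # boundary: kept
    ref_row("domconf", 90, 100, tax2 = "Eukaryota;Opisthokonta;C;O;F;G"),
    ref_row("uninf", 90, 100, informative = FALSE),
    ref_row("trna", 90, 100),
    ref_row("nometa", NA, 100))
  suppressMessages(out <- curate_reference_db(entries, trna_blacklist = "trna"))
  expect_setequal(out$accession, c("keep", "aq75", "pin100"))
  rej <- attr(out, "rejections")
  expect_equal(rej$reason[rej$accession == "aq74"], "align_quality < 75")
  expect_equal(rej$reason[rej$accession == "domconf"],
               "domain disagreement between taxonomies")
  expect_match(rej$reason[rej$accession == "nometa"], "missing")
})

test_that("curation is idempotent", {
  entries <- rbind(ref_row("a"), ref_row("b", 60), ref_row("c", 90, 80))
  suppressMessages(once <- curate_reference_db(entries))
  suppressMessages(twice <- curate_reference_db(once))
  attr(once, "rejections") <- attr(twice, "rejections") <- NULL
  expect_identical(once, twice)
})

mk_ref <- function(accs, paths) mk_ref2(accs, paths)

test_that("unanimous hits assign to genus; cross-phylum hits truncate to domain", {
  strep <- "Bacteria;Actinobacteria;Actinomycetia;Streptomycetales;Streptomycetaceae;Streptomyces"
  ref <- mk_ref(paste0("s", 1:10), rep(strep, 10))
  a <- assign_taxonomy_mlca(mk_hits(paste0("s", 1:10)), ref)
  expect_equal(a$rank, "genus")
  expect_equal(a$taxonomy, strep)
  expect_equal(a$n_best, 10)

  # 9 Actinobacteria + 1 Firmicutes: majority would go deep, but the
  # different-phyla rule truncates to domain
  firmi <- "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus"
  ref2 <- mk_ref(paste0("h", 1:10), c(rep(strep, 9), firmi))
  a2 <- assign_taxonomy_mlca(mk_hits(paste0("h", 1:10)), ref2,
                             strict_phylum = TRUE)
  expect_equal(a2$rank, "domain")
  expect_equal(a2$taxonomy, "Bacteria")
  a3 <- assign_taxonomy_mlca(mk_hits(paste0("h", 1:10)), ref2,
                             strict_phylum = FALSE)
  expect_equal(a3$rank, "genus")
})

test_that("majority descent goes one rank deeper than the strict LCA on 3/4 splits", {
  base <- "Bacteria;Actinobacteria;C1;O1;"
  paths <- paste0(base, c("FamA;G1", "FamA;G2", "FamA;G3", "FamB;G4"))
  ref <- mk_ref(paste0("x", 1:4), paths)
  a <- assign_taxonomy_mlca(mk_hits(paste0("x", 1:4)), ref)
  expect_equal(a$rank, "family")
  expect_equal(path_at <- strsplit(a$taxonomy, ";")[[1]][5], "FamA")
  expect_equal(oracle_classical_lca(paths), "Bacteria;Actinobacteria;C1;O1")

  # 2/2 family split: no unique winner, stop at order
  paths2 <- paste0(base, c("FamA;G1", "FamA;G2", "FamB;G3", "FamB;G4"))
  ref2 <- mk_ref(paste0("y", 1:4), paths2)
  a2 <- assign_taxonomy_mlca(mk_hits(paste0("y", 1:4)), ref2)
  expect_equal(a2$rank, "order")
})

test_that("only hits tied at the best rounded e-value participate", {
  strep <- "Bacteria;Actinobacteria;C;O;F;Streptomyces"
  other <- "Bacteria;Firmicutes;C2;O2;F2;Bacillus"
  ref <- mk_ref(c("a", "b", "c"), c(strep, strep, other))
  # c has a worse e-value: excluded, so no phylum conflict
  h <- mk_hits(c("a", "b", "c"), evalues = c(1e-40, 1.0004e-40, 1e-20))
  a <- assign_taxonomy_mlca(h, ref)
  expect_equal(a$n_best, 2)
  expect_equal(a$rank, "genus")
})

test_that("majority LCA equals the brute-force descent oracle on random cases", {
  set.seed(404)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    paths <- random_paths(n)
    maj <- sample(c(0.5, 0.6, 0.75, 1), 1)
    strict <- sample(c(TRUE, FALSE), 1)
    ref <- mk_ref(paste0("acc", seq_len(n)), paths)
    a <- assign_taxonomy_mlca(mk_hits(paste0("acc", seq_len(n))), ref,
                              majority = maj, strict_phylum = strict)
    expected <- oracle_mlca(paths, majority = maj, strict_phylum = strict)
    got <- if (is.na(a$taxonomy)) "" else a$taxonomy
    expect_identical(got, expected)
  }
})

test_that("majority = 1 without the phylum rule reduces to the classical LCA", {
  set.seed(505)
  for (i in 1:300) {
    paths <- random_paths(sample(2:6, 1))
    ref <- mk_ref(paste0("acc", seq_along(paths)), paths)
    a <- assign_taxonomy_mlca(mk_hits(paste0("acc", seq_along(paths))), ref,
                              majority = 1, strict_phylum = FALSE)
    got <- if (is.na(a$taxonomy)) "" else a$taxonomy
    expect_identical(got, oracle_classical_lca(paths))
  }
})

test_that("raising the majority never yields a deeper rank", {
  set.seed(606)
  depth_of <- function(x) if (is.na(x)) 0L else length(strsplit(x, ";")[[1]])
  for (i in 1:100) {
    paths <- random_paths(sample(3:8, 1))
    ref <- mk_ref(paste0("acc", seq_along(paths)), paths)
    h <- mk_hits(paste0("acc", seq_along(paths)))
    d <- vapply(c(0.5, 0.7, 0.9, 1), function(m)
      depth_of(assign_taxonomy_mlca(h, ref, majority = m,
                                    strict_phylum = FALSE)$taxonomy), integer(1))
    expect_true(all(diff(d) <= 0))
  }
})

test_that("profiles count, roll up and conserve reads", {
  asn <- structure(data.frame(
    read_id = paste0("r", 1:105),
    taxonomy = c(rep("Bacteria;Actinobacteria;C;O;F;G", 80),
                 rep("Bacteria;Proteobacteria", 20),
                 rep("Bacteria", 5)),
    rank = c(rep("genus", 80), rep("phylum", 20), rep("domain", 5)),
    n_best = 3, stringsAsFactors = FALSE),
    class = c("assignment_set", "data.frame"))
  prof <- compose_profile(asn, "phylum")
  expect_setequal(prof$taxon, c("Actinobacteria", "Proteobacteria", "Bacteria"))
  expect_equal(prof$count[prof$taxon == "Bacteria"], 5)
  expect_equal(sum(prof$count), 105)
  expect_equal(sum(prof$percent), 100, tolerance = 0.01)
  prof_d <- compose_profile(asn, "domain")
  expect_equal(prof_d$count, 105)
})

test_that("most synthetic reads with hits are assigned their true phylum", {
  comm <- simulate_community(33, n_taxa = 3, gene_lengths = c(SSU = 1200),
                             divergence = 0.08)
  sim <- simulate_reads(comm, 150, adaptors = NULL,
                        damage = damage_model(baseline_error = 5e-3,
                                              ct_interior = 0,
                                              terminal_factor = 1),
                        seed = 34)
  ref <- curate_reference_db(community_as_reference(comm))
  hits <- search_local(sim$reads, ref)
  asn <- assign_taxonomy_mlca(hits, ref)
  truth_phy <- path_at_rank(sim$truth$taxonomy[
    match(asn$read_id, sim$truth$read_id)], "phylum")
  got_phy <- path_at_rank(asn$taxonomy, "phylum")
  ok <- !is.na(got_phy) & got_phy == truth_phy
  expect_gte(mean(ok), 0.95)
})
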