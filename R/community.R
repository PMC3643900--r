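#' Simulate a small reference community of rRNA-bearing taxa
#'
#' Builds a mock community standing in for a curated rRNA reference plus the
#' microbial community of a bone sample: `n_taxa` taxa with complete ranked
#' lineages (domain to genus) spread over at least two phyla, one sequence
#' per gene class per taxon, and normalized abundance weights.
#'
#' Sequences of a gene class are derived from a common random ancestor; each
#' taxon substitutes sites at a rate chosen so that the *pairwise* divergence
#' between any two taxa is approximately `divergence` (solving
#' 2r - 4/3 r^2 = d for the per-lineage rate r, which accounts for
#' coincident substitutions to the same base).
#'
#' @param seed integer RNG seed; fixes every emitted byte.
#' @param n_taxa number of taxa (>= 1).
#' @param gene_lengths named integer vector of gene classes and their lengths,
#'   e.g. `c(SSU = 1500, LSU = 2900)`.
#' @param divergence target pairwise sequence divergence, in `[0, 0.3]`.
#' @param gc GC content of the ancestral sequences.
#' @param weights optional per-taxon abundance weights (recycled over gene
#'   classes and normalized); default is a 1/rank power law.
#' @return A data frame of class `reference_community` with columns
#'   `accession`, `taxonomy` (semicolon-delimited domain..genus), `gene`,
#'   `sequence` and `weight` (summing to 1 over all entries).
#' @export
simulate_community <- function(seed, n_taxa = 6,
                               gene_lengths = c(SSU = 1500, LSU = 2900),
                               divergence = 0.1, gc = 0.55, weights = NULL) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must be in [0, 0.3]")
  if (is.null(names(gene_lengths)) || any(gene_lengths < 1))
    stop("gene_lengths must be a named vector of positive lengths")
  set.seed(seed)

  # per-lineage substitution rate giving the requested pairwise divergence
  r <- if (divergence == 0) 0 else (2 - sqrt(4 - (16 / 3) * divergence)) / (8 / 3)

  phyla <- c("Actinobacteria", "Proteobacteria", "Firmicutes",
             "Bacteroidetes", "Chloroflexi", "Acidobacteria")
  lineage <- function(i) {
    ph <- phyla[(i - 1L) %% length(phyla) + 1L]
    join_path(c("Bacteria", ph,
                paste0(ph, "_class"), paste0(ph, "_order"),
                paste0("fam", sprintf("%02d", i)),
                paste0("gen", sprintf("%02d", i))))
  }

  if (is.null(weights)) weights <- 1 / seq_len(n_taxa)
  weights <- rep_len(weights, n_taxa)
  if (any(weights < 0)) stop("weights must be non-negative")

  bases <- c("A", "C", "G", "T")
  rows <- list()
  k <- 0L
  for (g in names(gene_lengths)) {
    anc <- strsplit(random_dna(gene_lengths[[g]], gc = gc), "")[[1]]
    for (i in seq_len(n_taxa)) {
      s <- anc
      if (r > 0) {
        hit <- which(runif(length(s)) < r)
        if (length(hit)) {
          s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1), "")
        }
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        accession = paste0("SYN", sprintf("%03d", i), "_", g),
        taxonomy = lineage(i), gene = g,
        sequence = paste(s, collapse = ""),
        weight = weights[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$weight <- out$weight / sum(out$weight)
  class(out) <- c("reference_community", "data.frame")
  out
}
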