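DEFAULT_END_ADAPTOR <- "CTGAGCGGGCTGGCAAGGCAGACCGATCGTACGCATGACTGCAG"  # 44 bp
DEFAULT_KEY_ADAPTOR <- "TCAG"                                           # 4 bp

#' Deamination damage and platform-error model
#'
#' Parametrizes post-mortem cytosine deamination (read as C->T, and G->A on
#' the complementary strand) plus the 454 platform error floor.
#'
#' `ct_interior` is the expected per-sequenced-base rate of damage-induced
#' C->T-class changes away from the read ends; internally it is converted to
#' a per-template-C probability (`ct_interior * L / n_C`), so the observed
#' C->T/G->A class frequency of a contig (counts over total bases) recovers
#' `ct_interior` directly. The deamination rate is multiplied at the 5'
#' terminus by `terminal_factor`, decaying geometrically into the read:
#' `rate(pos) = rate_int * (1 + (terminal_factor - 1) * exp(-(pos - 1)/decay_length))`.
#'
#' @param baseline_error per-site substitution error probability of the
#'   instrument (default 4e-4).
#' @param ct_interior per-site C->T-class damage rate away from ends.
#' @param terminal_factor fold enhancement of deamination at read position 1
#'   (>= 1); ancient samples show roughly 50--60-fold enhancement.
#' @param decay_length positions over which the terminal enhancement decays
#'   by a factor e.
#' @param homopolymer_indel_rate per-run probability of a one-base
#'   insertion/deletion in homopolymer runs (length >= 3), the characteristic
#'   454 error mode.
#' @return object of class `damage_model`.
#' @export
damage_model <- function(baseline_error = 4e-4, ct_interior = 5e-3,
                         terminal_factor = 55, decay_length = 3,
                         homopolymer_indel_rate = 1e-3) {
  rates <- c(baseline_error, ct_interior, homopolymer_indel_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  if (terminal_factor < 1) stop("terminal_factor must be >= 1")
  if (decay_length <= 0) stop("decay_length must be positive")
  structure(list(baseline_error = baseline_error, ct_interior = ct_interior,
                 terminal_factor = terminal_factor, decay_length = decay_length,
                 homopolymer_indel_rate = homopolymer_indel_rate),
            class = "damage_model")
}

#' Bimodal read-length model
#'
#' 454 shotgun libraries from degraded bone show a bimodal length
#' distribution: a large fraction of short reads (peak 44 bp) and a smaller
#' fraction of long reads (peak 255 bp). Lengths are drawn from a two-mode
#' normal mixture, rounded and truncated at 20 bp.
#'
#' @param short_mode,long_mode modal lengths (bp).
#' @param short_fraction mixture weight of the short component.
#' @param short_sd,long_sd component standard deviations (bp).
#' @return object of class `read_length_model`.
#' @export
read_length_model <- function(short_mode = 44, long_mode = 255,
                              short_fraction = 0.8, short_sd = 6, long_sd = 30) {
  if (short_mode <= 0 || long_mode <= 0) stop("modes must be positive")
  if (short_fraction < 0 || short_fraction > 1)
    stop("short_fraction must be in [0, 1]")
  structure(list(short_mode = short_mode, long_mode = long_mode,
                 short_fraction = short_fraction,
                 short_sd = short_sd, long_sd = long_sd),
            class = "read_length_model")
}

draw_lengths <- function(model, n) {
  short <- runif(n) < model$short_fraction
  len <- ifelse(short,
                round(rnorm(n, model$short_mode, model$short_sd)),
                round(rnorm(n, model$long_mode, model$long_sd)))
  pmax(len, 20L)
}

#' Adaptor configuration for simulated 454 reads
#'
#' Every raw read begins with a 4-bp key adaptor; the end adaptor (44 bp)
#' is present completely, partially, or not at all, with the given
#' probabilities (partial presence arises when the template is longer than
#' the flow budget).
#'
#' @param key_adaptor 4-base sequence prepended to every read.
#' @param end_adaptor 44-base end adaptor.
#' @param p_full,p_partial,p_absent presence probabilities (normalized).
#' @return object of class `adaptor_config`.
#' @export
adaptor_config <- function(key_adaptor = DEFAULT_KEY_ADAPTOR,
                           end_adaptor = DEFAULT_END_ADAPTOR,
                           p_full = 0.4, p_partial = 0.3, p_absent = 0.3) {
  if (nchar(key_adaptor) != 4) stop("key_adaptor must be exactly 4 bases")
  if (nchar(end_adaptor) != 44) stop("end_adaptor must be exactly 44 bases")
  p <- c(full = p_full, partial = p_partial, none = p_absent)
  if (any(p < 0) || sum(p) <= 0) stop("presence probabilities invalid")
  structure(list(key_adaptor = key_adaptor, end_adaptor = end_adaptor,
                 presence = p / sum(p)), class = "adaptor_config")
}

# Positional deamination probabilities for one template (read orientation,
# position 1 = 5' end). Returns a vector over template positions; non-C
# positions get 0.
deamination_probs <- function(template_chars, dm) {
  L <- length(template_chars)
  is_c <- template_chars == "C"
  nC <- sum(is_c)
  if (nC == 0 || dm$ct_interior == 0) return(numeric(L))
  p_int <- dm$ct_interior * L / nC
  pos <- seq_len(L)
  p <- p_int * (1 + (dm$terminal_factor - 1) * exp(-(pos - 1) / dm$decay_length))
  p[!is_c] <- 0
  pmin(p, 1)
}

apply_homopolymer_indels <- function(chars, rate) {
  if (rate <= 0 || length(chars) < 3) return(list(chars = chars, n = 0L))
  r <- rle(paste(chars))
  n_indel <- 0L
  out <- character(0)
  pos <- 1L
  for (j in seq_along(r$lengths)) {
    run <- chars[pos:(pos + r$lengths[j] - 1L)]
    if (r$lengths[j] >= 3 && runif(1) < rate) {
      n_indel <- n_indel + 1L
      if (runif(1) < 0.5) run <- c(run, run[1]) else run <- run[-1]
    }
    out <- c(out, run)
    pos <- pos + r$lengths[j]
  }
  list(chars = out, n = n_indel)
}

#' Simulate 454-style reads with full ground truth
#'
#' Draws template fragments from a [simulate_community()] reference, applies
#' deamination damage to each template (damage precedes amplification and
#' sequencing), replicates templates into emulsion-PCR duplicate groups,
#' then adds per-read sequencing errors, homopolymer indels, adaptors and
#' qualities. Everything is recorded in a truth table: source entry, strand
#' and coordinates, duplicate group, adaptor state, damaged positions and
#' error positions (insert coordinates, pre-indel).
#'
#' @param community a `reference_community`.
#' @param n_reads number of reads to emit (>= 1).
#' @param length_model a [read_length_model()].
#' @param adaptors an [adaptor_config()], or `NULL` for adaptor-free reads.
#' @param damage a [damage_model()].
#' @param duplication_mean mean duplicate-group size (>= 1); group sizes are
#'   geometric with this mean.
#' @param seed integer RNG seed.
#' @param n_emulsion_sets number of emulsion sets to spread groups over;
#'   duplicates never straddle sets.
#' @param quality_mean,quality_sd per-base Phred quality distribution
#'   (defaults give mean read quality about 27).
#' @return list with elements `reads` (a read set; `adaptor_state` is left
#'   `"unknown"` — the truth table holds the real state) and `truth`
#'   (one row per read).
#' @export
simulate_reads <- function(community, n_reads, length_model = read_length_model(),
                           adaptors = adaptor_config(), damage = damage_model(),
                           duplication_mean = 1, seed = 1,
                           n_emulsion_sets = 4, quality_mean = 27, quality_sd = 4) {
  if (!nrow(community)) stop("community is empty")
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (duplication_mean < 1) stop("duplication_mean must be >= 1")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  # duplicate-group sizes (geometric, mean duplication_mean), truncated to n_reads
  sizes <- integer(0)
  while (sum(sizes) < n_reads) {
    draw <- if (duplication_mean == 1) rep(1L, n_reads)
            else rgeom(max(64L, n_reads), 1 / duplication_mean) + 1L
    sizes <- c(sizes, draw)
  }
  cum <- cumsum(sizes)
  sizes <- sizes[seq_len(which(cum >= n_reads)[1])]
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_reads)
  sizes <- sizes[sizes > 0]
  n_groups <- length(sizes)

  entry_idx <- sample.int(nrow(community), n_groups, replace = TRUE,
                          prob = community$weight)
  strands <- sample(c("+", "-"), n_groups, replace = TRUE)
  lens <- draw_lengths(length_model, n_groups)
  sets <- paste0("emu", (seq_len(n_groups) - 1L) %% n_emulsion_sets + 1L)

  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  ri <- 0L
  for (g in seq_len(n_groups)) {
    src <- community[entry_idx[g], ]
    L_src <- nchar(src$sequence)
    L <- min(lens[g], L_src)
    start <- sample.int(L_src - L + 1L, 1)
    tmpl <- substr(src$sequence, start, start + L - 1L)
    if (strands[g] == "-") tmpl <- revcomp(tmpl)
    tc <- strsplit(tmpl, "")[[1]]

    # deamination on the template molecule, before duplication/sequencing
    p_deam <- deamination_probs(tc, damage)
    dmg_pos <- which(runif(L) < p_deam)
    if (length(dmg_pos)) tc[dmg_pos] <- "T"

    for (d in seq_len(sizes[g])) {
      ri <- ri + 1L
      if (ri > n_reads) break
      rc <- tc
      err_pos <- which(runif(L) < damage$baseline_error)
      if (length(err_pos)) {
        rc[err_pos] <- vapply(rc[err_pos],
                              function(b) sample(setdiff(bases, b), 1), "")
      }
      hp <- apply_homopolymer_indels(rc, damage$homopolymer_indel_rate)
      rc <- hp$chars

      state <- "none"
      tailseq <- ""
      if (!is.null(adaptors)) {
        state <- sample(names(adaptors$presence), 1, prob = adaptors$presence)
        tailseq <- switch(state,
          full = adaptors$end_adaptor,
          partial = substr(adaptors$end_adaptor, 1,
                           sample.int(nchar(adaptors$end_adaptor) - 1L, 1)),
          none = "")
        seqout <- paste0(adaptors$key_adaptor, paste(rc, collapse = ""), tailseq)
      } else {
        seqout <- paste(rc, collapse = "")
      }
      qual <- pmin(pmax(round(rnorm(nchar(seqout), quality_mean, quality_sd)), 2L), 40L)
      id <- paste0("R", sprintf("%06d", ri))
      reads[[ri]] <- data.frame(id = id, sequence = seqout,
                                quality = phred_encode(qual),
                                emulsion_set = sets[g],
                                adaptor_state = "unknown",
                                stringsAsFactors = FALSE)
      truth[[ri]] <- data.frame(
        read_id = id, accession = src$accession, taxonomy = src$taxonomy,
        gene = src$gene, strand = strands[g], start = start,
        end = start + L - 1L, dup_group = paste0("G", sprintf("%06d", g)),
        adaptor_state = state,
        damaged_positions = paste(dmg_pos, collapse = ","),
        error_positions = paste(err_pos, collapse = ","),
        n_indels = hp$n, stringsAsFactors = FALSE)
    }
  }
  reads <- as_read_set(do.call(rbind, reads))
  truth <- do.call(rbind, truth)
  list(reads = reads, truth = truth)
}

#' Write a truth table as tab-separated text
#' @param truth truth table from [simulate_reads()].
#' @param path output file.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
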