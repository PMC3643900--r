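#' @importFrom rlang .data
NULL

IUPAC_CLASSES <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

iupac_to_regex <- function(motif) {
  letters <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC letter(s) in motif: ",
                        paste(bad, collapse = ", "))
  paste(vapply(letters, function(l) {
    cls <- IUPAC_CLASSES[[l]]
    if (length(cls) == 1) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Restriction enzyme mixes
#'
#' An enzyme mix is a named set of IUPAC recognition motifs. `mix1()` and
#' `mix2()` are the two CpG-targeting cocktails used to deplete microbial
#' (high-GC) DNA from ancient-bone libraries: Mix 1 = BstUI (CGCG),
#' BsiEI (CGRYCG), Hpy99I (CGWCG); Mix 2 = BstUI, BsiEI, TaqI (TCGA),
#' MspI (CCGG), TauI (GCSGC), HinP1I (GCGC). All seven motifs are
#' reverse-complement palindromes, so forward-strand scanning is complete.
#'
#' @param name mix label.
#' @param motifs character vector of IUPAC recognition sequences.
#' @return object of class `enzyme_mix`.
#' @export
enzyme_mix <- function(name, motifs) {
  vapply(motifs, iupac_to_regex, "")  # validates
  structure(list(name = name, motifs = motifs), class = "enzyme_mix")
}

#' @rdname enzyme_mix
#' @export
mix1 <- function() enzyme_mix("Mix1", c(BstUI = "CGCG", BsiEI = "CGRYCG",
                                        Hpy99I = "CGWCG"))

#' @rdname enzyme_mix
#' @export
mix2 <- function() enzyme_mix("Mix2", c(BstUI = "CGCG", BsiEI = "CGRYCG",
                                        TaqI = "TCGA", MspI = "CCGG",
                                        TauI = "GCSGC", HinP1I = "GCGC"))

#' Map IUPAC recognition sites on a sequence
#'
#' Returns the 0-based start positions of every occurrence of every motif
#' in the mix, overlapping occurrences included; identical positions
#' reached by two motifs collapse to one. `N` in the sequence matches
#' nothing.
#'
#' @param sequence a DNA string over A/C/G/T/N.
#' @param mix an [enzyme_mix()] (or character vector of motifs).
#' @return sorted integer vector of 0-based cut positions.
#' @export
scan_iupac_motifs <- function(sequence, mix) {
  motifs <- if (inherits(mix, "enzyme_mix")) mix$motifs else mix
  pos <- integer(0)
  for (m in motifs) {
    re <- paste0("(?=", iupac_to_regex(m), ")")
    hit <- gregexpr(re, sequence, perl = TRUE)[[1]]
    if (hit[1] != -1) pos <- c(pos, as.integer(hit) - 1L)
  }
  sort(unique(pos))
}

#' In silico restriction digest of a sequence
#'
#' Cuts are placed at motif start positions (the per-site offset within the
#' recognition sequence is irrelevant for fragment-length summaries);
#' fragments are the intervals between consecutive cuts plus the two flanks.
#'
#' @param sequence a DNA string.
#' @param mix an [enzyme_mix()].
#' @param label sequence label for the summary.
#' @return object of class `digest_summary`: label, length, cut positions,
#'   fragment lengths (summing to the sequence length) and
#'   `mean_fragment` = length / (n_cuts + 1).
#' @export
digest_summary <- function(sequence, mix, label = "seq") {
  if (!nchar(sequence)) stop("empty sequence")
  cuts <- scan_iupac_motifs(sequence, mix)
  L <- nchar(sequence)
  frags <- diff(c(0L, cuts, L))
  structure(list(label = label, length = L, cuts = cuts,
                 fragment_lengths = frags,
                 n_cuts = length(cuts),
                 mean_fragment = L / (length(cuts) + 1)),
            class = "digest_summary")
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf("digest of %s (%d bp): %d cuts, mean fragment %.1f bp\n",
              x$label, x$length, x$n_cuts, x$mean_fragment))
  invisible(x)
}

#' Digest a multi-record FASTA, per record and pooled
#'
#' @param path FASTA file of genome sequences.
#' @param mix an [enzyme_mix()].
#' @return data frame with one row per record plus a `"pooled"` row
#'   (label, length, n_cuts, mean_fragment).
#' @export
digest_fasta <- function(path, mix) {
  seqs <- Biostrings::readDNAStringSet(path)
  rows <- lapply(seq_along(seqs), function(i) {
    d <- digest_summary(as.character(seqs[[i]]), mix, label = names(seqs)[i])
    data.frame(label = d$label, length = d$length, n_cuts = d$n_cuts,
               mean_fragment = d$mean_fragment, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  pooled <- data.frame(label = "pooled", length = sum(df$length),
                       n_cuts = sum(df$n_cuts),
                       mean_fragment = sum(df$length) / (sum(df$n_cuts) + nrow(df)),
                       stringsAsFactors = FALSE)
  rbind(df, pooled)
}

#' Analytic cut density and expected fragment length
#'
#' First-order expectation for i.i.d. sequence: the per-position cut
#' probability is the sum over motifs of the product over motif positions
#' of the summed probabilities of the allowed bases (overlap between motifs
#' ignored); the expected fragment length is its reciprocal.
#'
#' @param base_probs named probabilities for A, C, G, T (must sum to 1).
#' @param mix an [enzyme_mix()].
#' @return list with `cut_prob` (expected cuts per position) and
#'   `expected_fragment_length` (`Inf` when the density is zero).
#' @export
expected_cut_density <- function(base_probs, mix) {
  if (abs(sum(base_probs) - 1) > 1e-8) stop("base probabilities must sum to 1")
  motifs <- if (inherits(mix, "enzyme_mix")) mix$motifs else mix
  p <- sum(vapply(motifs, function(m) {
    prod(vapply(strsplit(m, "")[[1]],
                function(l) sum(base_probs[IUPAC_CLASSES[[l]]]), numeric(1)))
  }, numeric(1)))
  list(cut_prob = p,
       expected_fragment_length = if (p > 0) 1 / p else Inf)
}

#' Check that a mix's motifs are reverse-complement palindromes
#' @param mix an [enzyme_mix()].
#' @return named logical vector, one per motif.
#' @export
is_palindromic_mix <- function(mix) {
  motifs <- if (inherits(mix, "enzyme_mix")) mix$motifs else mix
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  vapply(motifs, function(m) {
    l <- strsplit(m, "")[[1]]
    identical(paste(rev(unname(comp[l])), collapse = ""), m)
  }, logical(1))
}
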