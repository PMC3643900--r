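# Karlin-Altschul constants for the +1/-2 (gap 3/1) scoring scheme used by
# the built-in search. The module's contract is threshold behaviour at the
# e-value cutoff, not e-value agreement with any external engine.
KA_LAMBDA <- 1.33
KA_K <- 0.621

#' Local similarity search of reads against an rRNA reference
#'
#' A desk-scale similarity search: every query is locally aligned (match +1,
#' mismatch -2, gap open 3, gap extend 1) against every reference sequence
#' on both strands; the better strand per (query, reference) pair is kept.
#' E-values follow the Karlin-Altschul form `K * m * n * exp(-lambda * S)`
#' with fixed constants, `m` the query length and `n` the total reference
#' length; hits above `evalue_cutoff` are suppressed.
#'
#' @param queries a read set (or named character vector of sequences).
#' @param references reference entries (needs `accession` and `sequence`
#'   columns), e.g. from [community_as_reference()].
#' @param evalue_cutoff maximum reported e-value (default 1e-10).
#' @return data frame of hit records with the standard 12 tabular columns
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`) plus `strand`. Minus-strand hits have `sstart` >
#'   `send`, the usual tabular convention; query coordinates always refer
#'   to the forward query.
#' @export
search_local <- function(queries, references, evalue_cutoff = 1e-10) {
  if (is.null(nrow(queries)))
    queries <- read_set(names(queries), queries,
                        vapply(nchar(queries), function(n) phred_encode(rep(30L, n)), ""))
  if (is.null(references) || !nrow(references)) stop("empty reference set")
  stopifnot(evalue_cutoff > 0)
  n_db <- sum(nchar(references$sequence))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  qlen <- nchar(queries$sequence)
  hits <- list()
  for (j in seq_len(nrow(references))) {
    subj <- Biostrings::DNAString(references$sequence[j])
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") queries$sequence else revcomp(queries$sequence)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(qseq), subj, type = "local",
        substitutionMatrix = mat, gapOpening = 3, gapExtension = 1)
      score <- Biostrings::score(aln)
      ev <- KA_K * qlen * n_db * exp(-KA_LAMBDA * score)
      keep <- which(ev <= evalue_cutoff)
      if (!length(keep)) next
      pat <- Biostrings::pattern(aln)
      sub <- Biostrings::subject(aln)
      pstart <- Biostrings::start(pat)[keep]
      pend <- Biostrings::end(pat)[keep]
      ni <- Biostrings::nindel(aln)
      insm <- Biostrings::insertion(ni)
      delm <- Biostrings::deletion(ni)
      nmat <- Biostrings::nmatch(aln)[keep]
      nmis <- Biostrings::nmismatch(aln)[keep]
      cols <- nmat + nmis + insm[keep, "WidthSum"] + delm[keep, "WidthSum"]
      gapopens <- insm[keep, "Length"] + delm[keep, "Length"]
      qstart <- if (strand == "+") pstart else qlen[keep] - pend + 1L
      qend <- if (strand == "+") pend else qlen[keep] - pstart + 1L
      sstart <- Biostrings::start(sub)[keep]
      send <- Biostrings::end(sub)[keep]
      if (strand == "-") { tmp <- sstart; sstart <- send; send <- tmp }
      hits[[length(hits) + 1L]] <- data.frame(
        qseqid = queries$id[keep], sseqid = references$accession[j],
        pident = round(100 * nmat / cols, 2), length = cols,
        mismatch = nmis, gapopen = gapopens,
        qstart = qstart, qend = qend, sstart = sstart, send = send,
        evalue = ev[keep],
        bitscore = round((KA_LAMBDA * score[keep] - log(KA_K)) / log(2), 1),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  # keep the better strand per (query, reference) pair
  o <- order(out$qseqid, out$sseqid, out$evalue, -out$bitscore)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(out[c("qseqid", "sseqid")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Import / export hits in 12-column tabular format
#'
#' The standard headerless tabular hit dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`); strand is
#' inferred from `sstart` > `send` on import. External search output in this
#' format can be used anywhere [search_local()] hits can.
#'
#' @param path file path.
#' @return `read_hits_table`: the hit data frame.
#' @export
read_hits_table <- function(path) {
  h <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                  col.names = HIT_COLS)
  h$strand <- ifelse(h$sstart > h$send, "-", "+")
  h
}

#' @rdname read_hits_table
#' @param hits hit records.
#' @export
write_hits_table <- function(hits, path) {
  write.table(format(hits[HIT_COLS], scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
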