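#' @importFrom stats rnorm runif rbinom rgeom setNames aggregate
#' @importFrom utils adist head tail write.table read.table
NULL

# Taxonomic ranks used throughout, shallow to deep.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Decode a Phred+33 quality string to integer scores
#'
#' @param q character vector of Sanger-encoded quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_decode <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of Phred scores (0--93).
#' @return A single character string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0), all(scores <= 93))
  rawToChar(as.raw(as.integer(scores) + 33L))
}

#' Mean Phred quality per read
#' @param reads a read set data frame (see [read_set()]).
#' @return numeric vector of per-read mean qualities.
#' @export
mean_quality <- function(reads) {
  vapply(phred_decode(reads$quality), function(x) mean(x), numeric(1))
}

#' Reverse-complement DNA strings
#' @param x character vector over the DNA alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split semicolon-delimited lineage strings into rank-named labels.
split_path <- function(path) {
  strsplit(path, ";", fixed = TRUE)
}

# Join rank labels back to a lineage string.
join_path <- function(labels) {
  paste(labels, collapse = ";")
}

#' Extract the label at a taxonomic rank from lineage strings
#'
#' @param paths semicolon-delimited lineage strings (domain..genus).
#' @param rank one of domain/phylum/class/order/family/genus.
#' @return character vector; NA where the path is truncated above the rank.
#' @export
path_at_rank <- function(paths, rank) {
  i <- match(rank, TAX_RANKS)
  vapply(split_path(paths), function(p) if (length(p) >= i) p[i] else NA_character_,
         character(1))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Construct a read set
#'
#' A read set is a plain data frame with one row per read: `id`, `sequence`
#' (over A/C/G/T/N), `quality` (Phred+33 string, same length as the
#' sequence), `emulsion_set` (the library partition within which PCR
#' duplicates can arise) and `adaptor_state` (one of full/partial/none/unknown).
#'
#' @param id,sequence,quality,emulsion_set,adaptor_state per-read fields.
#' @return data frame of class `read_set`.
#' @export
read_set <- function(id, sequence, quality, emulsion_set = "set1",
                     adaptor_state = "unknown") {
  stopifnot(length(id) == length(sequence), length(sequence) == length(quality))
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths differ")
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   quality = as.character(quality),
                   emulsion_set = rep_len(as.character(emulsion_set), length(id)),
                   adaptor_state = rep_len(as.character(adaptor_state), length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

as_read_set <- function(df) {
  needed <- c("id", "sequence", "quality")
  if (!all(needed %in% names(df))) stop("not a read set: need id/sequence/quality")
  if (is.null(df$emulsion_set)) df$emulsion_set <- "set1"
  if (is.null(df$adaptor_state)) df$adaptor_state <- "unknown"
  class(df) <- unique(c("read_set", class(df)))
  df
}

#' Write reads as FASTQ (Sanger Phred+33)
#' @param reads a read set.
#' @param path output file.
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality), con)
  invisible(path)
}

#' Write reads as FASTA
#' @param reads a read set.
#' @param path output file.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file (Sanger quality encoding).
#' @param emulsion_set label to attach to all reads.
#' @return a read set.
#' @export
read_reads_fastq <- function(path, emulsion_set = "set1") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(names(x), as.character(x),
           as.character(S4Vectors::mcols(x)$qualities),
           emulsion_set = emulsion_set)
}
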