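#' Remove reads with low mean quality
#'
#' Drops reads whose mean Phred quality is strictly below the threshold
#' (a read at exactly the threshold is retained). Input order is preserved.
#'
#' @param reads a read set.
#' @param threshold minimum mean Phred quality (default 20).
#' @return the retained read set.
#' @export
filter_mean_quality <- function(reads, threshold = 20) {
  stopifnot(threshold >= 0)
  if (!nrow(reads)) return(reads)
  reads[mean_quality(reads) >= threshold, , drop = FALSE]
}

# Representative of a cluster: longest member, ties broken by higher mean
# quality, then lexicographically smallest id.
pick_representative <- function(members) {
  o <- order(-nchar(members$sequence), -mean_quality(members), members$id)
  members$id[o[1]]
}

# Ends-free (overlap) alignment statistics for one read against a set of
# candidates: identity over aligned columns and coverage of the longer
# sequence.
overlap_stats <- function(candidates, read) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(candidates), Biostrings::DNAString(read),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1)
  nmat <- Biostrings::nmatch(aln)
  ni <- Biostrings::nindel(aln)
  cols <- nmat + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[, "WidthSum"] + Biostrings::deletion(ni)[, "WidthSum"]
  longer <- pmax(nchar(candidates), nchar(read))
  span_p <- Biostrings::width(Biostrings::pattern(aln))
  span_s <- Biostrings::width(Biostrings::subject(aln))
  span_longer <- ifelse(nchar(candidates) >= nchar(read), span_p, span_s)
  data.frame(identity = ifelse(cols > 0, nmat / cols, 0),
             coverage = span_longer / longer)
}

#' Cluster emulsion-PCR duplicate reads
#'
#' Two modes reproduce the two de-duplication strategies used for 454 bone
#' metagenomes:
#'
#' * `"linkage"` — pairwise global alignment distance (Levenshtein,
#'   normalized by the longer length) followed by single-linkage clustering
#'   at `cutoff`, run for each emulsion set separately (duplicates cannot
#'   arise across emulsions). Reads from different emulsion sets are never
#'   merged.
#' * `"greedy"` — cd-hit-style greedy clustering: reads are processed
#'   longest-first and each read joins the first existing representative it
#'   matches with identity >= `identity` over at least `coverage` of the
#'   longer sequence (ends-free alignment); otherwise it founds a new
#'   cluster.
#'
#' @param reads a read set.
#' @param mode `"linkage"` or `"greedy"`.
#' @param cutoff linkage mode: normalized edit-distance cutoff (default 0.03).
#' @param identity greedy mode: identity threshold in (0, 1] (default 0.97).
#' @param coverage greedy mode: alignment coverage of the longer sequence,
#'   in (0, 1] (default 0.8).
#' @return list of class `cluster_set`: `membership` (data frame read_id,
#'   cluster_id) and `representatives` (cluster_id, read_id). The clusters
#'   partition the input; each representative belongs to its cluster
#'   (longest member; ties by mean quality then id).
#' @export
cluster_duplicates <- function(reads, mode = c("linkage", "greedy"),
                               cutoff = 0.03, identity = 0.97, coverage = 0.8) {
  mode <- match.arg(mode)
  if (!nrow(reads)) stop("no reads to cluster")
  if (mode == "linkage") {
    if (cutoff < 0) stop("cutoff must be >= 0")
    memb <- data.frame(read_id = character(0), cluster_id = character(0))
    for (es in unique(reads$emulsion_set)) {
      sub <- reads[reads$emulsion_set == es, , drop = FALSE]
      if (nrow(sub) == 1) {
        cl <- 1L
      } else {
        d <- adist(sub$sequence)
        norm <- outer(nchar(sub$sequence), nchar(sub$sequence), pmax)
        nd <- d / norm
        hc <- stats::hclust(stats::as.dist(nd), method = "single")
        cl <- stats::cutree(hc, h = cutoff)
      }
      memb <- rbind(memb, data.frame(read_id = sub$id,
                                     cluster_id = paste0(es, ".", cl),
                                     stringsAsFactors = FALSE))
    }
  } else {
    if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
    if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
    o <- order(-nchar(reads$sequence), -mean_quality(reads), reads$id)
    sorted <- reads[o, , drop = FALSE]
    rep_seq <- character(0)
    rep_cl <- character(0)
    assign <- character(nrow(sorted))
    for (i in seq_len(nrow(sorted))) {
      s <- sorted$sequence[i]
      placed <- NA_character_
      if (length(rep_seq)) {
        st <- overlap_stats(rep_seq, s)
        ok <- which(st$identity >= identity & st$coverage >= coverage)
        if (length(ok)) placed <- rep_cl[ok[1]]
      }
      if (is.na(placed)) {
        placed <- paste0("C", length(rep_seq) + 1L)
        rep_seq <- c(rep_seq, s)
        rep_cl <- c(rep_cl, placed)
      }
      assign[i] <- placed
    }
    memb <- data.frame(read_id = sorted$id, cluster_id = assign,
                       stringsAsFactors = FALSE)
    memb <- memb[match(reads$id, memb$read_id), ]
  }
  rownames(memb) <- NULL
  reps <- do.call(rbind, lapply(split(memb$read_id, memb$cluster_id), function(ids) {
    data.frame(read_id = pick_representative(reads[match(ids, reads$id), ]),
               stringsAsFactors = FALSE)
  }))
  reps <- data.frame(cluster_id = rownames(reps), read_id = reps$read_id,
                     stringsAsFactors = FALSE)
  rownames(reps) <- NULL
  structure(list(membership = memb, representatives = reps),
            class = "cluster_set")
}

#' Keep one representative read per duplicate cluster
#' @param reads a read set.
#' @param clusters a `cluster_set` from [cluster_duplicates()].
#' @return the de-duplicated read set (input order preserved).
#' @export
deduplicate <- function(reads, clusters) {
  reads[reads$id %in% clusters$representatives$read_id, , drop = FALSE]
}

#' Write cluster membership as two-column tab-separated text
#' @param clusters a `cluster_set`.
#' @param path output file.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters$membership, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Longest suffix of `seq` matching a prefix of `adaptor` with at most
# max_mismatch_frac mismatches and length >= min_overlap; 0 when none.
suffix_prefix_overlap <- function(seq, adaptor, min_overlap, max_mismatch_frac) {
  L <- nchar(seq)
  A <- nchar(adaptor)
  if (min(L, A) < min_overlap) return(0L)
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adaptor, "")[[1]]
  for (ov in seq(min(L, A), min_overlap)) {
    mism <- sum(sc[(L - ov + 1):L] != ac[1:ov])
    if (mism / ov <= max_mismatch_frac) return(ov)
  }
  0L
}

#' Detect and trim the end adaptor from reads
#'
#' The 44-bp end adaptor appears completely, partially, or not at all at the
#' 3' end of raw 454 reads. For each read the longest suffix matching a
#' prefix of the adaptor (mismatch fraction <= `max_mismatch_frac`, length
#' >= `min_overlap`) is removed, quality trimmed in lockstep, and the
#' `adaptor_state` field set to `"full"` (the entire adaptor), `"partial"`
#' or `"none"`. Only the forward orientation is searched. Bases outside the
#' removed suffix are never altered.
#'
#' @param reads a read set.
#' @param adaptors an [adaptor_config()] (or a single adaptor string).
#' @param min_overlap minimum suffix length to call a partial adaptor.
#' @param max_mismatch_frac tolerated mismatch fraction in the overlap.
#' @return the trimmed read set.
#' @export
trim_end_adaptor <- function(reads, adaptors = adaptor_config(),
                             min_overlap = 6, max_mismatch_frac = 0.1) {
  stopifnot(min_overlap >= 1)
  adaptor <- if (inherits(adaptors, "adaptor_config")) adaptors$end_adaptor
             else as.character(adaptors)
  for (i in seq_len(nrow(reads))) {
    ov <- suffix_prefix_overlap(reads$sequence[i], adaptor,
                                min_overlap, max_mismatch_frac)
    if (ov > 0) {
      L <- nchar(reads$sequence[i])
      reads$sequence[i] <- substr(reads$sequence[i], 1, L - ov)
      reads$quality[i] <- substr(reads$quality[i], 1, L - ov)
      reads$adaptor_state[i] <- if (ov == nchar(adaptor)) "full" else "partial"
    } else {
      reads$adaptor_state[i] <- "none"
    }
  }
  reads
}

#' Trim the leading key adaptor from raw reads
#'
#' Raw 454 reads begin with a fixed 4-bp key; it is removed when present as
#' an exact prefix.
#'
#' @param reads a read set.
#' @param key the key adaptor sequence (default from [adaptor_config()]).
#' @return the trimmed read set.
#' @export
trim_key_adaptor <- function(reads, key = DEFAULT_KEY_ADAPTOR) {
  has <- startsWith(reads$sequence, key)
  k <- nchar(key)
  reads$sequence[has] <- substring(reads$sequence[has], k + 1L)
  reads$quality[has] <- substring(reads$quality[has], k + 1L)
  reads
}
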