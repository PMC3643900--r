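#' Select reads for a taxon/gene assembly bin
#'
#' Reads entering an assembly bin must be assigned to the requested taxon
#' (at the requested rank or any rank below it), have their hits to
#' references of the matching gene class (SSU and LSU are assembled
#' separately), and carry a best bit score strictly greater than
#' `score_min` among those hits.
#'
#' @param reads a read set.
#' @param assignments an `assignment_set` from [assign_taxonomy_mlca()].
#' @param hits hit records.
#' @param reference curated reference entries (maps accession to gene class).
#' @param taxon taxon label defining the bin.
#' @param gene `"SSU"` or `"LSU"`.
#' @param score_min minimum best bit score, exclusive (default 75).
#' @return the read subset for the bin (possibly empty, with a warning when
#'   the taxon label is unknown).
#' @export
bin_and_filter_reads <- function(reads, assignments, hits, reference,
                                 taxon, gene, score_min = 75) {
  stopifnot(score_min >= 0)
  a <- assignments[!is.na(assignments$taxonomy), , drop = FALSE]
  in_taxon <- vapply(split_path(a$taxonomy), function(p) taxon %in% p, logical(1))
  if (!any(vapply(split_path(reference[[grep("^taxonomy", names(reference))[1]]]),
                  function(p) taxon %in% p, logical(1))) && !any(in_taxon)) {
    warning("unknown taxon label: ", taxon)
    return(reads[0, , drop = FALSE])
  }
  ids <- a$read_id[in_taxon]
  genemap <- setNames(reference$gene, reference$accession)
  h <- hits[hits$qseqid %in% ids & genemap[hits$sseqid] == gene, , drop = FALSE]
  if (!nrow(h)) return(reads[0, , drop = FALSE])
  best <- tapply(h$bitscore, h$qseqid, max)
  keep <- names(best)[best > score_min]
  reads[reads$id %in% keep, , drop = FALSE]
}

#' Build a reference-guided consensus contig from binned reads
#'
#' Reads are locally aligned (both orientations; match +1, mismatch -2, gap
#' open 3, extend 1) to a layout sequence — `seed_reference` when given,
#' otherwise the longest read. The consensus base at each layout column is
#' the quality-weighted majority of the read bases covering it; the column
#' quality is the summed Phred of agreeing bases minus the summed Phred of
#' disagreeing bases, floored at 0. Coverage at a column is the number of
#' placed reads spanning it; columns never covered are dropped from the
#' consensus. Reads scoring below `min_score` are left unplaced and
#' reported. The seed only defines the coordinate system; it does not vote.
#'
#' @param reads a read set (>= 1 read).
#' @param seed_reference optional layout sequence.
#' @param min_score minimum local alignment score for placement.
#' @param id,taxon,gene contig annotations.
#' @return object of class `contig`: consensus sequence, per-column
#'   `coverage` and `quality`, per-read event calls (`calls`: read_id, ord
#'   in read orientation, op M/X/I/D, cons_base, read_base, column, qual,
#'   strand), placement table, unplaced read ids and summary statistics.
#' @export
build_consensus <- function(reads, seed_reference = NULL, min_score = 20,
                            id = "contig1", taxon = NA, gene = NA) {
  if (!nrow(reads)) stop("no reads to assemble")
  layout <- if (!is.null(seed_reference)) seed_reference
            else reads$sequence[order(-nchar(reads$sequence), reads$id)[1]]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  subj <- Biostrings::DNAString(layout)
  aln_fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads$sequence), subj, type = "local",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 1)
  aln_rev <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(revcomp(reads$sequence)), subj, type = "local",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 1)
  use_rev <- Biostrings::score(aln_rev) > Biostrings::score(aln_fwd)
  best_score <- pmax(Biostrings::score(aln_fwd), Biostrings::score(aln_rev))
  placed <- best_score >= min_score

  quals <- phred_decode(reads$quality)
  layout_chars <- strsplit(layout, "")[[1]]
  aseq_fwd <- reads$sequence
  aseq_rev <- revcomp(reads$sequence)

  # cheap vectorized accessors for both orientations
  side <- function(aln) {
    list(pstart = Biostrings::start(Biostrings::pattern(aln)),
         sstart = Biostrings::start(Biostrings::subject(aln)),
         nmat = Biostrings::nmatch(aln), nmis = Biostrings::nmismatch(aln),
         ins = Biostrings::insertion(aln), del = Biostrings::deletion(aln),
         mm = Biostrings::mismatchTable(aln))
  }
  fs <- side(aln_fwd)
  rs <- side(aln_rev)

  calls <- vector("list", nrow(reads))
  place_rows <- vector("list", nrow(reads))
  for (i in which(placed)) {
    s <- if (use_rev[i]) rs else fs
    aseq <- if (use_rev[i]) aseq_rev[i] else aseq_fwd[i]
    ins_r <- s$ins[[i]]
    del_r <- s$del[[i]]
    ncols <- s$nmat[i] + s$nmis[i] + sum(Biostrings::width(ins_r)) +
             sum(Biostrings::width(del_r))
    op <- rep("M", ncols)
    # indel ranges are in alignment-column coordinates
    if (length(ins_r))
      op[unlist(Map(seq.int, Biostrings::start(ins_r), Biostrings::end(ins_r)))] <- "I"
    if (length(del_r))
      op[unlist(Map(seq.int, Biostrings::start(del_r), Biostrings::end(del_r)))] <- "D"
    column <- s$sstart[i] - 1L + cumsum(op != "I")
    column[op == "I"] <- NA
    apos <- s$pstart[i] - 1L + cumsum(op != "D")  # position in aligned-orientation read
    apos[op == "D"] <- NA
    mm <- s$mm[s$mm$PatternId == i, , drop = FALSE]
    if (nrow(mm)) op[match(mm$SubjectStart, column)] <- "X"

    L <- nchar(reads$sequence[i])
    read_pos <- if (use_rev[i]) L - apos + 1L else apos
    achars <- strsplit(aseq, "")[[1]]
    df <- data.frame(read_id = reads$id[i], ord = NA_integer_, op = op,
                     cons_base = ifelse(is.na(column), NA, layout_chars[column]),
                     read_base = ifelse(is.na(apos), NA, achars[apos]),
                     column = column, read_pos = read_pos,
                     qual = ifelse(is.na(read_pos), NA, quals[[i]][read_pos]),
                     strand = ifelse(use_rev[i], "-", "+"),
                     stringsAsFactors = FALSE)
    if (use_rev[i]) df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$ord <- seq_len(nrow(df))
    calls[[i]] <- df
    place_rows[[i]] <- data.frame(read_id = reads$id[i],
                                  strand = ifelse(use_rev[i], "-", "+"),
                                  col_start = min(column, na.rm = TRUE),
                                  col_end = max(column, na.rm = TRUE),
                                  score = best_score[i], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  placements <- do.call(rbind, place_rows)
  if (is.null(calls) || !nrow(calls)) stop("no read could be placed on the layout")

  n_col <- nchar(layout)
  coverage <- integer(n_col)
  for (k in seq_len(nrow(placements)))
    coverage[placements$col_start[k]:placements$col_end[k]] <-
      coverage[placements$col_start[k]:placements$col_end[k]] + 1L

  # quality-weighted majority per column (gaps do not vote for a base)
  votes <- calls[!is.na(calls$column) & calls$op %in% c("M", "X"), , drop = FALSE]
  cons <- strsplit(layout, "")[[1]]
  colqual <- numeric(n_col)
  if (nrow(votes)) {
    agg <- aggregate(qual ~ column + read_base, data = votes, FUN = sum)
    for (colu in unique(agg$column)) {
      sub <- agg[agg$column == colu, ]
      w <- sub$qual
      best <- which.max(w)
      cons[colu] <- sub$read_base[best]
      colqual[colu] <- max(0, w[best] - sum(w[-best]))
    }
  }
  # re-label calls against the final consensus base
  calls$cons_base_final <- ifelse(is.na(calls$column), NA, cons[calls$column])
  upd <- !is.na(calls$column) & calls$op %in% c("M", "X")
  calls$op[upd] <- ifelse(calls$read_base[upd] == calls$cons_base_final[upd], "M", "X")
  calls$cons_base[upd] <- calls$cons_base_final[upd]
  calls$cons_base_final <- NULL

  covered <- coverage >= 1
  stats <- list(mean_coverage = mean(coverage[covered]),
                min_coverage = min(coverage[covered]),
                mean_quality = mean(colqual[covered]),
                min_quality = min(colqual[covered]),
                n_reads = sum(placed), n_unplaced = sum(!placed))
  structure(list(id = id, taxon = taxon, gene = gene,
                 consensus = paste(cons[covered], collapse = ""),
                 layout = layout, covered = which(covered),
                 coverage = coverage, quality = colqual,
                 calls = calls, placements = placements,
                 unplaced = reads$id[!placed], stats = stats),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("contig", x$id,
      sprintf("(%s/%s): %d bp consensus, %d reads placed, %d unplaced\n",
              x$taxon, x$gene, nchar(x$consensus), x$stats$n_reads,
              x$stats$n_unplaced))
  cat(sprintf("  coverage mean %.1f / min %d; column quality mean %.1f / min %d\n",
              x$stats$mean_coverage, x$stats$min_coverage,
              x$stats$mean_quality, as.integer(x$stats$min_quality)))
  invisible(x)
}

#' Export a contig as FASTA plus per-column statistics
#' @param contig a `contig`.
#' @param fasta,stats output paths (either may be NULL to skip).
#' @export
write_contig <- function(contig, fasta = NULL, stats = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(contig$consensus)
    names(x) <- contig$id
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(stats)) {
    df <- data.frame(column = contig$covered,
                     base = strsplit(contig$consensus, "")[[1]],
                     coverage = contig$coverage[contig$covered],
                     quality = contig$quality[contig$covered])
    write.table(df, stats, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(contig)
}
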