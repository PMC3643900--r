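#' Precision/recall evaluation of rRNA read detection
#'
#' Scores a set of reads flagged as rRNA by a similarity search against the
#' known positions of the reads on a reference with annotated rRNA genes:
#'
#' * **TP** — a flagged read whose mapped interval overlaps an rRNA gene by
#'   at least `min_overlap` bases.
#' * **FP** — a flagged read lying entirely outside every gene extended by
#'   `flank` on both sides.
#' * **ignored** — flagged reads overlapping a gene by less than
#'   `min_overlap` or falling inside the flank (gene borders and the
#'   neighbouring kilobase are ambiguous and excluded from the counts).
#' * **FN** — true rRNA reads (true interval overlapping a gene by at least
#'   `min_overlap`) that were not flagged.
#'
#' Precision = TP/(TP+FP); recall = TP/(TP+FN).
#'
#' @param read_intervals data frame `id`, `start`, `end`: the true mapped
#'   interval of every benchmark read (1-based, inclusive).
#' @param hit_ids ids of the reads the search flagged as rRNA.
#' @param genes data frame `start`, `end` (1-based, inclusive) of the rRNA
#'   genes, optionally with a `gene` class column.
#' @param min_overlap minimum overlap to count a gene hit (default 50).
#' @param flank ignore zone around genes, in bp (default 1000).
#' @return object of class `detection_metrics` with counts `tp`, `fp`,
#'   `fn`, `ignored` and `precision`, `recall` (NA when undefined).
#' @export
evaluate_detection <- function(read_intervals, hit_ids, genes,
                               min_overlap = 50, flank = 1000) {
  stopifnot(min_overlap >= 1, flank >= 0)
  if (any(read_intervals$end < read_intervals$start) ||
      any(genes$end < genes$start))
    stop("malformed intervals: end < start")

  ov <- function(s, e) {
    # max overlap of [s, e] with any gene
    if (!nrow(genes)) return(0L)
    max(pmax(0L, pmin(e, genes$end) - pmax(s, genes$start) + 1L))
  }
  in_flank <- function(s, e) {
    any(s <= genes$end + flank & e >= genes$start - flank)
  }

  overlap <- mapply(ov, read_intervals$start, read_intervals$end)
  is_true <- overlap >= min_overlap
  flagged <- read_intervals$id %in% hit_ids

  near <- mapply(in_flank, read_intervals$start, read_intervals$end)
  tp <- sum(flagged & is_true)
  fp <- sum(flagged & !near)
  ignored <- sum(flagged & near & !is_true)
  fn <- sum(!flagged & is_true)

  structure(list(tp = tp, fp = fp, fn = fn, ignored = ignored,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("detection: TP=%d FP=%d FN=%d ignored=%d | precision %.3f recall %.3f\n",
              x$tp, x$fp, x$fn, x$ignored, x$precision, x$recall))
  invisible(x)
}

#' Read BED-like gene annotations (0-based half-open) as 1-based intervals
#' @param path tab-separated file: chrom, start, end, and optionally a gene
#'   class column.
#' @return data frame `start`, `end`, `gene`.
#' @export
read_gene_bed <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(start = b[[2]] + 1L, end = b[[3]],
             gene = if (ncol(b) >= 4) b[[4]] else NA_character_,
             stringsAsFactors = FALSE)
}
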