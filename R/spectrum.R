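# The six complementary substitution classes, keyed by directed change.
SPECTRUM_CLASSES <- c("C>T/G>A", "T>C/A>G", "C>A/G>T", "A>C/T>G",
                      "C>G/G>C", "A>T/T>A")

directed_to_class <- function(from, to) {
  key <- paste0(from, ">", to)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  key2 <- paste0(comp[from], ">", comp[to])
  cls <- ifelse(paste0(key, "/", key2) %in% SPECTRUM_CLASSES,
                paste0(key, "/", key2), paste0(key2, "/", key))
  ifelse(cls %in% SPECTRUM_CLASSES, cls, NA_character_)
}

#' Read-versus-consensus substitution spectrum
#'
#' The statistic that separates cytosine-deamination damage from sequencing
#' error: each member read of a contig is compared to the consensus and the
#' ratio of changes to total bases is computed for the six pairs of
#' complementary changes (C>T/G>A, T>C/A>G, C>A/G>T, A>C/T>G, C>G/G>C,
#' A>T/T>A). Ancient, damaged DNA shows a strongly elevated C>T/G>A class;
#' undamaged DNA shows all classes near the instrument error floor.
#'
#' To avoid counting leftover partial adaptor sequence at read starts, each
#' read is scanned in its own orientation from its 5' end and only changes
#' *after the first `skip_run` contiguous consensus-matching bases* are
#' counted; changes at or before the end of that run are ignored. A read
#' with more than `max_changes` counted changes is discarded entirely
#' (neither numerator nor denominator), as is a read with no qualifying
#' match run. The denominator is the total number of read bases aligned to
#' consensus columns after the skip point, over retained reads; gap columns
#' (indels, the characteristic homopolymer error mode) are excluded from
#' both counts and reported separately.
#'
#' @param contig a `contig` from [build_consensus()].
#' @param skip_run length of the initial contiguous match run required
#'   before counting starts (default 5; 0 disables the rule).
#' @param max_changes discard reads with more counted changes than this
#'   (default 5; `Inf` disables).
#' @param error_floor per-site instrument error rate drawn as the reference
#'   line in plots (default 4e-4).
#' @return object of class `substitution_spectrum`: per-class `counts`,
#'   `bases` (denominator), `frequencies`, `n_used`, `n_discarded`,
#'   `n_indels`, `discard_reasons`, `error_floor`.
#' @export
substitution_spectrum <- function(contig, skip_run = 5, max_changes = 5,
                                  error_floor = 4e-4) {
  stopifnot(skip_run >= 0, max_changes >= 0)
  counts <- setNames(numeric(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  bases <- 0
  n_used <- 0L
  n_indels <- 0L
  reasons <- character(0)
  for (df in split(contig$calls, contig$calls$read_id)) {
    df <- df[order(df$ord), , drop = FALSE]
    scan <- scan_read_events(df$op, skip_run)
    if (is.null(scan)) { reasons <- c(reasons, "no_anchor"); next }
    after <- scan$after
    x_idx <- after[df$op[after] == "X"]
    if (length(x_idx) > max_changes) { reasons <- c(reasons, "too_many_changes"); next }
    n_used <- n_used + 1L
    bases <- bases + sum(df$op[after] %in% c("M", "X"))
    n_indels <- n_indels + sum(df$op[after] %in% c("I", "D"))
    if (length(x_idx)) {
      cls <- directed_to_class(df$cons_base[x_idx], df$read_base[x_idx])
      tab <- table(cls)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  structure(list(counts = counts, bases = bases,
                 frequencies = if (bases > 0) counts / bases else counts * NA,
                 n_used = n_used, n_discarded = length(reasons),
                 discard_reasons = table(reasons), n_indels = n_indels,
                 error_floor = error_floor),
            class = "substitution_spectrum")
}

# Indices of events after the skip point: the end of the first run of
# `skip_run` consecutive M events. NULL when no such run exists.
# skip_run = 0 counts everything.
scan_read_events <- function(op, skip_run) {
  n <- length(op)
  if (skip_run == 0) return(list(after = seq_len(n)))
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (op[i] == "M") run + 1L else 0L
    if (run == skip_run) {
      if (i == n) return(list(after = integer(0)))
      return(list(after = (i + 1L):n))
    }
  }
  NULL
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("substitution spectrum: %d reads used, %d discarded, %s bases\n",
              x$n_used, x$n_discarded, format(x$bases, big.mark = ",")))
  df <- data.frame(class = names(x$counts), count = as.integer(x$counts),
                   frequency = signif(x$frequencies, 3))
  print(df, row.names = FALSE)
  cat(sprintf("indel events (excluded): %d; error floor %.1e/site\n",
              x$n_indels, x$error_floor))
  invisible(x)
}

#' Export a spectrum as tab-separated text
#' @param spectrum a `substitution_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(class = names(spectrum$counts),
                   count = as.integer(spectrum$counts),
                   bases = spectrum$bases,
                   frequency = spectrum$frequencies)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bar plot of a substitution spectrum
#'
#' Per-class substitution frequencies with a horizontal line at the
#' estimated instrument error floor; damaged DNA stands out as a C>T/G>A
#' bar far above the line.
#'
#' @param spectrum a `substitution_spectrum` (or named list of them, drawn
#'   as facets).
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  if (inherits(spectrum, "substitution_spectrum"))
    spectrum <- list(spectrum = spectrum)
  df <- do.call(rbind, lapply(names(spectrum), function(nm) {
    s <- spectrum[[nm]]
    data.frame(panel = nm, class = factor(names(s$counts), SPECTRUM_CLASSES),
               frequency = as.numeric(s$frequencies),
               floor = s$error_floor)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$floor),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "changes per site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Positional mismatch-rate diagnostic
#'
#' Raw per-read-position rate of a substitution class over the member reads
#' of a contig (no smoothing or model fitting); useful to visualise the
#' terminal enhancement of deamination.
#'
#' @param contig a `contig`.
#' @param class one of the six class labels (default `"C>T/G>A"`).
#' @param max_pos last read position to report.
#' @return data frame `position`, `opportunities`, `changes`, `rate`.
#' @export
read_position_rates <- function(contig, class = "C>T/G>A", max_pos = 50) {
  calls <- contig$calls
  calls <- calls[!is.na(calls$read_pos) & calls$op %in% c("M", "X"), ]
  # read_pos is in original-read coordinates; convert to position along the
  # read's own 5'->3' scan order, which for both strands is the ord order.
  idx <- calls$op == "X"
  cls <- rep(NA_character_, nrow(calls))
  cls[idx] <- directed_to_class(calls$cons_base[idx], calls$read_base[idx])
  pos <- stats::ave(seq_along(calls$ord), calls$read_id, FUN = seq_along)
  keep <- pos <= max_pos
  opp <- tapply(rep(1, sum(keep)), pos[keep], sum)
  chg <- tapply(!is.na(cls[keep]) & cls[keep] == class, pos[keep], sum)
  data.frame(position = as.integer(names(opp)),
             opportunities = as.integer(opp), changes = as.integer(chg),
             rate = as.numeric(chg / opp))
}
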