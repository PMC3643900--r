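#' Majority-based lowest-common-ancestor taxonomic assignment
#'
#' Assigns each read with hits to the deepest taxonomic rank supported by an
#' abundance criterion over its tied best hits: among all hits sharing the
#' minimum e-value (ties detected after rounding e-values to 3 significant
#' figures, the precision of tabular hit files), the classifier descends
#' from domain towards genus and, at each rank, selects the child taxon
#' carried by at least `majority` of the tied hits (consistent with the
#' labels already chosen at higher ranks). Descent stops at the last rank
#' with a majority winner. This tolerates single misclassified reference
#' sequences that would drag a strict LCA towards the root.
#'
#' When `strict_phylum` is set (the default) a read whose tied best hits
#' span more than one phylum is classified only to the domain level,
#' regardless of any majority.
#'
#' Reads with no hits receive no assignment row (distinct from a
#' domain-level assignment).
#'
#' @param hits hit records (see [search_local()]); may cover many reads.
#' @param reference curated reference entries mapping `accession` to a
#'   taxonomy (the first `taxonomy_*` column is used).
#' @param majority required fraction of tied best hits, in `[0.5, 1]`;
#'   interpreted as ">= majority" (default 0.5). An exact 50/50 split has no
#'   unique winner and stops the descent.
#' @param strict_phylum truncate cross-phylum hit sets to domain (default TRUE).
#' @return data frame of class `assignment_set`: `read_id`, `taxonomy`
#'   (possibly truncated path), `rank` (deepest rank achieved, or NA when
#'   even the domain has no majority), `n_best` (number of tied best hits).
#' @export
assign_taxonomy_mlca <- function(hits, reference, majority = 0.5,
                                 strict_phylum = TRUE) {
  if (majority < 0.5 || majority > 1) stop("majority must be in [0.5, 1]")
  taxcol <- grep("^taxonomy", names(reference), value = TRUE)[1]
  if (is.na(taxcol)) stop("reference carries no taxonomy column")
  taxmap <- setNames(reference[[taxcol]], reference$accession)
  rows <- lapply(split(hits, hits$qseqid), function(h) {
    path <- mlca_one(h, taxmap, majority, strict_phylum)
    data.frame(read_id = h$qseqid[1],
               taxonomy = if (length(path$labels)) join_path(path$labels) else NA_character_,
               rank = if (length(path$labels)) TAX_RANKS[length(path$labels)] else NA_character_,
               n_best = path$n_best, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assignment_set", "data.frame")
  out
}

mlca_one <- function(h, taxmap, majority, strict_phylum) {
  ev <- signif(h$evalue, 3)
  tied <- h[ev == min(ev), , drop = FALSE]
  paths <- taxmap[tied$sseqid]
  if (anyNA(paths)) stop("hit to accession absent from the curated reference: ",
                         paste(unique(tied$sseqid[is.na(paths)]), collapse = ", "))
  split_paths <- split_path(unname(paths))
  n <- length(split_paths)

  max_depth <- length(TAX_RANKS)
  if (strict_phylum) {
    phyla <- unique(unlist(lapply(split_paths, function(p) if (length(p) >= 2) p[2])))
    if (length(phyla) > 1) max_depth <- 1L
  }

  chosen <- character(0)
  for (depth in seq_len(max_depth)) {
    # labels at this rank among hits consistent with the chosen prefix
    lab <- vapply(split_paths, function(p) {
      if (length(p) < depth) return(NA_character_)
      if (depth > 1 && !identical(p[seq_len(depth - 1)], chosen)) return(NA_character_)
      p[depth]
    }, character(1))
    tab <- table(lab[!is.na(lab)])
    if (!length(tab)) break
    winners <- names(tab)[tab >= majority * n]
    if (length(winners) != 1) break
    chosen <- c(chosen, winners)
  }
  list(labels = chosen, n_best = n)
}

#' Classical strict lowest common ancestor of a set of taxonomy paths
#'
#' The longest common prefix of the paths; used as the reference behaviour
#' that [assign_taxonomy_mlca()] reduces to at `majority = 1` with
#' `strict_phylum = FALSE`.
#'
#' @param paths character vector of semicolon-delimited paths.
#' @return the common-prefix path (possibly empty string).
#' @export
strict_lca <- function(paths) {
  sp <- split_path(paths)
  depth <- min(lengths(sp))
  out <- character(0)
  for (d in seq_len(depth)) {
    lab <- unique(vapply(sp, `[`, "", d))
    if (length(lab) != 1) break
    out <- c(out, lab)
  }
  join_path(out)
}

#' Taxonomic composition profile at a chosen rank
#'
#' Tabulates assignments at `level`. Reads assigned above the requested
#' level roll up into a bucket labelled with their deepest achieved taxon
#' (e.g. reads classified only to the domain appear under `"Bacteria"` in a
#' phylum-level profile). Counts partition the assigned reads; percents sum
#' to 100 up to rounding.
#'
#' @param assignments an `assignment_set`.
#' @param level one of domain/phylum/class/order/family/genus.
#' @return data frame `taxon`, `count`, `percent`, sorted by decreasing count.
#' @export
compose_profile <- function(assignments, level = "phylum") {
  level <- match.arg(level, TAX_RANKS)
  i <- match(level, TAX_RANKS)
  a <- assignments[!is.na(assignments$taxonomy), , drop = FALSE]
  lab <- vapply(split_path(a$taxonomy), function(p) {
    if (length(p) >= i) p[i] else p[length(p)]
  }, character(1))
  tab <- sort(table(lab), decreasing = TRUE)
  data.frame(taxon = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 2),
             stringsAsFactors = FALSE)
}
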