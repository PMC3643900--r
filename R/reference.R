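#' Curate a taxonomy-annotated rRNA reference table
#'
#' Applies the database curation rules used before rRNA similarity
#' searching: entries are removed when poorly aligned (`align_quality` < 75),
#' potentially chimeric (`pintail` < 100), annotated with *different domains*
#' by the available taxonomy sources (SILVA/EMBL/Greengenes/RDP columns —
#' mostly mitochondrial/chloroplast conflicts in real databases),
#' taxonomically uninformative (e.g. unannotated metagenome reads), listed
#' on the tRNA-contaminated accession blacklist, or missing curation
#' metadata. Curation is idempotent.
#'
#' @param entries data frame with columns `accession`, `gene` (SSU/LSU),
#'   `align_quality` (0--100), `pintail` (0--100), one or more
#'   `taxonomy_*` columns (semicolon-delimited paths; NA allowed),
#'   `informative` (logical) and `sequence`.
#' @param trna_blacklist accessions to exclude.
#' @return the retained entries, with a `rejections` attribute
#'   (data frame accession/reason) describing what was removed and why.
#' @export
curate_reference_db <- function(entries, trna_blacklist = character(0)) {
  taxcols <- grep("^taxonomy", names(entries), value = TRUE)
  if (!length(taxcols)) stop("entries carry no taxonomy_* columns")
  reasons <- character(nrow(entries))

  meta_missing <- is.na(entries$align_quality) | is.na(entries$pintail)
  reasons[meta_missing] <- "missing curation metadata"

  low_aq <- !meta_missing & entries$align_quality < 75
  reasons[low_aq & reasons == ""] <- "align_quality < 75"
  chim <- !meta_missing & entries$pintail < 100
  reasons[chim & reasons == ""] <- "pintail < 100"

  domains <- apply(as.matrix(entries[taxcols]), 1, function(p) {
    d <- vapply(p[!is.na(p) & p != ""], function(x) split_path(x)[[1]][1], "")
    unique(d)
  })
  dom_conflict <- vapply(domains, function(d) length(d) > 1, logical(1))
  reasons[dom_conflict & reasons == ""] <- "domain disagreement between taxonomies"

  uninform <- !is.na(entries$informative) & !entries$informative
  reasons[uninform & reasons == ""] <- "taxonomically uninformative"

  blk <- entries$accession %in% trna_blacklist
  reasons[blk & reasons == ""] <- "tRNA-contaminated accession"

  keep <- reasons == ""
  rejections <- data.frame(accession = entries$accession[!keep],
                           reason = reasons[!keep], stringsAsFactors = FALSE)
  if (nrow(rejections))
    message(nrow(rejections), " reference entries removed during curation")
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Derive a reference table from a simulated community
#'
#' Wraps a [simulate_community()] result in the tabular reference format
#' consumed by [curate_reference_db()] and [assign_taxonomy_mlca()], with
#' clean curation metadata.
#'
#' @param community a `reference_community`.
#' @return a reference entry data frame.
#' @export
community_as_reference <- function(community) {
  data.frame(accession = community$accession, gene = community$gene,
             align_quality = 100L, pintail = 100L,
             taxonomy_silva = community$taxonomy,
             taxonomy_embl = community$taxonomy,
             taxonomy_greengenes = community$taxonomy,
             taxonomy_rdp = community$taxonomy,
             informative = TRUE, sequence = community$sequence,
             stringsAsFactors = FALSE)
}

#' Read / write the tab-separated reference table
#' @param path file path.
#' @return `read_reference_table`: the entries data frame.
#' @export
read_reference_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' @rdname read_reference_table
#' @param entries reference entries.
#' @export
write_reference_table <- function(entries, path) {
  write.table(entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
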