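# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately re-derive results
# from first principles (all-pairs graphs, literal rule walks) rather than
# sharing code with the package.

# All-pairs single-linkage components at a normalized edit-distance cutoff,
# restricted to within emulsion sets: union-find over edges with d <= cutoff.
oracle_single_linkage <- function(seqs, sets, cutoff) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sets[i] != sets[j]) next
      d <- adist(seqs[i], seqs[j])[1, 1] / max(nchar(seqs[i]), nchar(seqs[j]))
      if (d <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical form of a partition: sorted list of sorted member vectors.
partition_canonical <- function(ids, labels) {
  unname(lapply(sort(vapply(split(ids, labels), function(m)
    paste(sort(m), collapse = ","), "")), identity))
}

same_partition <- function(ids1, labels1, ids2, labels2) {
  identical(partition_canonical(ids1, labels1), partition_canonical(ids2, labels2))
}

# Classical strict LCA: elementwise longest common prefix via pairwise
# reduction.
oracle_classical_lca <- function(paths) {
  sp <- strsplit(paths, ";", fixed = TRUE)
  pre <- Reduce(function(a, b) {
    k <- 0
    while (k < min(length(a), length(b)) && a[k + 1] == b[k + 1]) k <- k + 1
    if (k == 0) character(0) else a[seq_len(k)]
  }, sp)
  paste(pre, collapse = ";")
}

# Literal majority-descent over the taxonomy tree: at each depth enumerate
# every observed prefix extending the current one and keep descending while
# exactly one extension reaches the majority count over all paths.
oracle_mlca <- function(paths, majority = 0.5, strict_phylum = TRUE) {
  sp <- strsplit(paths, ";", fixed = TRUE)
  n <- length(sp)
  max_depth <- 6L
  if (strict_phylum) {
    ph <- unique(unlist(lapply(sp, function(p) if (length(p) >= 2) p[2])))
    if (length(ph) > 1) max_depth <- 1L
  }
  current <- character(0)
  repeat {
    d <- length(current) + 1L
    if (d > max_depth) break
    exts <- unlist(lapply(sp, function(p) {
      if (length(p) < d) return(NULL)
      if (d > 1 && !identical(p[seq_len(d - 1)], current)) return(NULL)
      p[d]
    }))
    if (is.null(exts)) break
    counts <- table(exts)
    qual <- names(counts)[counts >= majority * n]
    if (length(qual) != 1) break
    current <- c(current, qual)
  }
  paste(current, collapse = ";")
}

# Random ranked taxonomy paths over a small label tree, for property tests.
random_paths <- function(n, n_phyla = 3, branch = 2) {
  vapply(seq_len(n), function(i) {
    ph <- sample(paste0("P", seq_len(n_phyla)), 1)
    cl <- paste0(ph, "c", sample(branch, 1))
    or <- paste0(cl, "o", sample(branch, 1))
    fa <- paste0(or, "f", sample(branch, 1))
    ge <- paste0(fa, "g", sample(branch, 1))
    depth <- sample(2:6, 1)
    paste(c("Bacteria", ph, cl, or, fa, ge)[seq_len(depth)], collapse = ";")
  }, "")
}

# Build a contig object directly from gapped alignment strings, walking the
# characters literally; independent of build_consensus' range arithmetic.
# Each placement: list(read_aln, cons_aln, start_col, strand, qual) where the
# two gapped strings have equal length, in layout orientation, and start_col
# is the layout column of the first consensus (non-gap) character.
make_contig <- function(consensus, placements, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(placements))
  calls <- list()
  for (k in seq_along(placements)) {
    p <- placements[[k]]
    rc <- strsplit(p$read_aln, "")[[1]]
    cc <- strsplit(p$cons_aln, "")[[1]]
    stopifnot(length(rc) == length(cc))
    op <- ifelse(rc == "-", "D", ifelse(cc == "-", "I",
          ifelse(rc == cc, "M", "X")))
    column <- cumsum(cc != "-") + p$start_col - 1L
    column[cc == "-"] <- NA
    rpos_layout <- cumsum(rc != "-")
    rpos_layout[rc == "-"] <- NA
    n_read <- sum(rc != "-")
    strand <- if (is.null(p$strand)) "+" else p$strand
    read_pos <- if (strand == "-") n_read - rpos_layout + 1L else rpos_layout
    qual <- if (is.null(p$qual)) 30L else p$qual
    df <- data.frame(read_id = ids[k], ord = NA_integer_, op = op,
                     cons_base = ifelse(cc == "-", NA, cc),
                     read_base = ifelse(rc == "-", NA, rc),
                     column = column, read_pos = read_pos,
                     qual = ifelse(is.na(read_pos), NA, qual),
                     strand = strand, stringsAsFactors = FALSE)
    if (strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$ord <- seq_len(nrow(df))
    calls[[k]] <- df
  }
  structure(list(id = "test", taxon = NA, gene = NA, consensus = consensus,
                 layout = consensus, covered = seq_len(nchar(consensus)),
                 coverage = rep(1L, nchar(consensus)),
                 quality = rep(30, nchar(consensus)),
                 calls = do.call(rbind, calls),
                 placements = NULL, unplaced = character(0),
                 stats = list()), class = "contig")
}

# Plain mismatch counting over a contig built by make_contig: walk the
# gapped strings and tally mismatch classes and non-gap aligned bases.
oracle_plain_counts <- function(placements) {
  classes <- c("C>T/G>A", "T>C/A>G", "C>A/G>T", "A>C/T>G", "C>G/G>C", "A>T/T>A")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- setNames(numeric(6), classes)
  bases <- 0
  for (p in placements) {
    rc <- strsplit(p$read_aln, "")[[1]]
    cc <- strsplit(p$cons_aln, "")[[1]]
    both <- rc != "-" & cc != "-"
    bases <- bases + sum(both)
    mm <- which(both & rc != cc)
    for (i in mm) {
      k1 <- paste0(cc[i], ">", rc[i], "/", comp[cc[i]], ">", comp[rc[i]])
      k2 <- paste0(comp[cc[i]], ">", comp[rc[i]], "/", cc[i], ">", rc[i])
      key <- if (k1 %in% classes) k1 else k2
      counts[key] <- counts[key] + 1
    }
  }
  list(counts = counts, bases = bases)
}

# Literal skip-rule spectrum on make_contig placements: find the first
# skip_run consecutive agreeing bases scanning the gapped strings in read
# orientation, ignore everything up to the end of that run, count class
# changes after it, discard reads with > max_changes changes.
oracle_skip_spectrum <- function(placements, skip_run = 5, max_changes = 5) {
  classes <- c("C>T/G>A", "T>C/A>G", "C>A/G>T", "A>C/T>G", "C>G/G>C", "A>T/T>A")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- setNames(numeric(6), classes)
  bases <- 0
  n_used <- 0L
  n_disc <- 0L
  for (p in placements) {
    rc <- strsplit(p$read_aln, "")[[1]]
    cc <- strsplit(p$cons_aln, "")[[1]]
    strand <- if (is.null(p$strand)) "+" else p$strand
    if (strand == "-") { rc <- rev(rc); cc <- rev(cc) }
    n <- length(rc)
    # locate end of first run of skip_run consecutive matches
    run <- 0L
    endrun <- NA_integer_
    for (i in seq_len(n)) {
      m <- rc[i] != "-" && cc[i] != "-" && rc[i] == cc[i]
      run <- if (m) run + 1L else 0L
      if (run == skip_run) { endrun <- i; break }
    }
    if (skip_run == 0) endrun <- 0L
    if (is.na(endrun)) { n_disc <- n_disc + 1L; next }
    idx <- if (endrun >= n) integer(0) else (endrun + 1L):n
    both <- idx[rc[idx] != "-" & cc[idx] != "-"]
    mm <- both[rc[both] != cc[both]]
    if (length(mm) > max_changes) { n_disc <- n_disc + 1L; next }
    n_used <- n_used + 1L
    bases <- bases + length(both)
    for (i in mm) {
      k1 <- paste0(cc[i], ">", rc[i], "/", comp[cc[i]], ">", comp[rc[i]])
      k2 <- paste0(comp[cc[i]], ">", comp[rc[i]], "/", cc[i], ">", rc[i])
      key <- if (k1 %in% classes) k1 else k2
      counts[key] <- counts[key] + 1
    }
  }
  list(counts = counts, bases = bases, n_used = n_used, n_discarded = n_disc)
}
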