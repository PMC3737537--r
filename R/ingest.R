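# Aligned reads are held in a plain data.frame with columns
#   chrom, start, end (0-based half-open), strand (+/-), seq (or NA),
#   mult (collapsed-read multiplicity, >= 1)
# All downstream counts are multiplicity-weighted.

smrna_reads <- function(chrom, start, end, strand, seq = NA_character_,
                        mult = 1L) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   seq = rep_len(as.character(seq), n),
                   mult = rep_len(as.integer(mult), n),
                   stringsAsFactors = FALSE)
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad))
    stop_("invalid read coordinates (need 0 <= start < end) at record ", bad[1])
  if (any(!df$strand %in% c("+", "-")))
    stop_("read strand must be '+' or '-'")
  if (any(df$mult < 1L)) stop_("read multiplicity must be >= 1")
  has_seq <- !is.na(df$seq)
  if (any(nchar(df$seq[has_seq]) != (df$end - df$start)[has_seq]))
    stop_("read sequence length must equal end - start")
  class(df) <- c("smrna_reads", "data.frame")
  df
}

# multiplicity encoded in read names by collapsing tools, e.g. "r12_x37"
name_multiplicity <- function(name) {
  m <- regmatches(name, regexec("_x(\\d+)$", name))
  vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else 1L, integer(1))
}

cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    if (!length(ops)) return(0L)
    n <- as.integer(sub(".$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Read aligned small-RNA reads from BAM/SAM or BED6
#'
#' Coordinates are normalised to the 0-based half-open convention. BED reads
#' are hydrated with their sequence when a genome is supplied (reverse
#' complemented for minus-strand reads). Collapsed-read multiplicity is
#' parsed from read names of the form `name_xN`.
#'
#' @param path Alignment file (`.bam`, `.sam`, or `.bed`).
#' @param genome Optional [Biostrings::DNAStringSet]; required later if
#'   nucleotide features are requested for BED input.
#' @param unique_only Drop multi-mapping reads. For BAM this uses the `NH`
#'   tag; BED carries no hit count, so all reads are kept with a warning.
#' @param format Override the file-extension based format detection
#'   (`"bam"`, `"sam"` or `"bed"`).
#' @return A read table (`smrna_reads` data.frame) with columns
#'   `chrom, start, end, strand, seq, mult`.
#' @export
read_alignments <- function(path, genome = NULL, unique_only = FALSE,
                            format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("bam", "sam", "bed"))
    stop_("unsupported alignment format '", format, "' (need bam, sam or bed)")
  if (format == "bed") {
    reads <- parse_bed_reads(path)
    if (unique_only)
      warning("BED input carries no multi-mapping information; ",
              "treating all reads as uniquely mapped", call. = FALSE)
    if (!is.null(genome) && nrow(reads)) reads <- hydrate_reads(reads, genome)
  } else {
    reads <- parse_bam_reads(path, format, unique_only)
  }
  if (!is.null(genome) && nrow(reads)) {
    bad <- !reads$chrom %in% names(genome)
    if (any(bad))
      stop_("unknown chromosome '", reads$chrom[which(bad)[1]],
            "' (not present in the genome)")
  }
  reads
}

parse_bed_reads <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(smrna_reads(character(), integer(), integer(), character()))
  fl <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fl)
  if (any(nf < 6L))
    stop_("malformed BED record (fewer than 6 fields) at line ", idx[which(nf < 6L)[1]])
  m <- do.call(rbind, lapply(fl, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(start) | is.na(end) | !m[, 6] %in% c("+", "-")
  if (any(bad)) stop_("malformed BED record at line ", idx[which(bad)[1]])
  smrna_reads(m[, 1], start, end, m[, 6], mult = name_multiplicity(m[, 4]))
}

parse_bam_reads <- function(path, format, unique_only) {
  if (format == "sam") path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  if (!length(b$pos))
    return(smrna_reads(character(), integer(), integer(), character()))
  start <- b$pos - 1L
  end <- start + cigar_ref_width(b$cigar)
  seq <- as.character(b$seq)
  strand <- as.character(b$strand)
  minus <- strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])  # back to as-sequenced
  nh <- b$tag$NH
  mult <- name_multiplicity(b$qname)
  reads <- smrna_reads(as.character(b$rname), start, end, strand, seq, mult)
  if (unique_only) {
    if (is.null(nh)) {
      warning("no NH tag in BAM; treating all reads as uniquely mapped",
              call. = FALSE)
    } else {
      reads <- reads[is.na(nh) | nh == 1L, , drop = FALSE]
      class(reads) <- c("smrna_reads", "data.frame")
    }
  }
  reads
}

# ---------------------------------------------------------------------------
# Locus container: a summary data.frame plus the per-locus read tables.

new_locus_set <- function(summary, reads) {
  rownames(summary) <- NULL
  structure(list(summary = summary, reads = reads), class = "smrna_loci")
}

#' @export
length.smrna_loci <- function(x) nrow(x$summary)

#' @export
`[.smrna_loci` <- function(x, i) {
  new_locus_set(x$summary[i, , drop = FALSE], x$reads[i])
}

#' @export
print.smrna_loci <- function(x, ...) {
  cat("Small RNA locus set:", length(x), "loci,",
      sum(x$summary$n_reads), "assigned reads (multiplicity-weighted)\n")
  if ("label" %in% names(x$summary)) {
    tab <- table(x$summary$label)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  print(head(x$summary, 6))
  if (length(x) > 6) cat("...", length(x) - 6, "more\n")
  invisible(x)
}

#' Extract one locus with its assigned reads
#'
#' @param x A locus set from [segment_loci()].
#' @param i Locus index.
#' @return A `smrna_locus` list with fields `id, chrom, start, end, strand,
#'   n_sense, n_antisense, n_reads` and a `reads` data.frame.
#' @export
get_locus <- function(x, i) {
  stopifnot(inherits(x, "smrna_loci"), is_count(i), i <= length(x))
  loc <- as.list(x$summary[i, , drop = FALSE])
  loc$reads <- x$reads[[i]]
  structure(loc, class = "smrna_locus")
}

#' Merge aligned reads into transcribed loci
#'
#' Pools both strands into one multiplicity-weighted coverage profile per
#' chromosome, keeps maximal intervals with coverage at or above
#' `min_coverage`, and merges intervals separated by at most `max_gap`
#' uncovered bases. Every read overlapping a locus is assigned to it; the
#' locus strand is the strand carrying the majority of assigned read
#' multiplicity (ties go to `+`). Locus ids are `chrom:start-end` in 0-based
#' half-open coordinates.
#'
#' @param reads Read table from [read_alignments()].
#' @param min_coverage Minimum read depth for a base to seed a locus
#'   (default 1).
#' @param max_gap Maximum uncovered gap (bases) bridged when merging
#'   adjacent covered intervals (default 0).
#' @return A `smrna_loci` locus set, sorted by (chrom, start), with pairwise
#'   disjoint loci.
#' @export
segment_loci <- function(reads, min_coverage = 1L, max_gap = 0L) {
  stopifnot(is_count(min_coverage, 1L), is_count(max_gap, 0L))
  empty <- new_locus_set(
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), n_sense = integer(),
               n_antisense = integer(), n_reads = integer(),
               stringsAsFactors = FALSE), list())
  if (nrow(reads) == 0L) return(empty)
  out_sum <- list(); out_reads <- list()
  for (chrom in sort(unique(reads$chrom))) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    cov <- IRanges::coverage(ir, weight = as.numeric(r$mult))
    hit <- IRanges::slice(cov, lower = min_coverage, rangesOnly = TRUE)
    if (!length(hit)) next
    merged <- IRanges::reduce(hit, min.gapwidth = max_gap + 1L)
    ov <- IRanges::findOverlaps(ir, merged)
    for (j in seq_along(merged)) {
      ri <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      lr <- r[ri, , drop = FALSE]
      s0 <- IRanges::start(merged)[j] - 1L
      e0 <- IRanges::end(merged)[j]
      mult_by_strand <- c(`+` = sum(lr$mult[lr$strand == "+"]),
                          `-` = sum(lr$mult[lr$strand == "-"]))
      strand <- if (mult_by_strand["-"] > mult_by_strand["+"]) "-" else "+"
      out_sum[[length(out_sum) + 1L]] <- data.frame(
        id = sprintf("%s:%d-%d", chrom, s0, e0), chrom = chrom,
        start = s0, end = e0, strand = strand,
        n_sense = unname(mult_by_strand[strand]),
        n_antisense = unname(sum(mult_by_strand) - mult_by_strand[strand]),
        n_reads = unname(sum(mult_by_strand)), stringsAsFactors = FALSE)
      rownames(lr) <- NULL
      out_reads[[length(out_reads) + 1L]] <- lr
    }
  }
  if (!length(out_sum)) return(empty)
  new_locus_set(do.call(rbind, out_sum), out_reads)
}

#' Discard weakly covered loci
#'
#' Retains loci whose total assigned read multiplicity is at least
#' `min_reads`; order is preserved. The default of 15 reads is the usual
#' quality-control cutoff for calling a locus sufficiently transcribed.
#'
#' @param loci Locus set from [segment_loci()].
#' @param min_reads Minimum multiplicity-weighted read count (default 15).
#' @return The filtered locus set.
#' @export
filter_loci <- function(loci, min_reads = 15L) {
  stopifnot(inherits(loci, "smrna_loci"), is_count(min_reads, 1L))
  loci[loci$summary$n_reads >= min_reads]
}

#' Write loci as BED6
#'
#' The score column carries the multiplicity-weighted read count.
#'
#' @param loci Locus set.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  s <- loci$summary
  df <- data.frame(s$chrom, s$start, s$end, s$id, s$n_reads, s$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
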