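#' Read ncRNA annotations from BED or GTF
#'
#' BED input resolves the RNA class from the name column: the name is split
#' on `name_sep` and the last field is taken as the raw class. GTF input
#' takes the raw class from the attribute named by `class_field`. Raw
#' classes are then passed through `class_map` (a named character vector,
#' `raw -> class`); raw values already in the class vocabulary pass through
#' unchanged. Records resolving to no known class are dropped with a message.
#'
#' @param path Annotation file (`.bed`, `.gtf`/`.gff`).
#' @param class_map Optional named character vector mapping raw annotation
#'   types to the class vocabulary.
#' @param format Override extension-based format detection.
#' @param name_sep Separator inside BED names (default `"|"`).
#' @param class_field GTF attribute holding the raw class (default
#'   `"gene_type"`).
#' @param classes Closed class vocabulary (default [rna_classes]`(core = FALSE)`).
#' @return A data.frame with columns `chrom, start, end, strand, rna_class,
#'   name` (0-based half-open coordinates).
#' @export
read_annotations <- function(path, class_map = NULL, format = NULL,
                             name_sep = "|", class_field = "gene_type",
                             classes = rna_classes(core = FALSE)) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "bed") {
    ann <- parse_bed_annotations(path, name_sep)
  } else if (format %in% c("gtf", "gff", "gff3")) {
    g <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(g)
    if (!class_field %in% names(mc))
      stop_("GTF/GFF attribute '", class_field, "' not found")
    nm <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
          else paste0("ann", seq_along(g))
    ann <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g) - 1L,
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      raw = as.character(mc[[class_field]]),
                      name = nm, stringsAsFactors = FALSE)
    ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  } else {
    stop_("unsupported annotation format '", format, "'")
  }
  raw <- ann$raw
  cls <- ifelse(!is.null(class_map) & raw %in% names(class_map),
                unname(class_map[raw]), raw)
  known <- cls %in% classes
  if (any(!known))
    message(sum(!known), " annotation record(s) with unmapped class dropped")
  ann <- ann[known, , drop = FALSE]
  out <- data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                    strand = ann$strand, rna_class = cls[known],
                    name = ann$name, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop_("annotation with start >= end")
  rownames(out) <- NULL
  class(out) <- c("smrna_annotations", "data.frame")
  out
}

#' Read a class map from a plain-text key-value file
#'
#' Each non-comment line holds `raw_type<TAB or spaces>class`, mapping an
#' annotation source's type names onto the class vocabulary.
#'
#' @param path File path.
#' @return Named character vector suitable for [read_annotations()]'s
#'   `class_map`.
#' @export
read_class_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop_("malformed class-map line: ", lines[which(bad)[1]])
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

parse_bed_annotations <- function(path, name_sep) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), raw = character(),
                      name = character(), stringsAsFactors = FALSE))
  fl <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fl)
  if (any(nf < 4L))
    stop_("malformed annotation BED record at line ", idx[which(nf < 4L)[1]])
  chrom <- vapply(fl, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fl, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fl, `[`, "", 3L)))
  name <- vapply(fl, `[`, "", 4L)
  strand <- ifelse(nf >= 6L, vapply(fl, function(f) f[min(6L, length(f))], ""), "+")
  strand[!strand %in% c("+", "-")] <- "+"
  if (anyNA(start) || anyNA(end))
    stop_("malformed annotation BED record at line ",
          idx[which(is.na(start) | is.na(end))[1]])
  parts <- strsplit(name, name_sep, fixed = TRUE)
  raw <- vapply(parts, function(p) p[length(p)], "")
  # the class suffix is annotation metadata, not part of the record name
  base <- vapply(parts, function(p)
    if (length(p) > 1L) paste(p[-length(p)], collapse = name_sep) else p, "")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             raw = raw, name = base, stringsAsFactors = FALSE)
}

#' Label loci by annotation overlap
#'
#' Each locus receives the class of the overlapping annotation with the
#' largest base-pair overlap. Ties are broken by a fixed class priority
#' (miRNA > C/D box snoRNA > snRNA > scRNA > transposon > lincRNA > tRNA >
#' rRNA > other), then by annotation name, so labelling is deterministic for
#' any input order. Loci overlapping nothing are labelled `"unknown"`; loci
#' whose best annotation class is outside `classes` are also set to
#' `"unknown"` (they form the prediction-only pool).
#'
#' @param loci Locus set from [segment_loci()]/[filter_loci()].
#' @param annotations Annotation table from [read_annotations()].
#' @param strand_aware Only consider annotations on the locus strand
#'   (default `TRUE`).
#' @param classes Classes retained as labels (default the six core classes).
#' @return The locus set with `label`, `overlap_bp` and `ann_name` columns
#'   added to its summary.
#' @export
label_loci <- function(loci, annotations, strand_aware = TRUE,
                       classes = rna_classes()) {
  stopifnot(inherits(loci, "smrna_loci"))
  s <- loci$summary
  s$label <- "unknown"
  s$overlap_bp <- 0L
  s$ann_name <- NA_character_
  if (nrow(s) && nrow(annotations)) {
    gl <- GenomicRanges::GRanges(s$chrom,
                                 IRanges::IRanges(s$start + 1L, s$end),
                                 strand = s$strand)
    ga <- GenomicRanges::GRanges(annotations$chrom,
                                 IRanges::IRanges(annotations$start + 1L,
                                                  annotations$end),
                                 strand = annotations$strand)
    ov <- GenomicRanges::findOverlaps(gl, ga, ignore.strand = !strand_aware)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); a <- S4Vectors::subjectHits(ov)
      obp <- pmin(s$end[q], annotations$end[a]) -
             pmax(s$start[q], annotations$start[a])
      prio <- match(annotations$rna_class[a], CLASS_PRIORITY)
      ord <- order(q, -obp, prio, annotations$name[a], method = "radix")
      best <- ord[!duplicated(q[ord])]
      qi <- q[best]; ai <- a[best]
      cls <- annotations$rna_class[ai]
      s$label[qi] <- ifelse(cls %in% classes, cls, "unknown")
      s$overlap_bp[qi] <- obp[best]
      s$ann_name[qi] <- annotations$name[ai]
    }
  }
  new_locus_set(s, loci$reads)
}

#' Write labelled loci as TSV
#'
#' @param loci Labelled locus set from [label_loci()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_labeled_loci <- function(loci, path) {
  s <- loci$summary
  cols <- intersect(c("id", "chrom", "start", "end", "strand", "label",
                      "overlap_bp", "n_reads"), names(s))
  write_tsv(s[cols], path)
}
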