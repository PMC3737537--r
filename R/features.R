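# The 25-feature pileup representation of a locus.
#
# For a locus i spanning [a, b) the raw length feature for span L is
#   f_L = sum_k N_{L,k} / Length(i),  L = 14..30,
# where N_{L,k} is the multiplicity-weighted number of sense reads of
# reference span L covering base k, with k restricted to [a, b). Raw
# features are turned into proportions with a pseudocount scaled to the
# feature units (c = 1/Length(i)):
#   p_L = (f_L + alpha * c) / (sum_L' f_L' + 17 * alpha * c)
# and reported as log-odds log2(p_L / (1 - p_L)).

sense_reads <- function(locus) {
  locus$reads[locus$reads$strand == locus$strand, , drop = FALSE]
}

#' Read-length spectrum features of a locus
#'
#' @param locus A locus from [get_locus()].
#' @param alpha Pseudocount (default 0.5, Jeffreys-style).
#' @return Named numeric vector `L14`..`L30` of log-odds values.
#' @export
length_features <- function(locus, alpha = 0.5) {
  stopifnot(alpha > 0)
  len <- locus$end - locus$start
  r <- sense_reads(locus)
  f <- numeric(17)
  names(f) <- LENGTH_FEATURES
  if (nrow(r) == 0L) {
    message("locus ", locus$id, ": no sense-strand reads; ",
            "length features fall back to the uniform pseudocount")
  } else {
    span <- r$end - r$start
    ovl <- pmin(r$end, locus$end) - pmax(r$start, locus$start)
    keep <- span >= 14L & span <= 30L & ovl > 0L
    if (any(keep)) {
      per_span <- tapply(r$mult[keep] * ovl[keep], factor(span[keep], levels = 14:30), sum)
      per_span[is.na(per_span)] <- 0
      f <- as.numeric(per_span) / len
      names(f) <- LENGTH_FEATURES
    }
  }
  cc <- 1 / len
  p <- (f + alpha * cc) / (sum(f) + 17 * alpha * cc)
  log2(p / (1 - p))
}

#' Positional entropy of read 5' or 3' ends
#'
#' Shannon entropy (bits) of the multiplicity-weighted distribution of
#' sense-read end positions. For a minus-strand locus the 5' end of a read
#' is its maximum genomic coordinate. End positions outside the locus
#' bounds still count: they are real cleavage sites.
#'
#' @param locus A locus from [get_locus()].
#' @param which_end `"5p"` or `"3p"`.
#' @return Entropy in bits (0 for a single cleavage site or no sense reads).
#' @export
positional_entropy <- function(locus, which_end = c("5p", "3p")) {
  which_end <- match.arg(which_end)
  r <- sense_reads(locus)
  if (nrow(r) == 0L) {
    message("locus ", locus$id, ": no sense-strand reads; entropy set to 0")
    return(0)
  }
  plus <- locus$strand == "+"
  pos <- if ((which_end == "5p") == plus) r$start else r$end - 1L
  cnt <- tapply(r$mult, pos, sum)
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' Antisense expression feature
#'
#' Log-odds of the multiplicity-weighted fraction of reads mapping antisense
#' to the locus: `q = (n_antisense + alpha) / (n_total + 2 * alpha)`,
#' reported as `log2(q / (1 - q))`.
#'
#' @param locus A locus from [get_locus()].
#' @param alpha Pseudocount (default 0.5).
#' @return A single log-odds value.
#' @export
antisense_feature <- function(locus, alpha = 0.5) {
  stopifnot(alpha > 0)
  ns <- locus$n_sense
  na_ <- locus$n_antisense
  if (is.null(ns) || is.null(na_)) {
    m <- locus$reads$mult
    sense <- locus$reads$strand == locus$strand
    ns <- sum(m[sense]); na_ <- sum(m[!sense])
  }
  q <- (na_ + alpha) / (ns + na_ + 2 * alpha)
  log2(q / (1 - q))
}

#' Base-composition features
#'
#' Multiplicity-weighted nucleotide frequencies over all sense-read bases
#' (each read contributes length x multiplicity bases; `N` bases are
#' ignored), with an additive pseudocount per base, reported as log-odds
#' against equal base frequencies: `log2(f_b / 0.25)`.
#'
#' @param locus A locus from [get_locus()]; its reads must carry sequences
#'   (from BAM, or hydrated from a genome for BED input).
#' @param alpha Pseudocount added to each base count (default 0.5).
#' @return Named numeric vector `nuc_A, nuc_C, nuc_G, nuc_T`.
#' @export
nucleotide_features <- function(locus, alpha = 0.5) {
  stopifnot(alpha > 0)
  r <- sense_reads(locus)
  cnt <- c(A = 0, C = 0, G = 0, T = 0)
  if (nrow(r)) {
    if (anyNA(r$seq))
      stop_("locus ", locus$id, ": read sequences unavailable; ",
            "supply a genome FASTA so BED reads can be hydrated")
    freq <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(r$seq), c("A", "C", "G", "T"))
    cnt <- colSums(freq * r$mult)
  }
  f <- (cnt + alpha) / (sum(cnt) + 4 * alpha)
  out <- log2(f / 0.25)
  names(out) <- paste0("nuc_", c("A", "C", "G", "T"))
  out
}

#' Folding stability of the locus with flanking sequence
#'
#' Scores the sense-strand genomic sequence of the locus extended by
#' `flank` bases on either side (clipped at chromosome ends).
#'
#' Backends: `"vienna"` calls the external `RNAfold` program and returns the
#' minimum free energy in kcal/mol; `"nussinov"` returns minus the maximum
#' number of nested base pairs (Watson-Crick plus G.U wobble, minimum
#' hairpin loop of 3) from an exact dynamic program -- a documented proxy
#' that is monotone with fold stability but not in kcal/mol; `"table"`
#' looks the value up from a per-locus table.
#'
#' @param locus A locus from [get_locus()].
#' @param genome Genome [Biostrings::DNAStringSet] (vienna/nussinov backends).
#' @param flank Flanking bases on either side (default 40).
#' @param backend `"vienna"`, `"nussinov"` or `"table"`.
#' @param mfe_table data.frame with columns `locus_id`, `mfe` (table backend).
#' @return A single folding score.
#' @export
mfe_feature <- function(locus, genome = NULL, flank = 40L,
                        backend = c("vienna", "nussinov", "table"),
                        mfe_table = NULL) {
  backend <- match.arg(backend)
  if (backend == "table") {
    if (is.null(mfe_table)) stop_("table backend requires mfe_table")
    i <- match(locus$id, mfe_table$locus_id)
    if (is.na(i)) stop_("locus '", locus$id, "' missing from the mfe table")
    return(as.numeric(mfe_table$mfe[i]))
  }
  if (is.null(genome)) stop_("folding backends require a genome")
  seq <- genome_slice(genome, locus$chrom, locus$start - flank,
                      locus$end + flank, locus$strand)
  if (backend == "vienna") rnafold_mfe(seq) else nussinov_energy(seq)
}

#' Assemble the 25-column feature matrix for a set of loci
#'
#' Rows follow locus order; columns are [feature_names()] in fixed order,
#' preceded by `locus_id` and `label`. One folding backend is used for the
#' whole matrix (model features must be homogeneous).
#'
#' @param loci A (labelled) locus set.
#' @param genome Genome, required for nucleotide features on BED input
#'   without hydrated sequences and for the folding backends.
#' @param alpha Pseudocount used by all log-odds features (default 0.5).
#' @param mfe_backend Folding backend, see [mfe_feature()]. Defaults to
#'   `"vienna"` when `RNAfold` is on the PATH, else `"nussinov"`.
#' @param mfe_table Per-locus folding scores for the table backend.
#' @param flank Folding flank (default 40).
#' @return A `smrna_features` data.frame.
#' @export
build_feature_matrix <- function(loci, genome = NULL, alpha = 0.5,
                                 mfe_backend = NULL, mfe_table = NULL,
                                 flank = 40L) {
  stopifnot(inherits(loci, "smrna_loci"))
  if (is.null(mfe_backend)) {
    if (!is.null(mfe_table)) {
      mfe_backend <- "table"
    } else if (nzchar(Sys.which("RNAfold"))) {
      mfe_backend <- "vienna"
    } else {
      message("RNAfold not found; using the nussinov base-pair proxy backend")
      mfe_backend <- "nussinov"
    }
  }
  n <- length(loci)
  mat <- matrix(NA_real_, n, length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  need_seq <- n > 0L && !is.null(genome) &&
    any(vapply(loci$reads, function(r) anyNA(r$seq) && nrow(r) > 0L, logical(1)))
  for (i in seq_len(n)) {
    loc <- get_locus(loci, i)
    if (need_seq && nrow(loc$reads) && anyNA(loc$reads$seq))
      loc$reads <- hydrate_reads(loc$reads, genome)
    mat[i, LENGTH_FEATURES] <- length_features(loc, alpha)
    mat[i, "antisense"] <- antisense_feature(loc, alpha)
    mat[i, "pos_entropy5p"] <- positional_entropy(loc, "5p")
    mat[i, "pos_entropy3p"] <- positional_entropy(loc, "3p")
    mat[i, c("nuc_A", "nuc_C", "nuc_G", "nuc_T")] <- nucleotide_features(loc, alpha)
    mat[i, "mfe"] <- mfe_feature(loc, genome, flank, mfe_backend, mfe_table)
  }
  label <- loci$summary$label %||% rep(NA_character_, n)
  out <- data.frame(locus_id = loci$summary$id, label = label, mat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("smrna_features", "data.frame")
  out
}

#' Write / read a feature matrix as TSV
#'
#' Numeric values are written with 17 significant digits so a write -> read
#' round trip is bit-exact.
#'
#' @param x A `smrna_features` data.frame.
#' @param path File path.
#' @return `write_feature_matrix` returns the path invisibly;
#'   `read_feature_matrix` returns the matrix.
#' @export
write_feature_matrix <- function(x, path) write_tsv(x, path)

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("locus_id", "label", FEATURE_NAMES), names(df))
  if (length(missing))
    stop_("feature matrix is missing columns: ", paste(missing, collapse = ", "))
  df <- df[c("locus_id", "label", FEATURE_NAMES)]
  df$label <- as.character(df$label)
  class(df) <- c("smrna_features", "data.frame")
  df
}

# Split a feature table (or x/y pair) into a numeric matrix and label factor.
as_xy <- function(x, y = NULL) {
  if (inherits(x, "smrna_features")) {
    m <- as.matrix(x[FEATURE_NAMES])
    rownames(m) <- x$locus_id
    if (is.null(y)) y <- x$label
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  }
  if (!is.null(y)) y <- droplevels(factor(y))
  list(x = m, y = y)
}
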