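# Fixture builders used across test files. Everything is generated in code.

# Build a locus object directly from read coordinates.
make_locus <- function(start, end, strand = "+",
                       r_start = integer(), r_end = integer(),
                       r_strand = "+", r_seq = NA_character_, r_mult = 1L,
                       chrom = "chr1", id = NULL) {
  n <- length(r_start)
  reads <- data.frame(chrom = chrom, start = as.integer(r_start),
                      end = as.integer(r_end),
                      strand = rep_len(r_strand, n),
                      seq = rep_len(r_seq, n),
                      mult = as.integer(rep_len(r_mult, n)),
                      stringsAsFactors = FALSE)
  sense <- reads$strand == strand
  structure(list(id = id %||% sprintf("%s:%d-%d", chrom, start, end),
                 chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 n_sense = sum(reads$mult[sense]),
                 n_antisense = sum(reads$mult[!sense]),
                 n_reads = sum(reads$mult), reads = reads),
            class = "smrna_locus")
}

# Random locus with a random pileup, for oracle-agreement loops.
random_locus <- function(seed, with_seq = FALSE) {
  set.seed(seed)
  len <- sample(40:150, 1)
  start <- sample(0:500, 1)
  strand <- sample(c("+", "-"), 1)
  n <- sample(1:40, 1)
  span <- sample(10:34, n, replace = TRUE)   # includes out-of-range spans
  rs <- start + sample((-20):(len - 1), n, replace = TRUE)
  rs <- pmax(0L, rs)
  r_strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2))
  seqs <- if (with_seq)
    vapply(span, function(s) paste(sample(c("A", "C", "G", "T", "N"), s,
                                          replace = TRUE,
                                          prob = c(0.3, 0.2, 0.25, 0.24, 0.01)),
                                   collapse = ""), "")
  else NA_character_
  make_locus(start, start + len, strand,
             r_start = rs, r_end = rs + span, r_strand = r_strand,
             r_seq = seqs, r_mult = sample(1:3, n, replace = TRUE))
}

random_read_set <- function(seed, n_max = 50, coord_max = 500) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  start <- sample(0:(coord_max - 40), n, replace = TRUE)
  span <- sample(1:40, n, replace = TRUE)
  smrnaclass:::smrna_reads(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start, end = start + span,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mult = sample(1:3, n, replace = TRUE))
}

# Two-class Gaussian feature fixture with a planted mean shift.
make_gaussian <- function(n_per_class, p, shift, p_informative = 1,
                          seed = 1, classes = c("a", "b")) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- factor(rep(classes, each = n_per_class))
  for (j in seq_len(p_informative))
    x[y == classes[1], j] <- x[y == classes[1], j] + shift
  list(x = x, y = y)
}

# Planted-subgroup fixture: the "planted" class is a mixture of 8
# subgroups, each shifted in exactly one informative feature, so all 8
# informative features are individually necessary for classification.
# Features 1-4 are shifted up, 5-8 down; 17 pure-noise features follow.
make_planted_mixture <- function(n_per_class = 100, d = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * 25), n, 25,
              dimnames = list(NULL, c(paste0("inf", 1:8), paste0("noise", 1:17))))
  y <- rep(c("planted", "background"), each = n_per_class)
  sh <- c(rep(d, 4), rep(-d, 4))
  grp <- rep_len(1:8, n_per_class)
  pi <- which(y == "planted")
  for (j in 1:8) x[pi[grp == j], j] <- x[pi[grp == j], j] + sh[j]
  list(x = x, y = factor(y), shift_sign = c(sign(sh), rep(0L, 17)))
}

write_sam_fixture <- function(path, records,
                              header = c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000")) {
  writeLines(c(header, records), path)
  path
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
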