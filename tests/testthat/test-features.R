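test_that("length features peak at the dominant read span", {
  loc <- make_locus(100, 200, r_start = rep(120L, 10), r_end = rep(142L, 10))
  lf <- length_features(loc)
  expect_named(lf, paste0("L", 14:30))
  expect_gt(lf["L22"], max(lf[names(lf) != "L22"]))
  # every other span sits at the identical pseudocount floor
  expect_equal(unname(diff(range(lf[names(lf) != "L22"]))), 0)
})

test_that("loci with no in-range reads collapse to the uniform log-odds of -4", {
  # spans outside 14-30 nt contribute nothing to the length features
  loc <- make_locus(100, 200, r_start = c(110L, 120L), r_end = c(145L, 160L))
  expect_equal(unname(length_features(loc)), rep(log2((1 / 17) / (16 / 17)), 17))
  expect_equal(unname(length_features(loc)), rep(-4, 17))
  # no sense reads at all: same fallback, with a message
  anti <- make_locus(100, 200, r_start = 120L, r_end = 142L, r_strand = "-")
  expect_message(lf <- length_features(anti), "no sense-strand reads")
  expect_equal(unname(lf), rep(-4, 17))
})

test_that("length features equal a direct evaluation of the coverage formula", {
  loc <- make_locus(0, 100, r_start = c(rep(10L, 10), rep(40L, 5)),
                    r_end = c(rep(32L, 10), rep(65L, 5)))
  # raw features: f_22 = 10 * 22 / 100, f_25 = 5 * 25 / 100
  f <- setNames(numeric(17), paste0("L", 14:30))
  f["L22"] <- 2.2; f["L25"] <- 1.25
  alpha <- 0.5; cc <- 1 / 100
  p <- (f + alpha * cc) / (sum(f) + 17 * alpha * cc)
  expect_equal(length_features(loc, alpha = 0.5), log2(p / (1 - p)))
  expect_equal(length_features(loc), oracle_length_features(loc))
})

test_that("reads overhanging the locus only count their in-locus bases", {
  # span 20 read with 5 bases outside the locus: per-base count is 15
  loc <- make_locus(100, 160, r_start = c(95L, 110L), r_end = c(115L, 130L))
  expect_equal(length_features(loc), oracle_length_features(loc))
})

test_that("positional entropy follows the end distributions", {
  same5 <- make_locus(100, 200, r_start = rep(110L, 8),
                      r_end = 110L + c(20L, 21L, 22L, 23L, 20L, 21L, 22L, 24L))
  expect_equal(positional_entropy(same5, "5p"), 0)
  expect_gt(positional_entropy(same5, "3p"), 0)

  counts211 <- make_locus(100, 200, r_start = c(110L, 110L, 115L, 120L),
                          r_end = c(132L, 132L, 137L, 142L))
  expect_equal(positional_entropy(counts211, "5p"), 1.5)

  # realised uniform draw over 10 start positions
  set.seed(7)
  s <- sample(seq(110L, 119L), 1000, replace = TRUE)
  unif <- make_locus(100, 200, r_start = s, r_end = s + 22L)
  expect_equal(positional_entropy(unif, "5p"), oracle_entropy(unif, "5p"))
  expect_lt(abs(positional_entropy(unif, "5p") - log2(10)), 0.05)
})

test_that("the 5' end of a minus-strand locus is the read's maximum coordinate", {
  loc <- make_locus(100, 200, strand = "-",
                    r_start = c(110L, 115L, 120L),
                    r_end = c(140L, 140L, 140L), r_strand = "-")
  # all reads share the right end (= 5' on minus): zero 5' entropy
  expect_equal(positional_entropy(loc, "5p"), 0)
  expect_equal(positional_entropy(loc, "3p"), log2(3))
})

test_that("antisense log-odds match direct evaluation", {
  balanced <- make_locus(0, 50, r_start = c(10L, 10L), r_end = c(30L, 30L),
                         r_strand = c("+", "-"))
  expect_equal(antisense_feature(balanced), 0)

  none <- make_locus(0, 50, r_start = rep(10L, 20), r_end = rep(30L, 20))
  expect_equal(antisense_feature(none, 0.5), log2(0.5 / 20.5))

  five <- make_locus(0, 50, r_start = rep(10L, 20), r_end = rep(30L, 20),
                     r_strand = rep(c("+", "-"), c(15, 5)))
  expect_equal(antisense_feature(five, 0.5), log2(5.5 / 15.5))
})

test_that("nucleotide features are expression-weighted log-odds against 0.25", {
  eq <- make_locus(0, 50, r_start = c(10L, 20L), r_end = c(14L, 24L),
                   r_seq = c("ACGT", "GTCA"))
  expect_equal(unname(nucleotide_features(eq)), rep(0, 4))

  # 10 all-A reads of 20 bases: 200 A bases, alpha = 1
  alla <- make_locus(0, 50, r_start = rep(10L, 10), r_end = rep(30L, 10),
                     r_seq = strrep("A", 20))
  nf <- nucleotide_features(alla, alpha = 1)
  expect_equal(unname(nf["nuc_A"]), log2((201 / 204) / 0.25))
  expect_equal(unname(nf["nuc_C"]), log2((1 / 204) / 0.25))

  nosense <- make_locus(0, 50, r_start = 10L, r_end = 30L, r_strand = "-",
                        r_seq = strrep("A", 20))
  expect_equal(unname(nucleotide_features(nosense)), rep(0, 4))

  noseq <- make_locus(0, 50, r_start = 10L, r_end = 30L)
  expect_error(nucleotide_features(noseq), "genome")
})

test_that("the folding feature honours backend, flank and strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(400, seed = 3)))
  loc <- make_locus(100, 160, r_start = 110L, r_end = 132L)
  expected_seq <- as.character(Biostrings::subseq(genome[[1]], 61, 200))
  expect_equal(mfe_feature(loc, genome, backend = "nussinov"),
               nussinov_energy(expected_seq))
  # minus-strand locus folds the reverse complement
  locm <- make_locus(100, 160, strand = "-", r_start = 110L, r_end = 132L,
                     r_strand = "-")
  expect_equal(mfe_feature(locm, genome, backend = "nussinov"),
               nussinov_energy(as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(expected_seq)))))
  # flank clipped at the chromosome start
  locs <- make_locus(10, 60, r_start = 20L, r_end = 42L)
  expect_equal(mfe_feature(locs, genome, backend = "nussinov"),
               nussinov_energy(as.character(Biostrings::subseq(genome[[1]], 1, 100))))
  # vienna backend returns a finite kcal/mol value
  v <- mfe_feature(loc, genome, backend = "vienna")
  expect_true(is.finite(v) && v <= 0)
  # table backend: lookup and missing-id error
  tab <- data.frame(locus_id = loc$id, mfe = -12.5)
  expect_equal(mfe_feature(loc, backend = "table", mfe_table = tab), -12.5)
  expect_error(mfe_feature(locm, backend = "table",
                           mfe_table = data.frame(locus_id = "x", mfe = 1)),
               "missing from the mfe table")
})

test_that("feature ops agree with brute-force oracles on random loci", {
  for (seed in 1:150) {
    loc <- random_locus(seed, with_seq = TRUE)
    expect_equal(length_features(loc), oracle_length_features(loc),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(positional_entropy(loc, "5p"), oracle_entropy(loc, "5p"),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(positional_entropy(loc, "3p"), oracle_entropy(loc, "3p"),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(antisense_feature(loc), oracle_antisense(loc),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(nucleotide_features(loc), oracle_nucleotide(loc),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("features are invariant to translation and multiplicity expansion", {
  loc <- random_locus(1234, with_seq = TRUE)
  shifted <- loc
  shifted$start <- loc$start + 5000L; shifted$end <- loc$end + 5000L
  shifted$reads$start <- loc$reads$start + 5000L
  shifted$reads$end <- loc$reads$end + 5000L
  expect_equal(length_features(shifted), length_features(loc))
  expect_equal(positional_entropy(shifted, "5p"), positional_entropy(loc, "5p"))
  expect_equal(antisense_feature(shifted), antisense_feature(loc))
  expect_equal(nucleotide_features(shifted), nucleotide_features(loc))

  # a multiplicity-m read behaves like m duplicated rows
  expanded <- loc
  expanded$reads <- loc$reads[rep(seq_len(nrow(loc$reads)), loc$reads$mult), ]
  expanded$reads$mult <- 1L
  expect_equal(length_features(expanded), length_features(loc))
  expect_equal(positional_entropy(expanded, "5p"), positional_entropy(loc, "5p"))
  expect_equal(positional_entropy(expanded, "3p"), positional_entropy(loc, "3p"))
  expect_equal(antisense_feature(expanded), antisense_feature(loc))
  expect_equal(nucleotide_features(expanded), nucleotide_features(loc))
})

test_that("features are invariant under genome mirroring (strand symmetry)", {
  glen <- 400L
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(glen, seed = 8)))
  loc <- make_locus(100, 160, r_start = c(105L, 110L, 120L, 118L),
                    r_end = c(127L, 132L, 142L, 140L),
                    r_strand = c("+", "+", "+", "-"))
  loc$reads <- hydrate_reads(loc$reads, genome)

  mgenome <- Biostrings::DNAStringSet(c(chr1 = revcomp(as.character(genome[[1]]))))
  mloc <- loc
  mloc$start <- glen - loc$end; mloc$end <- glen - loc$start
  mloc$strand <- "-"
  mloc$reads$start <- glen - loc$reads$end
  mloc$reads$end <- glen - loc$reads$start
  mloc$reads$strand <- ifelse(loc$reads$strand == "+", "-", "+")
  mloc$reads$seq <- NA_character_
  mloc$reads <- hydrate_reads(mloc$reads, mgenome)

  expect_equal(mloc$reads$seq, loc$reads$seq)  # same RNA product per read
  expect_equal(length_features(mloc), length_features(loc))
  expect_equal(positional_entropy(mloc, "5p"), positional_entropy(loc, "5p"))
  expect_equal(positional_entropy(mloc, "3p"), positional_entropy(loc, "3p"))
  expect_equal(antisense_feature(mloc), antisense_feature(loc))
  expect_equal(nucleotide_features(mloc), nucleotide_features(loc))
  expect_equal(mfe_feature(mloc, mgenome, backend = "nussinov"),
               mfe_feature(loc, genome, backend = "nussinov"))
})

test_that("entropy is bounded by the log of distinct end positions and depth scaling shrinks the pseudocount effect", {
  for (seed in 1:25) {
    loc <- random_locus(seed)
    sense <- loc$reads[loc$reads$strand == loc$strand, ]
    if (!nrow(sense)) next
    ends5 <- if (loc$strand == "+") sense$start else sense$end - 1L
    h <- positional_entropy(loc, "5p")
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(ends5))) + 1e-12)
  }
  # scaling all counts leaves raw proportions unchanged and moves the
  # pseudocounted log-odds closer to the raw value
  loc <- make_locus(0, 100, r_start = c(rep(10L, 3), rep(40L, 2)),
                    r_end = c(rep(32L, 3), rep(65L, 2)))
  raw_p <- function(l) {
    f <- setNames(numeric(17), paste0("L", 14:30))
    sp <- l$reads$end - l$reads$start
    for (i in seq_len(nrow(l$reads)))
      f[paste0("L", sp[i])] <- f[paste0("L", sp[i])] +
        l$reads$mult[i] * (l$reads$end[i] - l$reads$start[i]) / 100
    log2((f / sum(f)) / (1 - f / sum(f)))
  }
  scaled <- loc; scaled$reads$mult <- 10L
  expect_equal(raw_p(scaled), raw_p(loc))
  d1 <- abs(length_features(loc)[c("L22", "L25")] - raw_p(loc)[c("L22", "L25")])
  d10 <- abs(length_features(scaled)[c("L22", "L25")] - raw_p(scaled)[c("L22", "L25")])
  expect_true(all(d10 < d1))
})

test_that("the assembled matrix matches per-op outputs and round-trips bit-exactly", {
  ds <- generate_dataset(n_per_class = 2, seed = 31)
  fm <- dataset_features(ds)
  expect_s3_class(fm, "smrna_features")
  expect_equal(names(fm), c("locus_id", "label", feature_names()))
  expect_false(anyNA(fm[feature_names()]))

  loci <- filter_loci(segment_loci(ds$reads, max_gap = 50), 15)
  loci <- label_loci(loci, ds$annotations, strand_aware = FALSE,
                     classes = names(ds$profiles))
  i <- which(loci$summary$id == fm$locus_id[1])
  loc <- get_locus(loci, i)
  expect_equal(as.numeric(fm[1, paste0("L", 14:30)]),
               unname(length_features(loc)))
  expect_equal(fm$antisense[1], antisense_feature(loc))
  expect_equal(fm$pos_entropy5p[1], positional_entropy(loc, "5p"))

  tsv <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, tsv)
  back <- read_feature_matrix(tsv)
  expect_identical(as.matrix(back[feature_names()]),
                   as.matrix(fm[feature_names()]))
  expect_identical(back$locus_id, fm$locus_id)
})
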