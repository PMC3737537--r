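# Synthetic class-specific read pileups. Each class profile encodes the
# pileup statistics the classifier keys on: a multinomial over read spans
# 14-30 nt, 5'/3' cleavage-site concentrations (larger -> tighter cleavage,
# lower positional entropy; the positional spread is locus_length /
# concentration), an antisense read fraction, read base composition, and a
# folding-score distribution used by the "table" folding backend.

#' Construct a class profile for the pileup generator
#'
#' @param name Class name.
#' @param length_weights 17 non-negative weights over read spans 14-30
#'   (normalised internally).
#' @param end5_concentration,end3_concentration Positive reals; the
#'   positional standard deviation of the anchored end is
#'   `locus_length / concentration`, so larger values mean more precise
#'   cleavage and lower positional entropy.
#' @param antisense_fraction Expected fraction of reads on the antisense
#'   strand, in `[0, 1)`.
#' @param base_weights 4 non-negative weights (A, C, G, T) for the genomic
#'   base composition inside the locus and 60 bp around it.
#' @param mfe_mean,mfe_sd Normal distribution of the per-locus folding
#'   score (kcal/mol scale; higher = less stable).
#' @param locus_length_range Integer range of locus lengths (bp).
#' @param reads_per_locus_range Integer range of reads per locus
#'   (minimum >= 15 so generated loci pass the default read filter).
#' @return A `class_profile` list.
#' @export
class_profile <- function(name, length_weights, end5_concentration,
                          end3_concentration, antisense_fraction,
                          base_weights, mfe_mean, mfe_sd,
                          locus_length_range, reads_per_locus_range) {
  stopifnot(length(length_weights) == 17L, all(length_weights >= 0),
            sum(length_weights) > 0,
            end5_concentration > 0, end3_concentration > 0,
            antisense_fraction >= 0, antisense_fraction < 1,
            length(base_weights) == 4L, all(base_weights >= 0),
            sum(base_weights) > 0,
            is.finite(mfe_mean), mfe_sd >= 0,
            length(locus_length_range) == 2L,
            locus_length_range[1] >= 40L,
            locus_length_range[1] <= locus_length_range[2],
            length(reads_per_locus_range) == 2L,
            reads_per_locus_range[1] >= 15L,
            reads_per_locus_range[1] <= reads_per_locus_range[2])
  structure(list(
    name = name,
    length_weights = stats::setNames(length_weights / sum(length_weights),
                                     paste0("L", 14:30)),
    end5_concentration = end5_concentration,
    end3_concentration = end3_concentration,
    antisense_fraction = antisense_fraction,
    base_weights = stats::setNames(base_weights / sum(base_weights),
                                   c("A", "C", "G", "T")),
    mfe_mean = mfe_mean, mfe_sd = mfe_sd,
    locus_length_range = as.integer(locus_length_range),
    reads_per_locus_range = as.integer(reads_per_locus_range)),
    class = "class_profile")
}

# span weights as a discretised normal over 14..30
span_peak <- function(center, sd) stats::dnorm(14:30, center, sd)

#' Default class profiles for the six non-coding RNA classes
#'
#' The profiles encode the class-specific pileup signatures observed in
#' small RNA-seq: miRNA loci yield a sharp 22 nt product with a precise 5'
#' and a looser 3' cleavage site and a stably folding hairpin; C/D box
#' snoRNA fragments are long (>25 nt, with a minor short component) with
#' imprecise cleavage at both ends; transposon-derived fragments are short
#' (<19 nt), precisely cleaved, with substantial antisense transcription
#' and weak folding; lincRNA fragments are short degradation-like products
#' with dispersed ends; scRNA fragments peak at 27 nt with weak folding;
#' snRNA fragments peak at 14 nt from U-rich transcripts.
#'
#' @return Named list of six [class_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    miRNA = class_profile("miRNA",
      # sharp enough that the 22-mer is the modal product of nearly every locus
      length_weights = span_peak(22, 0.7),
      end5_concentration = 40, end3_concentration = 5,
      antisense_fraction = 0.02,
      base_weights = c(0.28, 0.22, 0.28, 0.22),
      mfe_mean = -35, mfe_sd = 4,
      locus_length_range = c(60, 95),
      reads_per_locus_range = c(30, 80)),
    CD_box_snoRNA = class_profile("CD_box_snoRNA",
      length_weights = 0.15 * span_peak(15, 1) + 0.85 * span_peak(28, 2),
      end5_concentration = 3, end3_concentration = 3,
      antisense_fraction = 0.02,
      base_weights = c(0.28, 0.20, 0.24, 0.28),
      mfe_mean = -25, mfe_sd = 4,
      locus_length_range = c(70, 120),
      reads_per_locus_range = c(25, 70)),
    transposon = class_profile("transposon",
      length_weights = span_peak(17, 1.5),
      end5_concentration = 30, end3_concentration = 30,
      antisense_fraction = 0.25,
      base_weights = c(0.34, 0.18, 0.22, 0.26),
      mfe_mean = -8, mfe_sd = 3,
      locus_length_range = c(80, 140),
      reads_per_locus_range = c(20, 60)),
    lincRNA = class_profile("lincRNA",
      length_weights = span_peak(15.5, 1.8),
      end5_concentration = 3, end3_concentration = 3,
      antisense_fraction = 0.12,
      base_weights = c(0.25, 0.25, 0.25, 0.25),
      mfe_mean = -15, mfe_sd = 5,
      locus_length_range = c(90, 150),
      reads_per_locus_range = c(15, 50)),
    scRNA = class_profile("scRNA",
      length_weights = span_peak(27, 1.5),
      end5_concentration = 10, end3_concentration = 10,
      antisense_fraction = 0.05,
      base_weights = c(0.24, 0.26, 0.28, 0.22),
      mfe_mean = -10, mfe_sd = 3,
      locus_length_range = c(90, 130),
      reads_per_locus_range = c(25, 70)),
    snRNA = class_profile("snRNA",
      length_weights = span_peak(14, 1.2),
      end5_concentration = 10, end3_concentration = 10,
      antisense_fraction = 0.02,
      base_weights = c(0.20, 0.20, 0.20, 0.40),
      mfe_mean = -28, mfe_sd = 4,
      locus_length_range = c(110, 170),
      reads_per_locus_range = c(20, 60)))
}

#' Write / read generator profiles as a YAML config
#'
#' @param profiles Named list of [class_profile()] objects.
#' @param path File path.
#' @return `write_profiles` returns the path invisibly; `read_profiles`
#'   the restored profile list.
#' @export
write_profiles <- function(profiles, path) {
  yaml::write_yaml(lapply(profiles, function(p) {
    p <- unclass(p)
    p$length_weights <- as.numeric(p$length_weights)
    p$base_weights <- as.numeric(p$base_weights)
    p
  }), path, precision = 15L)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(class_profile, p))
}

#' Interpolate class profiles toward their pooled mean
#'
#' `scale = 1` leaves the profiles fully distinct; `scale = 0` collapses
#' every class onto the pooled mean profile, making the classes
#' statistically identical. All profile parameters are interpolated
#' linearly.
#'
#' @param profiles Named list of profiles.
#' @param scale Number in `[0, 1]`.
#' @return Interpolated profile list.
#' @export
interpolate_profiles <- function(profiles, scale) {
  stopifnot(scale >= 0, scale <= 1)
  fields <- c("end5_concentration", "end3_concentration",
              "antisense_fraction", "mfe_mean", "mfe_sd")
  mean_lw <- rowMeans(sapply(profiles, `[[`, "length_weights"))
  mean_bw <- rowMeans(sapply(profiles, `[[`, "base_weights"))
  mean_f <- sapply(fields, function(f) mean(sapply(profiles, `[[`, f)))
  mean_ll <- round(rowMeans(sapply(profiles, `[[`, "locus_length_range")))
  mean_rr <- round(rowMeans(sapply(profiles, `[[`, "reads_per_locus_range")))
  lapply(profiles, function(p) {
    args <- list(
      name = p$name,
      length_weights = scale * p$length_weights + (1 - scale) * mean_lw,
      base_weights = scale * p$base_weights + (1 - scale) * mean_bw,
      locus_length_range = round(scale * p$locus_length_range +
                                 (1 - scale) * mean_ll),
      reads_per_locus_range = round(scale * p$reads_per_locus_range +
                                    (1 - scale) * mean_rr))
    for (f in fields)
      args[[f]] <- scale * p[[f]] + (1 - scale) * mean_f[[f]]
    do.call(class_profile, args)
  })
}

#' Generate a synthetic dataset of class-specific read pileups
#'
#' Loci are placed non-overlapping (at least 100 bp apart) on one synthetic
#' chromosome in shuffled class order, each on a random strand. Per read,
#' the span is drawn from the class length multinomial; one end is anchored
#' (5' with probability `c5 / (c5 + c3)`, else 3') at a class-typical
#' cleavage site with positional standard deviation
#' `locus_length / concentration`, and the other end follows at span
#' distance, so the realised span distribution is exactly the multinomial.
#' Antisense reads are placed uniformly on the opposite strand. Genomic
#' bases inside each locus (plus 60 bp) follow the class base weights;
#' the background is uniform A/C/G/T. Per-locus folding scores are drawn
#' from `Normal(mfe_mean, mfe_sd)`. The same seed gives byte-identical
#' output files via [write_dataset()].
#'
#' @param profiles Named list of [class_profile()]s (default
#'   [default_profiles()]).
#' @param n_per_class Loci per class (scalar or per-class vector).
#' @param seed RNG seed.
#' @param chrom Chromosome name (default `"chrS"`).
#' @param gap_range Range of inter-locus gaps in bp (default 150-250; must
#'   stay >= 100 so loci remain well separated after read overhang).
#' @return A `smrna_sim` list: `genome` ([Biostrings::DNAStringSet]),
#'   `reads` (read table), `annotations`, `truth`, `mfe`, `seed`,
#'   `profiles`.
#' @export
generate_dataset <- function(profiles = default_profiles(), n_per_class = 50L,
                             seed = 1L, chrom = "chrS",
                             gap_range = c(150L, 250L)) {
  stopifnot(length(profiles) >= 1L, gap_range[1] >= 100L,
            gap_range[1] <= gap_range[2])
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, "", "name")
  n_per_class <- rep_len(as.integer(n_per_class), length(profiles))
  stopifnot(all(n_per_class >= 0L))
  with_seed(seed, {
    cls_of <- rep(names(profiles), n_per_class)
    n_loci <- length(cls_of)
    if (n_loci == 0L)
      return(empty_dataset(chrom, seed, profiles))
    cls_of <- cls_of[sample.int(n_loci)]
    idx_within <- stats::ave(seq_len(n_loci), cls_of, FUN = seq_along)
    lens <- integer(n_loci); starts <- integer(n_loci)
    cur <- 500L
    for (i in seq_len(n_loci)) {
      p <- profiles[[cls_of[i]]]
      lens[i] <- sample(p$locus_length_range[1]:p$locus_length_range[2], 1L)
      starts[i] <- cur
      cur <- cur + lens[i] + sample(gap_range[1]:gap_range[2], 1L)
    }
    ends <- starts + lens
    strands <- sample(c("+", "-"), n_loci, replace = TRUE)
    glen <- cur + 500L
    gseq <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    reads <- vector("list", n_loci)
    mfe <- numeric(n_loci)
    for (i in seq_len(n_loci)) {
      p <- profiles[[cls_of[i]]]
      gfrom <- max(1L, starts[i] - 60L + 1L)
      gto <- min(glen, ends[i] + 60L)
      gseq[gfrom:gto] <- sample(c("A", "C", "G", "T"), gto - gfrom + 1L,
                                replace = TRUE, prob = p$base_weights)
      reads[[i]] <- draw_locus_reads(p, starts[i], lens[i], strands[i], chrom)
      mfe[i] <- rnorm(1, p$mfe_mean, p$mfe_sd)
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(gseq, collapse = ""), chrom))
    reads <- do.call(rbind, reads)
    reads <- reads[order(reads$start, reads$end, reads$strand), , drop = FALSE]
    rownames(reads) <- NULL
    class(reads) <- c("smrna_reads", "data.frame")
    reads <- hydrate_reads(reads, genome)
    name <- sprintf("%s_%04d", cls_of, idx_within)
    annotations <- data.frame(chrom = chrom, start = starts, end = ends,
                              strand = strands, rna_class = cls_of,
                              name = name, stringsAsFactors = FALSE)
    ord <- order(annotations$start)
    annotations <- annotations[ord, , drop = FALSE]
    rownames(annotations) <- NULL
    class(annotations) <- c("smrna_annotations", "data.frame")
    truth <- data.frame(name = annotations$name, chrom = chrom,
                        start = annotations$start, end = annotations$end,
                        strand = annotations$strand,
                        rna_class = annotations$rna_class,
                        stringsAsFactors = FALSE)
    mfe_tab <- data.frame(name = annotations$name, mfe = mfe[ord],
                          stringsAsFactors = FALSE)
    structure(list(genome = genome, reads = reads, annotations = annotations,
                   truth = truth, mfe = mfe_tab, seed = seed,
                   profiles = profiles),
              class = "smrna_sim")
  })
}

empty_dataset <- function(chrom, seed, profiles) {
  structure(list(
    genome = Biostrings::DNAStringSet(stats::setNames(
      paste(rep("A", 100), collapse = ""), chrom)),
    reads = smrna_reads(character(), integer(), integer(), character()),
    annotations = structure(data.frame(chrom = character(), start = integer(),
                                       end = integer(), strand = character(),
                                       rna_class = character(),
                                       name = character(),
                                       stringsAsFactors = FALSE),
                            class = c("smrna_annotations", "data.frame")),
    truth = data.frame(), mfe = data.frame(name = character(),
                                           mfe = numeric()),
    seed = seed, profiles = profiles), class = "smrna_sim")
}

# Draw the reads of one locus, in local coordinates [0, len), then map to
# the genome; for minus-strand loci the local axis is mirrored so that the
# 5' anchor sits at the high-coordinate end.
draw_locus_reads <- function(p, start, len, strand, chrom) {
  n <- sample(p$reads_per_locus_range[1]:p$reads_per_locus_range[2], 1L)
  n_anti <- min(rbinom(1L, n, p$antisense_fraction), n - 1L)
  n_sense <- n - n_anti
  span <- sample(14:30, n_sense, replace = TRUE, prob = p$length_weights)
  mu5 <- round(0.15 * len)
  med_span <- round(sum((14:30) * p$length_weights))
  mu3 <- mu5 + med_span
  anchor5 <- runif(n_sense) < p$end5_concentration /
    (p$end5_concentration + p$end3_concentration)
  s_loc <- integer(n_sense)
  s_loc[anchor5] <- round(rnorm(sum(anchor5), mu5, len / p$end5_concentration))
  e3 <- round(rnorm(sum(!anchor5), mu3, len / p$end3_concentration))
  s_loc[!anchor5] <- e3 - span[!anchor5]
  # keep reads within 20 bp of the locus so neighbouring loci stay separate
  s_loc <- pmax(-20L, pmin(s_loc, len + 20L - span))
  if (strand == "+") {
    rs <- start + s_loc
  } else {
    rs <- start + (len - (s_loc + span))
  }
  out <- data.frame(chrom = chrom, start = rs, end = rs + span,
                    strand = strand, seq = NA_character_, mult = 1L,
                    stringsAsFactors = FALSE)
  if (n_anti > 0L) {
    aspan <- sample(14:30, n_anti, replace = TRUE, prob = p$length_weights)
    as_loc <- vapply(aspan, function(sp) sample.int(len - sp, 1L) - 1L,
                     integer(1))
    ars <- start + as_loc
    out <- rbind(out, data.frame(chrom = chrom, start = ars,
                                 end = ars + aspan,
                                 strand = if (strand == "+") "-" else "+",
                                 seq = NA_character_, mult = 1L,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.smrna_sim <- function(x, ...) {
  cat("Synthetic small RNA dataset (seed", paste0(x$seed, "):"),
      nrow(x$truth), "loci,", nrow(x$reads), "reads on",
      names(x$genome), paste0("(", Biostrings::width(x$genome), " bp)\n"))
  if (nrow(x$truth)) print(table(x$truth$rna_class))
  invisible(x)
}

#' Generate a dataset with tunable class separability
#'
#' Interpolates every profile toward the pooled mean profile
#' ([interpolate_profiles()]) and generates a dataset. At `scale = 0` the
#' classes are statistically identical (accuracy should fall to the
#' permutation baseline); at `scale = 1` the classes are fully distinct.
#'
#' @param scale Separability in `[0, 1]`.
#' @inheritParams generate_dataset
#' @return A `smrna_sim` dataset.
#' @export
sweep_separability <- function(scale, profiles = default_profiles(),
                               n_per_class = 50L, seed = 1L, ...) {
  generate_dataset(interpolate_profiles(profiles, scale),
                   n_per_class = n_per_class, seed = seed, ...)
}

#' Write a synthetic dataset to files
#'
#' Emits `genome.fa`, `reads.bed` (BED6), `annotations.bed` (BED6, class
#' appended to the name as `name|class`), `truth.tsv` and `mfe.tsv`.
#' Output is byte-deterministic given the dataset.
#'
#' @param ds A `smrna_sim` dataset.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "smrna_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             reads = file.path(dir, "reads.bed"),
             annotations = file.path(dir, "annotations.bed"),
             truth = file.path(dir, "truth.tsv"),
             mfe = file.path(dir, "mfe.tsv"))
  Biostrings::writeXStringSet(ds$genome, paths["genome"])
  r <- ds$reads
  rb <- data.frame(r$chrom, r$start, r$end,
                   sprintf("r%06d", seq_len(nrow(r))), 0L, r$strand)
  write.table(rb, paths["reads"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  a <- ds$annotations
  ab <- data.frame(a$chrom, a$start, a$end,
                   paste0(a$name, "|", a$rna_class), 0L, a$strand)
  write.table(ab, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(ds$truth, paths["truth"])
  write_tsv(ds$mfe, paths["mfe"])
  invisible(paths)
}

#' Run the full feature pipeline on a synthetic dataset
#'
#' Segments the reads into loci, applies the read filter, labels loci from
#' the dataset's annotations, and assembles the feature matrix. The
#' default folding backend is the per-locus score table shipped with the
#' dataset; `"nussinov"` or `"vienna"` fold the synthetic genome instead.
#'
#' @param ds A `smrna_sim` dataset.
#' @param min_coverage,max_gap Segmentation parameters (defaults 1 and 50).
#' @param min_reads Locus read filter (default 15).
#' @param alpha Feature pseudocount (default 0.5).
#' @param mfe_backend `"table"` (default), `"nussinov"` or `"vienna"`.
#' @param flank Folding flank (default 40).
#' @param drop_unknown Drop loci that fail to acquire a class label
#'   (default `TRUE`).
#' @return A `smrna_features` table labelled with the true classes.
#' @export
dataset_features <- function(ds, min_coverage = 1L, max_gap = 50L,
                             min_reads = 15L, alpha = 0.5,
                             mfe_backend = "table", flank = 40L,
                             drop_unknown = TRUE) {
  stopifnot(inherits(ds, "smrna_sim"))
  loci <- segment_loci(ds$reads, min_coverage = min_coverage,
                       max_gap = max_gap)
  loci <- filter_loci(loci, min_reads = min_reads)
  loci <- label_loci(loci, ds$annotations, strand_aware = FALSE,
                     classes = names(ds$profiles))
  if (drop_unknown && any(loci$summary$label == "unknown")) {
    message(sum(loci$summary$label == "unknown"),
            " unlabelled locus/loci dropped")
    loci <- loci[loci$summary$label != "unknown"]
  }
  mfe_table <- NULL
  if (identical(mfe_backend, "table"))
    mfe_table <- data.frame(
      locus_id = loci$summary$id,
      mfe = ds$mfe$mfe[match(loci$summary$ann_name, ds$mfe$name)],
      stringsAsFactors = FALSE)
  build_feature_matrix(loci, genome = ds$genome, alpha = alpha,
                       mfe_backend = mfe_backend, mfe_table = mfe_table,
                       flank = flank)
}
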