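# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each definition (per-base loops, explicit
# enumeration, dense arrays) so they share no code path with the package.

oracle_length_features <- function(locus, alpha = 0.5) {
  len <- locus$end - locus$start
  f <- stats::setNames(numeric(17), paste0("L", 14:30))
  for (ri in seq_len(nrow(locus$reads))) {
    r <- locus$reads[ri, ]
    if (r$strand != locus$strand) next
    span <- r$end - r$start
    if (span < 14 || span > 30) next
    for (k in locus$start:(locus$end - 1)) {
      if (k >= r$start && k < r$end)
        f[paste0("L", span)] <- f[paste0("L", span)] + r$mult
    }
  }
  f <- f / len
  cc <- 1 / len
  p <- (f + alpha * cc) / (sum(f) + 17 * alpha * cc)
  log2(p / (1 - p))
}

oracle_entropy <- function(locus, which_end) {
  pos <- c()
  for (ri in seq_len(nrow(locus$reads))) {
    r <- locus$reads[ri, ]
    if (r$strand != locus$strand) next
    five <- if (locus$strand == "+") r$start else r$end - 1
    three <- if (locus$strand == "+") r$end - 1 else r$start
    pos <- c(pos, rep(if (which_end == "5p") five else three, r$mult))
  }
  if (!length(pos)) return(0)
  p <- as.numeric(table(pos)) / length(pos)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

oracle_antisense <- function(locus, alpha = 0.5) {
  ns <- 0; na_ <- 0
  for (ri in seq_len(nrow(locus$reads))) {
    r <- locus$reads[ri, ]
    if (r$strand == locus$strand) ns <- ns + r$mult else na_ <- na_ + r$mult
  }
  q <- (na_ + alpha) / (ns + na_ + 2 * alpha)
  log2(q / (1 - q))
}

oracle_nucleotide <- function(locus, alpha = 0.5) {
  cnt <- c(A = 0, C = 0, G = 0, T = 0)
  for (ri in seq_len(nrow(locus$reads))) {
    r <- locus$reads[ri, ]
    if (r$strand != locus$strand) next
    for (b in strsplit(r$seq, "")[[1]])
      if (b %in% names(cnt)) cnt[b] <- cnt[b] + r$mult
  }
  f <- (cnt + alpha) / (sum(cnt) + 4 * alpha)
  stats::setNames(log2(f / 0.25), paste0("nuc_", names(cnt)))
}

# Exhaustive enumeration of all nested (non-crossing) structures with
# Watson-Crick + G.U pairing and a minimum hairpin loop; returns the
# maximum pair count. Only for short sequences.
oracle_nussinov <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Uacgtu", "TACGTT", seq), "")[[1]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    m <- best(i + 1, j)                       # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (pairs_ok(s[i], s[k]))               # i paired with k
        m <- max(m, 1 + best(i + 1, k - 1) + (if (k < j) best(k + 1, j) else 0))
    }
    m
  }
  if (length(s) < 2) 0 else best(1, length(s))
}

# Dense per-base coverage array segmentation oracle.
oracle_segment <- function(reads, min_coverage, max_gap) {
  out <- data.frame(chrom = character(), start = integer(), end = integer())
  for (chrom in sort(unique(reads$chrom))) {
    r <- reads[reads$chrom == chrom, ]
    cov <- numeric(max(r$end))
    for (ri in seq_len(nrow(r)))
      cov[(r$start[ri] + 1):r$end[ri]] <- cov[(r$start[ri] + 1):r$end[ri]] + r$mult[ri]
    above <- cov >= min_coverage
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    iv <- cbind(starts[runs$values], ends[runs$values])
    if (!nrow(iv)) next
    merged <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      gap <- iv[i, 1] - merged[nrow(merged), 2] - 1
      if (gap <= max_gap) merged[nrow(merged), 2] <- iv[i, 2]
      else merged <- rbind(merged, iv[i, ])
    }
    out <- rbind(out, data.frame(chrom = chrom, start = merged[, 1] - 1,
                                 end = merged[, 2]))
  }
  out
}
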