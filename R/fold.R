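#' Base-pair maximisation folding score
#'
#' Exact dynamic program for the maximum number of nested base pairs
#' (Watson-Crick A-T/U and G-C plus G.U wobble) with a minimum hairpin loop
#' of `min_loop` unpaired bases. Returns minus the pair count, so that, like
#' a free energy, lower values mean more stable folds. The score is a proxy
#' in pair units, not kcal/mol.
#'
#' @param seq A nucleotide string (DNA or RNA alphabet; case-insensitive).
#' @param min_loop Minimum hairpin loop size (default 3).
#' @return Minus the maximum number of base pairs (<= 0).
#' @export
#' @examples
#' nussinov_energy("GGGAAAACCC")  # -3: three G-C pairs around an AAAA loop
nussinov_energy <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, is_count(min_loop, 0L))
  -.nussinov_pairs(seq, as.integer(min_loop))
}

#' Minimum free energy via RNAfold
#'
#' Thin wrapper around the external ViennaRNA `RNAfold` program (default
#' parameters). Errors with advice to use the `nussinov` or `table` folding
#' backends when `RNAfold` is not on the PATH.
#'
#' @param seq A nucleotide string.
#' @return The predicted minimum free energy in kcal/mol.
#' @export
rnafold_mfe <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  if (!nzchar(Sys.which("RNAfold")))
    stop_("RNAfold (ViennaRNA) not found on the PATH; use the 'nussinov' ",
          "or 'table' folding backend instead")
  out <- system2("RNAfold", args = "--noPS", input = seq, stdout = TRUE)
  last <- out[length(out)]
  m <- regmatches(last, regexec("\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)\\s*$", last))[[1]]
  if (length(m) != 2L) stop_("could not parse RNAfold output: ", last)
  as.numeric(m[2])
}
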