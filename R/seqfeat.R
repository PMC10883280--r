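# Motif sequence properties: Kyte-Doolittle hydropathy and the hydropathy
# symmetry score.

#' Kyte-Doolittle hydropathy scale
#'
#' Named vector over the 20 standard one-letter amino acids; values in
#' \[-4.5, 4.5\] (positive = hydrophobic).
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

hydropathy_profile <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(chars, names(KYTE_DOOLITTLE))
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  unname(KYTE_DOOLITTLE[chars])
}

#' Average hydropathy of a peptide
#'
#' Mean Kyte-Doolittle hydropathy over the residues of the sequence.
#'
#' @param sequence Peptide over the 20 standard one-letter codes.
#' @return Mean hydropathy value.
#' @export
average_hydropathy <- function(sequence) mean(hydropathy_profile(sequence))

#' Hydropathy symmetry score of a peptide
#'
#' With `x` the motif length, `a = floor(x / 2)` and `H_n` the hydropathy of
#' residue `n`, the score is `sum_{n=1..a} |H_n - H_{x-n+1}| / a`: zero for a
#' hydropathy-palindromic peptide, larger the more asymmetric its hydropathy
#' profile. The middle residue of odd-length peptides does not contribute.
#'
#' @param sequence Peptide of length at least 2.
#' @return Non-negative symmetry score.
#' @export
symmetry_score <- function(sequence) {
  h <- hydropathy_profile(sequence)
  x <- length(h)
  if (x < 2L) stop("sequence must have length >= 2")
  a <- x %/% 2L
  n <- seq_len(a)
  sum(abs(h[n] - h[x - n + 1L])) / a
}
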