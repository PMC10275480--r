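#' Convert mRNA-seq RPKM to absolute mRNA abundance
#'
#' Distributes the total cellular transcript pool `N_m` across genes in
#' proportion to their RPKM, so that abundances sum exactly to `N_m`.
#' Because the normalisation runs over exactly the genes supplied,
#' subsetting the table changes absolute abundances (and hence rates).
#'
#' @param r Numeric vector of mRNA-seq RPKM values (>= 0, not all zero).
#' @param N_m Total number of transcripts per cell.
#'
#' @return Numeric vector of mRNA copies per cell, summing to `N_m`.
#' @examples
#' mrna_abundance_from_rpkm(c(1, 3), N_m = 60000)
#' @export
mrna_abundance_from_rpkm <- function(r, N_m = rate_constants()$N_m) {
  if (!is.numeric(r) || length(r) == 0 || any(!is.finite(r)) || any(r < 0))
    stop("invalid measurement: RPKM values must be finite and non-negative")
  tot <- sum(r)
  if (tot <= 0)
    stop("invalid measurement: all RPKM values are zero")
  stopifnot_positive(N_m = N_m)
  N_m * r / tot
}

#' Transcription rate from mRNA abundance and decay
#'
#' At steady state the synthesis rate of transcripts balances their decay,
#' so the transcription rate is the product of mRNA copy number and mRNA
#' decay rate.
#'
#' @param m mRNA copies per cell (> 0).
#' @param alpha mRNA decay rate in h^-1 (> 0); either the median constant
#'   or a gene-specific value.
#'
#' @return Transcription rate beta_m in mRNA/h.
#' @export
transcription_rate <- function(m, alpha = rate_constants()$alpha_m) {
  stopifnot_positive(m = m, alpha = alpha)
  m * alpha
}

#' Translation rates from ribosome-footprint RPKM
#'
#' The total translational flux of the cell, `N_p * alpha_p` proteins per
#' hour, is apportioned to genes by their share of ribosome-footprint RPKM
#' and divided by mRNA abundance, giving per-transcript translation rates.
#' The flux identity `sum(beta_p * m) == N_p * alpha_p` holds by
#' construction.
#'
#' @param s Footprint RPKM vector (>= 0, not all zero).
#' @param m mRNA copies per cell, positive wherever `s > 0`.
#' @param N_p Total proteins per cell.
#' @param alpha_p Median protein decay rate, h^-1.
#'
#' @return Translation rates beta_p in proteins per mRNA per hour.
#' @export
translation_rate <- function(s, m,
                             N_p = rate_constants()$N_p,
                             alpha_p = rate_constants()$alpha_p) {
  if (!is.numeric(s) || length(s) == 0 || any(!is.finite(s)) || any(s < 0))
    stop("invalid measurement: footprint RPKM must be finite and non-negative")
  if (length(m) != length(s))
    stop("s and m must have the same length")
  tot <- sum(s)
  if (tot <= 0)
    stop("invalid measurement: all footprint RPKM values are zero")
  if (any(!is.finite(m)) || any(m <= 0 & s > 0))
    stop("invalid measurement: zero mRNA abundance with nonzero footprints")
  stopifnot_positive(N_p = N_p, alpha_p = alpha_p)
  out <- (N_p * alpha_p / m) * (s / tot)
  out[s == 0] <- 0
  out
}

#' Steady-state protein abundance from rates
#'
#' `p = beta_m * beta_p / (alpha_m * alpha_p)`: proteins per cell produced
#' when transcription, translation and the two decay processes balance.
#'
#' @param beta_m Transcription rate, mRNA/h.
#' @param beta_p Translation rate, proteins per mRNA per hour.
#' @param alpha_m,alpha_p Decay rates in h^-1 (medians by default).
#'
#' @return Protein copies per cell.
#' @examples
#' protein_abundance(5.10, 1.34)  # rates equal to decay constants -> 1
#' @export
protein_abundance <- function(beta_m, beta_p,
                              alpha_m = rate_constants()$alpha_m,
                              alpha_p = rate_constants()$alpha_p) {
  stopifnot_positive(beta_m = beta_m, beta_p = beta_p,
                     alpha_m = alpha_m, alpha_p = alpha_p)
  beta_m * beta_p / (alpha_m * alpha_p)
}

#' Total decay rate from an active decay constant
#'
#' Experimental decay constants often quantify active degradation only;
#' in a growing cell, dilution at rate `log(2)` per division time adds to
#' it.  `T_div` is given in minutes and converted to hours internally.
#'
#' @param gamma Active decay constant, h^-1 (>= 0).
#' @param T_div Cell division time in minutes.
#'
#' @return Total decay rate `gamma + log(2) / (T_div / 60)` in h^-1.
#' @export
decay_with_dilution <- function(gamma, T_div = rate_constants()$T_div) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma < 0))
    stop("gamma must be finite and non-negative")
  stopifnot_positive(T_div = T_div)
  gamma + log(2) / (T_div / 60)
}
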