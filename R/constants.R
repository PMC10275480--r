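#' Cell-biological constants for budding yeast expression models
#'
#' Bundles the constants used throughout the package: transcriptome and
#' proteome sizes, median decay rates, the maximal growth rate, the
#' expression-noise floor, the per-nucleotide cost of transcription and the
#' bounds of the noise-sensitivity parameter.  Values describe
#' *Saccharomyces cerevisiae* in exponential growth on rich medium; any
#' entry can be overridden by name.
#'
#' @param ... Named overrides for individual constants.
#'
#' @return An object of class `rate_constants`, a named list with entries:
#' \describe{
#'   \item{N_m}{transcripts per cell (60 000).}
#'   \item{N_p}{proteins per cell (1.1e8).}
#'   \item{alpha_m}{median mRNA decay rate, h^-1 (5.10); includes dilution
#'     by growth.}
#'   \item{alpha_p}{median protein decay rate, h^-1 (1.34).}
#'   \item{mu}{maximal growth rate, h^-1 (0.42); fitness at the expression
#'     optimum.}
#'   \item{cv0}{noise floor: minimal coefficient of variation of protein
#'     abundance in an isogenic population (0.1).}
#'   \item{l_m}{median pre-mRNA length, nt (1350).}
#'   \item{c_m}{transcription cost per nucleotide, nt^-1 (1.2e-9), under
#'     the assumption that transcriptional resources are limiting.}
#'   \item{T_div}{cell division time, minutes (99); sets the dilution term
#'     of decay rates.}
#'   \item{Q_max}{theoretical maximum of the noise-sensitivity parameter
#'     (about 6.8588e-6).}
#'   \item{delta_opt}{post-duplication optimum as a multiple of the
#'     ancestral protein-abundance optimum (1.87).}
#' }
#'
#' @examples
#' cs <- rate_constants()
#' cs$alpha_m
#' rate_constants(alpha_m = 6.2)$alpha_m
#' @export
rate_constants <- function(...) {
  cs <- list(
    N_m       = 60000,
    N_p       = 1.1e8,
    alpha_m   = 5.10,
    alpha_p   = 1.34,
    mu        = 0.42,
    cv0       = 0.1,
    l_m       = 1350,
    c_m       = 1.2e-9,
    T_div     = 99,
    Q_max     = 6.8588e-6,
    delta_opt = 1.87
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cs))
    if (length(bad) || is.null(names(override)) || any(names(override) == ""))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    cs[names(override)] <- override
  }
  vals <- unlist(cs)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all constants must be finite and strictly positive")
  if (cs$cv0 >= 1)
    stop("cv0 must be below 1")
  if (cs$delta_opt <= 1 || cs$delta_opt >= 2)
    stop("delta_opt must lie strictly between 1 and 2")
  structure(cs, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Yeast expression-model constants:\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_positive <- function(..., strict = TRUE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) ||
        (strict && any(v <= 0)) || (!strict && any(v < 0)))
      stop(nms[i], " must be ", if (strict) "strictly positive" else "non-negative",
           " and finite", call. = FALSE)
  }
  invisible(TRUE)
}
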