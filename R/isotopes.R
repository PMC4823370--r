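## Natural isotope arithmetic and MID correction for silylated GC-MS fragments.

.ABUNDANCE_VERSION <- "iupac2013-v1"

## Per-element natural isotope abundances by nominal mass shift (M+0, M+1, ...).
## Base-isotope abundance is 1 minus the listed heavy isotopes. Versioned as a
## constant so CorrectionMatrix objects record which table produced them.
.ISOTOPES <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  S  = c(0.95, 0.0075, 0.0425)
)

#' Natural isotope abundance table
#'
#' The per-element isotope abundance vectors (indexed by nominal mass shift)
#' used throughout the package, with the table version identifier.
#'
#' @return named list of numeric abundance vectors with attribute `version`
#' @examples
#' isotopeAbundances()$C
#' @export
isotopeAbundances <- function() {
  structure(.ISOTOPES, version = .ABUNDANCE_VERSION)
}

#' Parse an elemental formula string
#'
#' Parses Hill-style formulas such as `"C11H26NO3Si2"` into a named count
#' vector. An element symbol without a count means one atom. Supported
#' elements: C, H, N, O, Si, S.
#'
#' @param text formula string
#' @return named integer vector of atom counts (an `ElementalFormula`)
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(integer(0))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!length(parts) || nchar(text) != sum(nchar(parts)))
    stop("malformed formula string: '", text, "'")
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    if (!el %in% names(.ISOTOPES))
      stop("unsupported element '", el, "' in formula '", text, "'")
    ntxt <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(ntxt)) as.integer(ntxt) else 1L
    if (is.na(n) || n < 1L) stop("invalid count for element '", el, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

.newPattern <- function(abundance, truncated = TRUE) {
  new("IsotopePattern", abundance = pmax(abundance, 0), truncated = truncated)
}

#' Isotope pattern of n atoms of one element
#'
#' The multinomial distribution of total nominal mass shift over `count`
#' atoms of one element, truncated at shift K.
#'
#' @param element element symbol (C, H, N, O, Si, S)
#' @param count number of atoms (>= 0)
#' @param K maximum retained mass shift
#' @return an [IsotopePattern-class] of length K + 1
#' @examples
#' elementPattern("C", 6, 3)
#' @export
elementPattern <- function(element, count, K) {
  if (!element %in% names(.ISOTOPES)) stop("unknown element '", element, "'")
  stopifnot(count >= 0, K >= 0)
  single <- .ISOTOPES[[element]]
  acc <- c(1, rep(0, K))
  if (count > 0) {
    s <- c(single, rep(0, max(0L, K + 1L - length(single))))[seq_len(K + 1L)]
    for (i in seq_len(count)) acc <- .convolveTrunc(acc, s)
  }
  .newPattern(acc)
}

.convolveTrunc <- function(a, b) {
  K <- length(a) - 1L
  out <- numeric(K + 1L)
  for (i in 0:K) {
    j <- 0:(K - i)
    out[i + j + 1L] <- out[i + j + 1L] + a[i + 1L] * b[j + 1L]
  }
  out
}

#' Convolve two isotope patterns
#'
#' Discrete convolution truncated at the common K. Commutative and
#' associative, with identity `[1, 0, ..., 0]`.
#'
#' @param a,b [IsotopePattern-class] objects of equal length
#' @return their convolution as an [IsotopePattern-class]
#' @export
convolvePatterns <- function(a, b) {
  stopifnot(is(a, "IsotopePattern"), is(b, "IsotopePattern"))
  if (length(a@abundance) != length(b@abundance))
    stop("patterns truncated at different K (lengths ",
         length(a@abundance), " and ", length(b@abundance), ")")
  .newPattern(.convolveTrunc(a@abundance, b@abundance),
              truncated = a@truncated || b@truncated)
}

#' Natural isotope pattern of an elemental formula
#'
#' Convolution of the per-element patterns over all atoms of `f`: the
#' isotope pattern a fully unlabeled fragment presents to the mass
#' spectrometer.
#'
#' @param f an `ElementalFormula` (named counts, as from [parseFormula()]) or
#'   a formula string
#' @param K maximum retained mass shift
#' @return an [IsotopePattern-class]
#' @examples
#' naturalPattern("C6H12O6", 3)
#' @export
naturalPattern <- function(f, K) {
  if (is.character(f)) f <- parseFormula(f)
  acc <- .newPattern(c(1, rep(0, K)))
  for (el in names(f)) acc <- convolvePatterns(acc, elementPattern(el, f[[el]], K))
  acc
}

#' Build a natural-abundance correction matrix for a fragment
#'
#' Column j (j = 0 ... nBackbone) is the natural isotope pattern of the
#' fragment with j of its carbons fixed as 13C: the pattern of the formula
#' minus j carbons, shifted up by j. The remaining backbone carbons keep
#' their natural 13C abundance, as do all derivatization-group atoms (Si
#' isotopes dominate the M+1/M+2 background of silylated fragments).
#'
#' @param fragment `ElementalFormula` or formula string of the observed
#'   (derivatized) fragment ion
#' @param nBackbone number of tracer-traceable backbone carbons
#' @param K maximum observed shift; default `nBackbone + 3` captures the
#'   Si-driven tail without requiring the full scan range
#' @param fragmentId identifier stored in the object
#' @return a [CorrectionMatrix-class] of dimension (K+1) x (nBackbone+1)
#' @examples
#' buildCorrectionMatrix("C11H26NO2Si2", 3, fragmentId = "alanine_M-57")
#' @export
buildCorrectionMatrix <- function(fragment, nBackbone, K = nBackbone + 3L,
                                  fragmentId = "fragment") {
  if (is.character(fragment)) fragment <- parseFormula(fragment)
  nBackbone <- as.integer(nBackbone)
  K <- as.integer(K)
  nC <- if ("C" %in% names(fragment)) fragment[["C"]] else 0L
  if (nBackbone > nC)
    stop("nBackbone (", nBackbone, ") exceeds fragment carbon count (", nC, ")")
  if (K < nBackbone) stop("K must be >= nBackbone")
  m <- matrix(0, nrow = K + 1L, ncol = nBackbone + 1L,
              dimnames = list(paste0("M+", 0:K), paste0("x", 0:nBackbone)))
  for (j in 0:nBackbone) {
    fj <- fragment
    fj[["C"]] <- nC - j
    if (fj[["C"]] == 0L) fj <- fj[names(fj) != "C"]
    pat <- naturalPattern(fj, K - j)@abundance
    m[(j + 1L):(K + 1L), j + 1L] <- pat
  }
  new("CorrectionMatrix", matrix = m, fragment = fragmentId,
      abundanceVersion = .ABUNDANCE_VERSION)
}

#' Correct a measured isotopologue intensity vector for natural abundance
#'
#' Solves the non-negative least squares problem `measured ~ cm %*% x` and
#' renormalizes x to the simplex. NNLS is used rather than matrix inversion
#' because inversion can return negative fractions on noisy data.
#'
#' @param measured raw intensity vector over M+0 ... M+K (any scale)
#' @param cm a [CorrectionMatrix-class] with K+1 rows
#' @param metabolite,fragment identifiers stored on the result
#' @return a [MIDVector-class]; the NNLS residual norm (on the normalized
#'   intensity scale) is attached as `attr(x, "residual")`
#' @examples
#' cm <- buildCorrectionMatrix("C6H12O6", 3)
#' x <- c(0.2, 0.3, 0.1, 0.4)
#' correctMid(correctionMatrix(cm) %*% x, cm)
#' @export
correctMid <- function(measured, cm, metabolite = "metabolite",
                       fragment = cm@fragment) {
  stopifnot(is(cm, "CorrectionMatrix"))
  measured <- as.numeric(measured)
  A <- cm@matrix
  if (length(measured) != nrow(A))
    stop("measured vector has length ", length(measured),
         " but correction matrix has ", nrow(A), " rows")
  if (any(!is.finite(measured)) || any(measured < 0))
    stop("measured intensities must be finite and >= 0")
  tot <- sum(measured)
  if (tot == 0) stop("all-zero intensity vector for ", metabolite, "/", fragment)
  b <- measured / tot
  fit <- pracma::lsqnonneg(A, b)
  x <- fit$x
  if (sum(x) == 0) stop("NNLS returned the zero solution for ", metabolite)
  resid <- sqrt(sum((A %*% x - b)^2))
  out <- new("MIDVector", metabolite = metabolite, fragment = fragment,
             nBackbone = ncol(A) - 1L, fractions = x / sum(x))
  attr(out, "residual") <- resid
  out
}

#' Carbon-atom fractional enrichment of a MID
#'
#' Default definition: the fraction of backbone carbon atoms that are 13C,
#' `sum(i * m_i) / n`. The alternate molecule-level convention `1 - M+0`
#' (fraction of molecules carrying any label) is available via
#' `method = "labeled-fraction"`.
#'
#' @param mid a [MIDVector-class] or a numeric simplex vector
#' @param method "atom" (default) or "labeled-fraction"
#' @return enrichment in `[0, 1]`
#' @examples
#' fractionalEnrichment(c(0.5, 0, 0, 0.5))
#' @export
fractionalEnrichment <- function(mid, method = c("atom", "labeled-fraction")) {
  method <- match.arg(method)
  f <- if (is(mid, "MIDVector")) mid@fractions else as.numeric(mid)
  n <- length(f) - 1L
  if (n == 0L) stop("fragment has no backbone carbons; enrichment undefined")
  f <- f / sum(f)
  if (method == "atom") sum((0:n) * f) / n else 1 - f[1L]
}
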