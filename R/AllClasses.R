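#' @import methods
NULL

#' IsotopePattern: abundances over nominal mass shifts
#'
#' A vector of isotope abundances indexed by nominal mass shift M+0 ... M+K,
#' as produced by combining the natural isotope distributions of the atoms in
#' an elemental formula. Patterns are truncated at K, so entries sum to at
#' most 1; the mass lost beyond K is recorded implicitly by the shortfall.
#'
#' @slot abundance numeric vector, entry i+1 is the abundance at shift M+i
#' @slot truncated logical, TRUE when mass beyond K was cut off
#' @export
setClass("IsotopePattern",
  representation(abundance = "numeric", truncated = "logical"),
  validity = function(object) {
    a <- object@abundance
    if (length(a) < 1L) return("abundance must have at least one entry (M+0)")
    if (any(!is.finite(a))) return("abundance entries must be finite")
    if (any(a < -1e-12)) return("abundance entries must be >= 0")
    if (sum(a) > 1 + 1e-12) return("abundances sum to more than 1")
    TRUE
  }
)

#' MIDVector: mass isotopomer distribution of one metabolite fragment
#'
#' Fractions of a metabolite fragment at mass shifts M+0 ... M+n over the
#' tracer-traceable backbone carbons, after natural-abundance correction (or
#' as simulator ground truth). Always on the simplex.
#'
#' @slot metabolite metabolite identifier
#' @slot fragment fragment identifier (e.g. the derivatized M-57 ion)
#' @slot nBackbone number of tracer-traceable backbone carbons
#' @slot fractions numeric vector of length nBackbone + 1, sums to 1
#' @export
setClass("MIDVector",
  representation(metabolite = "character", fragment = "character",
                 nBackbone = "integer", fractions = "numeric"),
  validity = function(object) {
    n <- object@nBackbone
    if (length(n) != 1L || is.na(n) || n < 0L) return("nBackbone must be a single non-negative integer")
    f <- object@fractions
    if (length(f) != n + 1L) return(sprintf("fractions must have length nBackbone + 1 = %d", n + 1L))
    if (any(!is.finite(f))) return("fractions must be finite")
    if (any(f < -1e-12)) return("fractions must be >= 0")
    if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 (tolerance 1e-9)")
    TRUE
  }
)

#' CorrectionMatrix: backbone labeling states to observable isotopologues
#'
#' Column j (j = 0 ... nBackbone) holds the isotope pattern observed for the
#' fragment when exactly j backbone carbons are 13C: the natural pattern of
#' the remaining atoms (including derivatization Si/C/H/N/O) shifted by j.
#' Multiplying by a true MID gives the expected measured intensity pattern;
#' non-negative least squares inverts it.
#'
#' @slot matrix numeric matrix, (K+1) x (nBackbone+1)
#' @slot fragment fragment identifier
#' @slot abundanceVersion identifier of the isotope abundance table used
#' @export
setClass("CorrectionMatrix",
  representation(matrix = "matrix", fragment = "character",
                 abundanceVersion = "character"),
  validity = function(object) {
    m <- object@matrix
    if (any(!is.finite(m))) return("matrix entries must be finite")
    if (any(m < -1e-12)) return("matrix entries must be >= 0")
    if (any(colSums(m) > 1 + 1e-9)) return("each column must sum to <= 1 (truncated natural pattern)")
    TRUE
  }
)

#' CarbonPool: positional 13C label-state distribution of one metabolite
#'
#' A probability distribution over all 2^n binary labeling vectors of an
#' n-carbon metabolite pool. State s (0-based) labels carbon i when bit i of
#' s is set (carbon 1 = least significant bit).
#'
#' @slot name pool name
#' @slot nCarbons number of carbons (<= 6 so state spaces stay <= 64)
#' @slot probs numeric vector of length 2^nCarbons, sums to 1
#' @export
setClass("CarbonPool",
  representation(name = "character", nCarbons = "integer", probs = "numeric"),
  validity = function(object) {
    n <- object@nCarbons
    if (length(n) != 1L || is.na(n) || n < 1L) return("nCarbons must be a positive integer")
    if (n > 6L) return("nCarbons must be <= 6")
    p <- object@probs
    if (length(p) != 2L^n) return(sprintf("probs must have length 2^nCarbons = %d", 2L^n))
    if (any(!is.finite(p)) || any(p < -1e-12)) return("probs must be finite and >= 0")
    if (abs(sum(p) - 1) > 1e-9) return("probs must sum to 1 (tolerance 1e-9)")
    TRUE
  }
)

#' TracerNetwork: atom-mapped reaction network for label propagation
#'
#' Pools, atom-mapped reactions and fixed-label input pools for the exact
#' positional 13C propagation. Each reaction maps every product carbon to
#' exactly one substrate carbon or to an external unlabeled source (CO2),
#' and lists the substrate carbons released as CO2 so that label is
#' conserved per application.
#'
#' @slot poolCarbons named integer vector, carbons per pool
#' @slot reactions list of reactions (see [atomMappedReaction()])
#' @slot inputs character vector of pool names whose distributions are fixed
#' @slot symmetric character vector of pools scrambled end-to-end
#'   (succinate, fumarate)
#' @slot updateOrder character vector, canonical Gauss-Seidel sweep order
#' @export
setClass("TracerNetwork",
  representation(poolCarbons = "integer", reactions = "list",
                 inputs = "character", symmetric = "character",
                 updateOrder = "character"),
  validity = function(object) {
    pc <- object@poolCarbons
    if (is.null(names(pc)) || any(names(pc) == "")) return("poolCarbons must be named")
    if (any(pc < 1L) || any(pc > 6L)) return("pool carbon counts must be in 1..6")
    bad <- setdiff(c(object@inputs, object@symmetric, object@updateOrder), names(pc))
    if (length(bad)) return(paste("unknown pools:", paste(bad, collapse = ", ")))
    for (rx in object@reactions) {
      msg <- .validateReaction(rx, pc)
      if (!isTRUE(msg)) return(msg)
    }
    TRUE
  }
)

#' PathwayConfig: tracer choice and flux splits for label propagation
#'
#' Fractions are dimensionless flux splits in [0, 1]; at each branch point
#' the producing routes of a pool are weighted so they sum to 1.
#'
#' @slot tracer "glucose" ([U-13C6]glucose) or "glutamine" ([U-13C5]glutamine)
#' @slot g fraction of the pyruvate pool supplied by tracer glucose via
#'   glycolysis (the remainder is unlabeled)
#' @slot q fraction of medium glutamine feeding glutaminolysis that is tracer
#' @slot pcFraction fraction of oxaloacetate production from pyruvate
#'   carboxylase (vs malate dehydrogenase)
#' @slot oxGln fraction of alpha-ketoglutarate production from glutamate
#'   (oxidative glutamine entry) vs isocitrate dehydrogenase
#' @slot redIdh fraction of citrate production from reductive carboxylation
#'   of alpha-ketoglutarate (vs citrate synthase)
#' @slot gsFraction fraction of the intracellular glutamine pool made by
#'   glutamine synthetase (vs medium uptake)
#' @slot gluFromGln fraction of glutamate from glutaminase (vs transamination
#'   of alpha-ketoglutarate)
#' @slot serSynth fraction of serine synthesized de novo from 3-phosphoglycerate
#' @slot purity 13C atom purity per labeled tracer position
#' @slot turns integer turn limit (Gauss-Seidel sweeps), or NA for steady state
#' @slot tol convergence tolerance for steady-state mode
#' @slot maxIter iteration cap for steady-state mode
#' @export
setClass("PathwayConfig",
  representation(tracer = "character", g = "numeric", q = "numeric",
                 pcFraction = "numeric", oxGln = "numeric", redIdh = "numeric",
                 gsFraction = "numeric", gluFromGln = "numeric",
                 serSynth = "numeric", purity = "numeric",
                 turns = "integer", tol = "numeric", maxIter = "integer"),
  validity = function(object) {
    if (!object@tracer %in% c("glucose", "glutamine"))
      return("tracer must be 'glucose' or 'glutamine'")
    fr <- c(g = object@g, q = object@q, pcFraction = object@pcFraction,
            oxGln = object@oxGln, redIdh = object@redIdh,
            gsFraction = object@gsFraction, gluFromGln = object@gluFromGln,
            serSynth = object@serSynth, purity = object@purity)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
      return(paste("fractions must lie in [0, 1]:",
                   paste(names(fr)[!is.finite(fr) | fr < 0 | fr > 1], collapse = ", ")))
    if (!is.na(object@turns) && object@turns < 1L) return("turns must be >= 1")
    if (object@tol <= 0) return("tol must be > 0")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    TRUE
  }
)

#' StudyConfig: true parameters of the synthetic three-line study
#'
#' Ground-truth parameters per cell line and condition, from which the
#' synthetic-data generator draws reproducible datasets. Every numeric
#' default in [defaultStudyConfig()] carries an annotation string recording
#' the reported quantity it encodes.
#'
#' @slot lines cell line names (reference line first)
#' @slot mediaExchange data.frame: line, metabolite, exchange_umol_mg,
#'   annotation (negative = consumed)
#' @slot freshMedia named numeric, fresh-medium concentrations (mM)
#' @slot sourceFractions data.frame: line, metabolite, tracer, fraction,
#'   annotation - tracer-derived fraction at the NMR-observed carbon
#' @slot enrichments data.frame: line, tracer, metabolite, enrichment,
#'   annotation - true carbon-atom fractional enrichment of the pool
#' @slot poolPercent data.frame: metabolite, line, percent, annotation -
#'   pool size as percent of the reference line
#' @slot nMedia,nMid,nPool replicate counts per assay family
#' @slot cvIntensity,cvProtein multiplicative noise CVs
#' @slot volumeMl medium volume per well (mL)
#' @slot proteinMg mean protein per well (mg)
#' @slot tracerPurity 13C atom purity of the tracers
#' @slot tracerConcMm named numeric, tracer concentrations (mM)
#' @export
setClass("StudyConfig",
  representation(lines = "character", mediaExchange = "data.frame",
                 freshMedia = "numeric", sourceFractions = "data.frame",
                 enrichments = "data.frame", poolPercent = "data.frame",
                 nMedia = "integer", nMid = "integer", nPool = "integer",
                 cvIntensity = "numeric", cvProtein = "numeric",
                 volumeMl = "numeric", proteinMg = "numeric",
                 tracerPurity = "numeric", tracerConcMm = "numeric"),
  validity = function(object) {
    if (length(object@lines) < 2L) return("need at least two cell lines")
    if (any(c(object@nMedia, object@nMid, object@nPool) < 2L))
      return("replicate counts must be >= 2")
    if (any(c(object@cvIntensity, object@cvProtein) < 0))
      return("noise CVs must be >= 0")
    if (object@volumeMl <= 0 || object@proteinMg <= 0)
      return("volumeMl and proteinMg must be > 0")
    if (object@tracerPurity < 0 || object@tracerPurity > 1)
      return("tracerPurity must be in [0, 1]")
    for (nm in c("mediaExchange", "sourceFractions", "enrichments", "poolPercent")) {
      df <- slot(object, nm)
      if (!"line" %in% names(df)) next
      bad <- setdiff(unique(df$line), object@lines)
      if (length(bad)) return(sprintf("%s refers to undeclared lines: %s",
                                      nm, paste(bad, collapse = ", ")))
    }
    TRUE
  }
)

setMethod("show", "IsotopePattern", function(object) {
  a <- object@abundance
  cat(sprintf("IsotopePattern over M+0..M+%d%s\n", length(a) - 1L,
              if (object@truncated) " (truncated)" else ""))
  print(round(stats::setNames(a, paste0("M+", seq_along(a) - 1L)), 6))
})

setMethod("show", "MIDVector", function(object) {
  cat(sprintf("MIDVector: %s [%s], %d backbone carbons\n",
              object@metabolite, object@fragment, object@nBackbone))
  print(round(stats::setNames(object@fractions,
                              paste0("M+", 0:object@nBackbone)), 6))
})

setMethod("show", "CorrectionMatrix", function(object) {
  d <- dim(object@matrix)
  cat(sprintf("CorrectionMatrix for fragment %s: %d observed shifts x %d labeling states (%s)\n",
              object@fragment, d[1], d[2], object@abundanceVersion))
})

setMethod("show", "CarbonPool", function(object) {
  cat(sprintf("CarbonPool %s (%d carbons)\n", object@name, object@nCarbons))
  m <- midOf(object)
  print(round(stats::setNames(m@fractions, paste0("M+", 0:m@nBackbone)), 6))
})

setMethod("show", "TracerNetwork", function(object) {
  cat(sprintf("TracerNetwork: %d pools, %d reactions; inputs: %s; symmetric: %s\n",
              length(object@poolCarbons), length(object@reactions),
              paste(object@inputs, collapse = ", "),
              paste(object@symmetric, collapse = ", ")))
})

setMethod("show", "PathwayConfig", function(object) {
  cat(sprintf(paste0("PathwayConfig: tracer=%s g=%.2f q=%.2f PC=%.2f oxGln=%.2f ",
                     "redIDH=%.2f GS=%.2f gluFromGln=%.2f serSynth=%.2f purity=%.3f %s\n"),
              object@tracer, object@g, object@q, object@pcFraction, object@oxGln,
              object@redIdh, object@gsFraction, object@gluFromGln, object@serSynth,
              object@purity,
              if (is.na(object@turns)) "steady-state" else sprintf("turns=%d", object@turns)))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(paste0("StudyConfig: lines %s; n(media)=%d n(MID)=%d n(pool)=%d; ",
                     "CV intensity %.0f%%, protein %.0f%%\n"),
              paste(object@lines, collapse = "/"), object@nMedia, object@nMid,
              object@nPool, 100 * object@cvIntensity, 100 * object@cvProtein))
})
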