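## Atom-mapped reaction network for exact positional 13C label propagation.
##
## Each reaction maps every product carbon to exactly one substrate carbon or
## to an external unlabeled source ("EXT", e.g. CO2 fixed by pyruvate
## carboxylase or reductive IDH); substrate carbons lost as CO2 are listed in
## `release` so label is conserved per application. The CO2 pool is fixed
## unlabeled: the culture is an open system and 13CO2 refixation is not
## modeled except through the explicit EXT carbons of PC / reductive IDH.

#' Construct an atom-mapped reaction
#'
#' @param name reaction name
#' @param product product pool name
#' @param substrates character vector of substrate pool names (may be empty
#'   for pure external supply)
#' @param map data.frame with columns `prodCarbon`, `source` (a substrate
#'   name or `"EXT"` for an external unlabeled carbon), `sourceCarbon`
#'   (NA for EXT)
#' @param release data.frame with columns `source`, `sourceCarbon`: substrate
#'   carbons released as CO2 (or to the one-carbon pool)
#' @param weight relative flux weight among the producers of `product`
#' @return a reaction (plain list, validated when the network is built)
#' @export
atomMappedReaction <- function(name, product, substrates, map,
                               release = NULL, weight = 1) {
  if (is.null(release))
    release <- data.frame(source = character(0), sourceCarbon = integer(0))
  list(name = name, product = product, substrates = substrates,
       map = map, release = release, weight = weight)
}

.validateReaction <- function(rx, poolCarbons) {
  need <- c("name", "product", "substrates", "map", "release", "weight")
  if (!all(need %in% names(rx))) return(paste("reaction missing fields:", rx$name))
  if (!rx$product %in% names(poolCarbons))
    return(paste("unknown product pool:", rx$product))
  bad <- setdiff(rx$substrates, names(poolCarbons))
  if (length(bad)) return(paste("unknown substrate pools:", paste(bad, collapse = ", ")))
  np <- poolCarbons[[rx$product]]
  m <- rx$map
  if (!setequal(m$prodCarbon, seq_len(np)) || anyDuplicated(m$prodCarbon))
    return(sprintf("reaction %s: carbon map must cover each product carbon exactly once", rx$name))
  for (i in seq_len(nrow(m))) {
    src <- m$source[i]
    if (src == "EXT") next
    if (!src %in% rx$substrates)
      return(sprintf("reaction %s: map source %s not a substrate", rx$name, src))
    sc <- m$sourceCarbon[i]
    if (is.na(sc) || sc < 1 || sc > poolCarbons[[src]])
      return(sprintf("reaction %s: bad source carbon for %s", rx$name, src))
  }
  ## injectivity: a substrate carbon feeds at most one product carbon
  used <- m[m$source != "EXT", c("source", "sourceCarbon")]
  used <- rbind(used, rx$release[, c("source", "sourceCarbon")])
  if (anyDuplicated(used))
    return(sprintf("reaction %s: substrate carbon mapped twice", rx$name))
  TRUE
}

.cmap <- function(prod, source, srcCarbons) {
  data.frame(prodCarbon = prod, source = source, sourceCarbon = srcCarbons,
             stringsAsFactors = FALSE)
}

#' Build the default glycolysis / TCA / amino-acid tracer network
#'
#' Lumped glycolysis (glucose C1-C3 and C4-C6 halves each yielding a triose
#' with the standard carbon inversion of the upper half), the
#' 3-phosphoglycerate -> serine -> glycine branch, pyruvate dehydrogenase
#' (CO2 from pyruvate C1), pyruvate carboxylase (CO2 fixed as the C4
#' carboxyl of oxaloacetate), citrate synthase, aconitase/isocitrate
#' dehydrogenase (CO2 taken from the oxaloacetate-derived C4 carboxyl, per
#' aconitase stereospecificity), alpha-ketoglutarate dehydrogenase (CO2 from
#' alpha-ketoglutarate C1), the symmetric succinate/fumarate segment, malate
#' dehydrogenase, glutaminase, glutamate/alpha-ketoglutarate transamination,
#' glutamine synthetase, reductive carboxylation of alpha-ketoglutarate,
#' lactate dehydrogenase, alanine transaminase and aspartate transaminase.
#'
#' Carbon conventions: oxaloacetate C1 and C4 are the carboxyls (C4 the one
#' lost at IDH after condensation, C1 the one lost at the subsequent
#' alpha-ketoglutarate dehydrogenase step); citrate C1-C4 derive from
#' oxaloacetate and C5-C6 from acetyl-CoA; alpha-ketoglutarate C4-C5 derive
#' from acetyl-CoA.
#'
#' @return a [TracerNetwork-class]
#' @export
buildDefaultNetwork <- function() {
  poolCarbons <- c(
    glucose = 6L, glnMedium = 5L,
    PG3 = 3L, PEP = 3L, pyruvate = 3L, lactate = 3L, alanine = 3L,
    serine = 3L, glycine = 2L, acetylCoA = 2L,
    OAA = 4L, citrate = 6L, isocitrate = 6L, AKG = 5L,
    succinate = 4L, fumarate = 4L, malate = 4L,
    glutamate = 5L, glutamine = 5L, aspartate = 4L
  )
  rx <- list(
    ## upper glycolysis: the C1-C3 triose is inverted, C4-C6 maps directly
    atomMappedReaction("glycolysis_c123", "PG3", "glucose",
      .cmap(1:3, "glucose", c(3L, 2L, 1L)), weight = 0.5),
    atomMappedReaction("glycolysis_c456", "PG3", "glucose",
      .cmap(1:3, "glucose", c(4L, 5L, 6L)), weight = 0.5),
    atomMappedReaction("enolase", "PEP", "PG3", .cmap(1:3, "PG3", 1:3)),
    atomMappedReaction("pyruvateKinase", "pyruvate", "PEP", .cmap(1:3, "PEP", 1:3)),
    atomMappedReaction("pyruvateExchange", "pyruvate", character(0),
      .cmap(1:3, "EXT", NA_integer_)),
    atomMappedReaction("ldh", "lactate", "pyruvate", .cmap(1:3, "pyruvate", 1:3)),
    atomMappedReaction("alaTransaminase", "alanine", "pyruvate",
      .cmap(1:3, "pyruvate", 1:3)),
    atomMappedReaction("serineSynthesis", "serine", "PG3", .cmap(1:3, "PG3", 1:3)),
    atomMappedReaction("serineImport", "serine", character(0),
      .cmap(1:3, "EXT", NA_integer_)),
    ## SHMT: serine C3 leaves to the one-carbon pool
    atomMappedReaction("shmt", "glycine", "serine", .cmap(1:2, "serine", 1:2),
      release = data.frame(source = "serine", sourceCarbon = 3L)),
    atomMappedReaction("pdh", "acetylCoA", "pyruvate",
      .cmap(1:2, "pyruvate", 2:3),
      release = data.frame(source = "pyruvate", sourceCarbon = 1L)),
    atomMappedReaction("pyruvateCarboxylase", "OAA", "pyruvate",
      rbind(.cmap(1:3, "pyruvate", 1:3), .cmap(4L, "EXT", NA_integer_))),
    atomMappedReaction("mdh", "OAA", "malate", .cmap(1:4, "malate", 1:4)),
    atomMappedReaction("citrateSynthase", "citrate", c("acetylCoA", "OAA"),
      rbind(.cmap(1:4, "OAA", 1:4), .cmap(5:6, "acetylCoA", 1:2))),
    atomMappedReaction("reductiveIdh", "citrate", "AKG",
      rbind(.cmap(1:3, "AKG", 1:3), .cmap(4L, "EXT", NA_integer_),
            .cmap(5:6, "AKG", 4:5))),
    atomMappedReaction("aconitase", "isocitrate", "citrate",
      .cmap(1:6, "citrate", 1:6)),
    atomMappedReaction("idh", "AKG", "isocitrate",
      rbind(.cmap(1:3, "isocitrate", 1:3), .cmap(4:5, "isocitrate", 5:6)),
      release = data.frame(source = "isocitrate", sourceCarbon = 4L)),
    atomMappedReaction("gdhTransaminase", "AKG", "glutamate",
      .cmap(1:5, "glutamate", 1:5)),
    atomMappedReaction("akgdh", "succinate", "AKG", .cmap(1:4, "AKG", 2:5),
      release = data.frame(source = "AKG", sourceCarbon = 1L)),
    atomMappedReaction("sdh", "fumarate", "succinate", .cmap(1:4, "succinate", 1:4)),
    atomMappedReaction("fumarase", "malate", "fumarate", .cmap(1:4, "fumarate", 1:4)),
    atomMappedReaction("glutaminase", "glutamate", "glutamine",
      .cmap(1:5, "glutamine", 1:5)),
    atomMappedReaction("gluTransaminase", "glutamate", "AKG", .cmap(1:5, "AKG", 1:5)),
    atomMappedReaction("glnUptake", "glutamine", "glnMedium",
      .cmap(1:5, "glnMedium", 1:5)),
    atomMappedReaction("glutamineSynthetase", "glutamine", "glutamate",
      .cmap(1:5, "glutamate", 1:5)),
    atomMappedReaction("aspTransaminase", "aspartate", "OAA", .cmap(1:4, "OAA", 1:4))
  )
  updateOrder <- c("PG3", "PEP", "serine", "glycine", "pyruvate", "lactate",
                   "alanine", "acetylCoA", "glutamine", "glutamate", "AKG",
                   "succinate", "fumarate", "malate", "OAA", "citrate",
                   "isocitrate", "aspartate")
  new("TracerNetwork", poolCarbons = poolCarbons, reactions = rx,
      inputs = c("glucose", "glnMedium"),
      symmetric = c("succinate", "fumarate"),
      updateOrder = updateOrder)
}

#' Construct a PathwayConfig
#'
#' @param tracer "glucose" or "glutamine"
#' @param g fraction of pyruvate supplied by tracer glucose via glycolysis
#' @param q fraction of medium glutamine that is tracer
#' @param pcFraction fraction of oxaloacetate production via pyruvate
#'   carboxylase
#' @param oxGln fraction of alpha-ketoglutarate production from glutamate
#' @param redIdh fraction of citrate production via reductive carboxylation
#' @param gsFraction fraction of intracellular glutamine from glutamine
#'   synthetase
#' @param gluFromGln fraction of glutamate from glutaminase
#' @param serSynth fraction of serine synthesized from 3-phosphoglycerate
#' @param purity 13C atom purity per labeled tracer position
#' @param turns number of propagation turns (Gauss-Seidel sweeps in the
#'   canonical metabolic order), or NA (default) for steady state
#' @param tol steady-state convergence tolerance (max absolute change)
#' @param maxIter steady-state iteration cap
#' @return a [PathwayConfig-class]
#' @export
pathwayConfig <- function(tracer = "glucose", g = 1, q = 1, pcFraction = 0,
                          oxGln = 0, redIdh = 0, gsFraction = 0,
                          gluFromGln = 1, serSynth = 1, purity = 1,
                          turns = NA_integer_, tol = 1e-12, maxIter = 500L) {
  new("PathwayConfig", tracer = tracer, g = g, q = q, pcFraction = pcFraction,
      oxGln = oxGln, redIdh = redIdh, gsFraction = gsFraction,
      gluFromGln = gluFromGln, serSynth = serSynth, purity = purity,
      turns = as.integer(turns), tol = tol, maxIter = as.integer(maxIter))
}
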