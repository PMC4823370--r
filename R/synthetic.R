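## Seeded synthetic three-line study generator.
##
## Ground truths are the reported study values (annotated per entry); noise
## is multiplicative mean-preserving lognormal so that pipeline estimates
## are unbiased for the configured truths as CV -> 0.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

## mean-preserving multiplicative lognormal noise factors
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.df <- function(...) data.frame(..., stringsAsFactors = FALSE)

#' Default study configuration with the reported ground truths
#'
#' Returns a [StudyConfig-class] whose true parameters equal the reported
#' values of the three-line NSC-34 / WT-NSC / G93A-NSC serum-deprivation
#' study: media exchange contrasts (e.g. medium lactate +79% WT-NSC and
#' +161% G93A-NSC vs NSC-34, hence +46% G93A vs WT; glucose consumption
#' +37% in G93A-NSC vs NSC-34), NMR source fractions (~80% of lactate and
#' alanine from glucose), 13C fractional enrichments (~90% PEP, ~60%
#' pyruvate/lactate/alanine in NSC-34 rising to ~80% in the transfected
#' lines; glutamine 32/18/24% from glucose and 39/67/56% from glutamine),
#' and pool sizes as percent of NSC-34 (e.g. serine +164% in WT-NSC).
#' Quantities reported only as ranges are fixed at in-range values. Every
#' entry carries an annotation naming the reported quantity it encodes.
#' Replicate counts follow the assay families: media n = 4, MIDs n = 5,
#' pools n = 6.
#'
#' @return a [StudyConfig-class]
#' @export
defaultStudyConfig <- function() {
  lines <- c("NSC-34", "WT-NSC", "G93A-NSC")

  media <- rbind(
    .df(line = lines, metabolite = "glucose",
        exchange_umol_mg = c(-60, -72, -60 * 1.37),
        annotation = c("baseline glucose consumption, serum-free",
                       "WT-NSC glucose consumption intermediate",
                       "reported +37% glucose consumption G93A-NSC vs NSC-34")),
    .df(line = lines, metabolite = "lactate",
        exchange_umol_mg = c(55, 55 * 1.79, 55 * 1.79 * 1.46),
        annotation = c("baseline medium lactate release, serum-free",
                       "reported +79% medium lactate WT-NSC vs NSC-34, serum-free",
                       "reported +46% medium lactate G93A-NSC vs WT-NSC, serum-free")),
    .df(line = lines, metabolite = "alanine",
        exchange_umol_mg = c(1.5, 1.5 * 2.97, 1.5 * 2.97 * 2.09),
        annotation = c("baseline alanine release",
                       "reported +197% alanine release WT-NSC vs NSC-34",
                       "reported +109% alanine release G93A-NSC vs WT-NSC")),
    .df(line = lines, metabolite = "formate",
        exchange_umol_mg = c(1.0, 1.0 * 2.37, 1.0 * 2.37 * 1.29),
        annotation = c("baseline formate release",
                       "reported +137% formate release WT-NSC vs NSC-34",
                       "reported +29% formate release G93A-NSC vs WT-NSC")),
    .df(line = lines, metabolite = "glutamine",
        exchange_umol_mg = c(-4, -4, -4),
        ## 1 mM glutamine in 2 mL bounds consumption at 10 umol/mg for
        ## 0.2 mg protein; -4 leaves a measurable residual concentration
        annotation = rep("glutamine consumption, no significant line difference", 3)),
    .df(line = lines, metabolite = "glutamate",
        exchange_umol_mg = c(4.0, 4.0 * 0.46, 4.0 * 0.46 * 1.41),
        annotation = c("baseline glutamate release",
                       "reported -54% glutamate release WT-NSC vs NSC-34",
                       "reported +41% glutamate release G93A-NSC vs WT-NSC")),
    .df(line = lines, metabolite = "pyruvate",
        exchange_umol_mg = c(-3, -3, -3),
        annotation = rep("minor pyruvate consumption from the 1 mM medium supplement", 3))
  )

  fresh <- c(glucose = 25, glutamine = 1, pyruvate = 1,
             lactate = 0, alanine = 0, formate = 0, glutamate = 0)

  src <- rbind(
    .df(line = rep(lines, 2),
        metabolite = rep(c("lactate", "alanine"), each = 3),
        tracer = "glucose", fraction = 0.80,
        annotation = "reported ~80% of lactate/alanine glucose-derived, all lines"),
    .df(line = rep(lines, 2),
        metabolite = rep(c("lactate", "alanine"), each = 3),
        tracer = "glutamine", fraction = 0.04,
        annotation = "minor glutamine-derived fraction of lactate/alanine")
  )

  enrTable <- function(tracer, metabolite, e, ann)
    .df(line = lines, tracer = tracer, metabolite = metabolite,
        enrichment = e, annotation = ann)
  enr <- rbind(
    enrTable("glucose", "PEP", c(0.90, 0.90, 0.90),
             rep("reported ~90% PEP glucose-derived, all lines", 3)),
    enrTable("glucose", "pyruvate", c(0.60, 0.80, 0.80),
             c("reported ~60% pyruvate glucose-derived, NSC-34",
               rep("reported ~80% pyruvate glucose-derived, transfected lines", 2))),
    enrTable("glucose", "lactate", c(0.60, 0.80, 0.80),
             c("reported ~60% lactate glucose-derived, NSC-34",
               rep("reported ~80% lactate glucose-derived, transfected lines", 2))),
    enrTable("glucose", "alanine", c(0.60, 0.79, 0.77),
             c("reported ~60% alanine glucose-derived, NSC-34",
               "reported 79% alanine glucose-derived, WT-NSC",
               "reported 77% alanine glucose-derived, G93A-NSC")),
    enrTable("glucose", "citrate", c(0.50, 0.52, 0.48),
             rep("glucose carbon in citrate, within reported 40-55% range; G93A reduced vs WT", 3)),
    enrTable("glucose", "isocitrate", c(0.48, 0.50, 0.49),
             rep("glucose carbon in isocitrate, within reported 40-55% range", 3)),
    enrTable("glucose", "succinate", c(0.22, 0.23, 0.23),
             rep("glucose carbon in succinate, within reported 20-25% range", 3)),
    enrTable("glucose", "fumarate", c(0.45, 0.52, 0.52),
             rep("glucose carbon in fumarate, significant increase in transfected lines", 3)),
    enrTable("glucose", "malate", c(0.45, 0.52, 0.52),
             rep("glucose carbon in malate, significant increase in transfected lines", 3)),
    enrTable("glucose", "glutamate", c(0.50, 0.50, 0.509),
             c(rep("reported >=50% glutamate glucose-derived", 2),
               "reported +0.9 points glutamate enrichment G93A vs NSC-34")),
    enrTable("glucose", "glutamine", c(0.32, 0.18, 0.24),
             c("reported 32% glutamine glucose-derived, NSC-34",
               "reported 18% glutamine glucose-derived, WT-NSC",
               "reported 24% glutamine glucose-derived, G93A-NSC")),
    enrTable("glucose", "aspartate", c(0.40, 0.45, 0.45),
             rep("glucose carbon in aspartate (oxaloacetate-derived)", 3)),
    enrTable("glucose", "serine", c(0.35, 0.50, 0.55),
             rep("serine synthesis from glucose, increased in transfected lines", 3)),
    enrTable("glucose", "glycine", c(0.30, 0.45, 0.50),
             rep("glycine from glucose-derived serine, increased in transfected lines", 3)),
    enrTable("glucose", "cystathionine", c(0.20, 0.28, 0.34),
             rep("cystathionine from glucose-derived serine, increased in transfected lines", 3)),
    enrTable("glutamine", "PEP", c(0.05, 0.05, 0.05),
             rep("reported <10% glutamine-derived carbon in glycolytic pools", 3)),
    enrTable("glutamine", "pyruvate", c(0.05, 0.05, 0.05),
             rep("reported <10% glutamine-derived carbon in glycolytic pools", 3)),
    enrTable("glutamine", "lactate", c(0.05, 0.05, 0.05),
             rep("reported <10% glutamine-derived carbon in glycolytic pools", 3)),
    enrTable("glutamine", "alanine", c(0.05, 0.05, 0.05),
             rep("reported <10% glutamine-derived carbon in glycolytic pools", 3)),
    enrTable("glutamine", "citrate", c(0.15, 0.15, 0.15),
             rep("glutamine carbon in citrate, within reported 10-20% range", 3)),
    enrTable("glutamine", "isocitrate", c(0.15, 0.15, 0.15),
             rep("glutamine carbon in isocitrate, within reported 10-20% range", 3)),
    enrTable("glutamine", "succinate", c(0.24, 0.22, 0.22),
             rep("glutamine carbon in succinate, within reported 20-25% range", 3)),
    enrTable("glutamine", "fumarate", c(0.15, 0.15, 0.15),
             rep("glutamine carbon in fumarate, within reported 10-20% range", 3)),
    enrTable("glutamine", "malate", c(0.15, 0.15, 0.15),
             rep("glutamine carbon in malate, within reported 10-20% range", 3)),
    enrTable("glutamine", "glutamate", c(0.22, 0.22, 0.22),
             rep("reported 20-25% glutamate glutamine-derived", 3)),
    enrTable("glutamine", "glutamine", c(0.39, 0.67, 0.56),
             c("reported 39% glutamine enrichment on glutamine tracer, NSC-34",
               "reported 67% glutamine enrichment on glutamine tracer, WT-NSC",
               "reported 56% glutamine enrichment on glutamine tracer, G93A-NSC")),
    enrTable("glutamine", "aspartate", c(0.12, 0.12, 0.12),
             rep("glutamine carbon in aspartate (oxaloacetate-derived)", 3)),
    enrTable("glutamine", "serine", c(0.04, 0.04, 0.04),
             rep("minor glutamine-derived carbon in serine", 3)),
    enrTable("glutamine", "glycine", c(0.05, 0.05, 0.05),
             rep("minor glutamine-derived carbon in glycine", 3)),
    enrTable("glutamine", "cystathionine", c(0.05, 0.05, 0.05),
             rep("minor glutamine-derived carbon in cystathionine", 3))
  )

  poolRow <- function(metabolite, wt, g93a, ann)
    .df(metabolite = metabolite, line = lines, percent = c(100, wt, g93a),
        annotation = c("reference NSC-34 level (100%)", ann[1], ann[2]))
  pool <- rbind(
    poolRow("GAP", 100, 100, rep("no significant change in glyceraldehyde-3-phosphate", 2)),
    poolRow("DHAP", 100, 100, rep("no significant change in dihydroxyacetone phosphate", 2)),
    poolRow("3PG", 175, 180,
            rep("reported 70-80% higher 3-phosphoglycerate in transfected lines", 2)),
    poolRow("PEP", 361, 138,
            c("reported +261% PEP WT-NSC vs NSC-34",
              "reported +162% PEP WT-NSC vs G93A-NSC (G93A-NSC at 138%)")),
    poolRow("pyruvate", 278, 361,
            c("reported +178% pyruvate WT-NSC vs NSC-34",
              "reported +261% pyruvate G93A-NSC vs NSC-34")),
    poolRow("lactate", 250, 250,
            rep("intracellular lactate elevated in both transfected lines", 2)),
    poolRow("alanine", 230, 240,
            rep("intracellular alanine elevated in both transfected lines", 2)),
    poolRow("citrate", 135, 130,
            rep("reported +30-40% citrate, not significant", 2)),
    poolRow("isocitrate", 135, 130,
            rep("reported +30-40% isocitrate, not significant", 2)),
    poolRow("succinate", 100, 100, rep("no reported succinate pool change", 2)),
    poolRow("fumarate", 405, 304,
            c("reported up-to-+305% fumarate, significant",
              "reported -25% fumarate G93A-NSC vs WT-NSC")),
    poolRow("malate", 245, 149,
            c("reported +145% malate, significant",
              "reported -39% malate G93A-NSC vs WT-NSC")),
    poolRow("serine", 264, 158,
            c("reported +164% serine WT-NSC vs NSC-34",
              "reported -40% serine G93A-NSC vs WT-NSC")),
    poolRow("glycine", 147, 120,
            c("reported +47% glycine WT-NSC, not significant", "glycine G93A-NSC intermediate")),
    poolRow("aspartate", 177, 130,
            c("reported +77% aspartate WT-NSC, not significant", "aspartate G93A-NSC intermediate")),
    poolRow("glutamate", 200, 130,
            c("reported +100% glutamate WT-NSC vs NSC-34",
              "glutamate G93A-NSC not significantly above NSC-34")),
    poolRow("glutamine", 611, 134,
            c("reported +511% glutamine WT-NSC vs NSC-34",
              "reported -78% glutamine G93A-NSC vs WT-NSC")),
    poolRow("asparagine", 205, 66,
            c("reported +105% asparagine WT-NSC vs NSC-34",
              "reported -68% asparagine G93A-NSC vs WT-NSC")),
    poolRow("N-acetylaspartate", 206, 132,
            c("reported +106% N-acetylaspartate WT-NSC vs NSC-34",
              "reported -36% N-acetylaspartate G93A-NSC vs WT-NSC")),
    poolRow("leucine", 100, 49,
            c("no change in leucine with wtSOD1", "reported -51% leucine G93A-NSC vs NSC-34")),
    poolRow("isoleucine", 100, 49,
            c("no change in isoleucine with wtSOD1", "reported -51% isoleucine G93A-NSC vs NSC-34")),
    poolRow("valine", 100, 47,
            c("no change in valine with wtSOD1", "reported -53% valine G93A-NSC vs NSC-34")),
    poolRow("cysteine", 95, 44,
            c("no significant cysteine change with wtSOD1",
              "reported -56% cysteine G93A-NSC vs NSC-34"))
  )

  new("StudyConfig", lines = lines, mediaExchange = media, freshMedia = fresh,
      sourceFractions = src, enrichments = enr, poolPercent = pool,
      nMedia = 4L, nMid = 5L, nPool = 6L,
      cvIntensity = 0.05, cvProtein = 0.10,
      volumeMl = 2, proteinMg = 0.2, tracerPurity = 0.99,
      tracerConcMm = c(glucose = 25, glutamine = 1))
}

#' Generate synthetic media concentration tables
#'
#' Draws per-sample protein contents and spent-medium concentrations around
#' the configured true exchanges: the per-sample exchange is the line truth
#' times mean-preserving lognormal noise at `cvIntensity`, converted to a
#' concentration change via the sample's protein and the medium volume.
#'
#' @param cfg a [StudyConfig-class]
#' @param seed integer seed (mandatory; full determinism given config + seed)
#' @param n replicates per line; default `cfg@nMedia`
#' @param lines cell lines to generate; default all
#' @return data.frame in the media schema: sample_id, line, metabolite,
#'   fresh_mM, end_mM, volume_ml, protein_mg, plus true_exchange
#' @export
generateMediaDataset <- function(cfg, seed, n = cfg@nMedia, lines = cfg@lines) {
  stopifnot(is(cfg, "StudyConfig"))
  validObject(cfg)
  .withSeed(seed, {
    out <- list()
    for (ln in lines) {
      protein <- cfg@proteinMg * .lnoise(n, cfg@cvProtein)
      ex <- cfg@mediaExchange[cfg@mediaExchange$line == ln, ]
      for (i in seq_len(nrow(ex))) {
        met <- ex$metabolite[i]
        truth <- ex$exchange_umol_mg[i]
        fresh <- if (met %in% names(cfg@freshMedia)) cfg@freshMedia[[met]] else 0
        noisy <- truth * .lnoise(n, cfg@cvIntensity)
        end <- fresh + noisy * protein / cfg@volumeMl
        if (any(end < 0)) end <- pmax(end, 0)
        out[[paste(ln, met)]] <- .df(
          sample_id = sprintf("%s_media_%02d", ln, seq_len(n)),
          line = ln, metabolite = met, fresh_mM = fresh, end_mM = end,
          volume_ml = cfg@volumeMl, protein_mg = protein,
          true_exchange = truth)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

## memoized labeled-material MIDs from the positional simulator, per tracer.
## Dilution-like splits are set to 1 so each pool is the pure product of its
## tracer-fed route; the synthetic truth is then a mixture of this labeled
## material with unlabeled molecules.
.simCache <- new.env(parent = emptyenv())

.labeledMaterialMids <- function(tracer, purity) {
  key <- sprintf("%s_%.6f", tracer, purity)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  ## four pathway turns: finite turnover over the 22 h incubation, so TCA
  ## pools carry mixed isotopologue ladders rather than the fully-labeled
  ## infinite-cycling limit
  cfg <- if (tracer == "glucose")
    pathwayConfig("glucose", g = 1, q = 0, pcFraction = 0, oxGln = 0,
                  redIdh = 0, gsFraction = 1, gluFromGln = 0, serSynth = 1,
                  purity = purity, turns = 4L)
  else
    pathwayConfig("glutamine", g = 0, q = 1, pcFraction = 0, oxGln = 1,
                  redIdh = 0, gsFraction = 0, gluFromGln = 1, serSynth = 0,
                  purity = purity, turns = 4L)
  sim <- simulateExperiment(cfg)
  mids <- split(sim$mids$fraction, sim$mids$metabolite)
  ## restore panel order lost by split()
  mids <- mids[unique(sim$mids$metabolite)]
  .simCache[[key]] <- mids
  mids
}

## true MID at a target atom enrichment: dilute the simulator's labeled
## material with unlabeled molecules; if the labeled material is less
## enriched than the target (route not represented in the network, e.g.
## malic-enzyme carbon under glutamine tracer), fall back to independent
## per-carbon labeling at the target fraction.
.trueMid <- function(labeled, target) {
  n <- length(labeled) - 1L
  eL <- sum((0:n) * labeled) / n
  if (eL >= target && eL > 0) {
    d <- target / eL
    mid <- d * labeled
    mid[1L] <- mid[1L] + (1 - d)
  } else {
    mid <- stats::dbinom(0:n, n, target)
  }
  mid / sum(mid)
}

#' Generate synthetic tracer datasets (GC-MS isotopologue + NMR integrals)
#'
#' True MIDs come from the positional label-propagation simulator (with
#' tracer purity applied to the tracer input) diluted per line so the
#' carbon-atom enrichment equals the configured truth. GC-MS intensities
#' are the forward natural-abundance convolution of the true MID with the
#' TBDMS fragment's correction matrix, times multiplicative noise. NMR
#' center/satellite integrals are consistent with the configured
#' tracer-source fractions plus single-site natural abundance.
#'
#' @param cfg a [StudyConfig-class]
#' @param seed integer seed
#' @param tracers subset of c("glucose", "glutamine")
#' @param lines cell lines to generate; default all
#' @param metabolites metabolite subset for the GC-MS table; default the
#'   full configured panel
#' @param n replicates; default `cfg@nMid`
#' @return list with `gcms` (sample_id, line, tracer, metabolite,
#'   fragment_id, shift, intensity), `nmr` (NMR integral schema plus line
#'   and tracer), and `truth` (the configured enrichment and source
#'   fractions used)
#' @export
generateTracerDataset <- function(cfg, seed, tracers = c("glucose", "glutamine"),
                                  lines = cfg@lines, metabolites = NULL,
                                  n = cfg@nMid) {
  stopifnot(is(cfg, "StudyConfig"))
  validObject(cfg)
  lib <- readFragmentLibrary()
  gcms <- list(); nmr <- list()
  .withSeed(seed, {
    for (tr in tracers) {
      lmids <- .labeledMaterialMids(tr, cfg@tracerPurity)
      enr <- cfg@enrichments[cfg@enrichments$tracer == tr, ]
      if (!is.null(metabolites)) enr <- enr[enr$metabolite %in% metabolites, ]
      for (ln in lines) {
        eln <- enr[enr$line == ln, ]
        for (i in seq_len(nrow(eln))) {
          met <- eln$metabolite[i]
          frag <- lib[lib$metabolite == met, ]
          if (nrow(frag) != 1L) next
          labeled <- lmids[[met]]
          if (is.null(labeled)) next
          mid <- .trueMid(labeled, eln$enrichment[i])
          cm <- .cachedCorrectionMatrix(frag$formula, frag$n_backbone,
                                        frag$fragment_id)
          expected <- as.numeric(cm@matrix %*% mid)
          K <- nrow(cm@matrix) - 1L
          for (s in seq_len(n)) {
            intens <- 1e6 * expected * .lnoise(K + 1L, cfg@cvIntensity)
            gcms[[paste(tr, ln, met, s)]] <- .df(
              sample_id = sprintf("%s_%s_%02d", ln, tr, s),
              line = ln, tracer = tr, metabolite = met,
              fragment_id = frag$fragment_id, shift = 0:K,
              intensity = intens)
          }
        }
        ## NMR: lactate/alanine methyl resonances
        sf <- cfg@sourceFractions[cfg@sourceFractions$tracer == tr &
                                    cfg@sourceFractions$line == ln, ]
        for (i in seq_len(nrow(sf))) {
          met <- sf$metabolite[i]
          f13 <- sf$fraction[i] + (1 - sf$fraction[i]) * .C13_NATURAL
          total <- 300  # arbitrary integral scale; ratios carry the signal
          for (s in seq_len(n)) {
            cen <- total * (1 - f13) * .lnoise(1, cfg@cvIntensity)
            sat <- total * f13 * .lnoise(1, cfg@cvIntensity)
            nmr[[paste(tr, ln, met, s)]] <- .df(
              sample_id = sprintf("%s_%s_%02d", ln, tr, s),
              line = ln, tracer = tr, metabolite = met,
              resonance = paste0(met, "_CH3_d"),
              center = cen, satellites = sat,
              tsp = 50 * .lnoise(1, cfg@cvIntensity), protons = 3L)
          }
        }
      }
    }
  })
  list(gcms = if (length(gcms)) do.call(rbind, c(gcms, list(make.row.names = FALSE))),
       nmr = if (length(nmr)) do.call(rbind, c(nmr, list(make.row.names = FALSE))),
       truth = list(enrichments = cfg@enrichments,
                    sourceFractions = cfg@sourceFractions))
}

.cmCache <- new.env(parent = emptyenv())
.cachedCorrectionMatrix <- function(formula, nBackbone, fragmentId) {
  key <- paste(formula, nBackbone)
  if (is.null(.cmCache[[key]]))
    .cmCache[[key]] <- buildCorrectionMatrix(formula, nBackbone,
                                             fragmentId = fragmentId)
  .cmCache[[key]]
}

#' Generate a synthetic GC-MS profiling dataset
#'
#' Per-line fold-changes applied to baseline abundances (arbitrary units;
#' only ratios are meaningful), with injected internal-standard and protein
#' variation that the normalization step must remove, and optional missing
#' cells for back-fill testing.
#'
#' @param cfg a [StudyConfig-class]
#' @param seed integer seed
#' @param n replicates per line; default `cfg@nPool`
#' @param missingness fraction of cells set missing (NA), default 0
#' @return data.frame in the profiling schema: sample_id, line, metabolite,
#'   quant_ion_intensity, is_intensity, protein_mg
#' @export
generatePoolDataset <- function(cfg, seed, n = cfg@nPool, missingness = 0) {
  stopifnot(is(cfg, "StudyConfig"), missingness >= 0, missingness < 1)
  validObject(cfg)
  .withSeed(seed, {
    out <- list()
    for (ln in cfg@lines) {
      protein <- cfg@proteinMg * .lnoise(n, cfg@cvProtein)
      isFactor <- .lnoise(n, 0.15)  # injected injection/derivatization drift
      pp <- cfg@poolPercent[cfg@poolPercent$line == ln, ]
      for (i in seq_len(nrow(pp))) {
        truthAbundance <- pp$percent[i] / 100  # baseline 1.0 arbitrary units
        value <- truthAbundance * .lnoise(n, cfg@cvIntensity)
        raw <- value * protein * isFactor * 1e5
        if (missingness > 0) {
          drop <- stats::runif(n) < missingness
          raw[drop] <- NA_real_
        }
        out[[paste(ln, pp$metabolite[i])]] <- .df(
          sample_id = sprintf("%s_pool_%02d", ln, seq_len(n)),
          line = ln, metabolite = pp$metabolite[i],
          quant_ion_intensity = raw, is_intensity = isFactor * 1e5,
          protein_mg = protein)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
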