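test_that("the default study configuration is valid and fully annotated", {
  cfg <- defaultStudyConfig()
  expect_true(validObject(cfg))
  expect_equal(slot(cfg, "lines"), c("NSC-34", "WT-NSC", "G93A-NSC"))
  expect_equal(slot(cfg, "nMedia"), 4L)
  expect_equal(slot(cfg, "nMid"), 5L)
  expect_equal(slot(cfg, "nPool"), 6L)
  expect_equal(unname(slot(cfg, "tracerConcMm")), c(25, 1))
  for (nm in c("mediaExchange", "sourceFractions", "enrichments", "poolPercent")) {
    ann <- slot(cfg, nm)$annotation
    expect_true(all(nzchar(ann)), label = nm)
  }
  ## key configured contrasts encode the reported effects
  me <- slot(cfg, "mediaExchange")
  lac <- me[me$metabolite == "lactate", ]
  expect_equal(lac$exchange_umol_mg[lac$line == "G93A-NSC"] /
                 lac$exchange_umol_mg[lac$line == "WT-NSC"], 1.46)
  glc <- me[me$metabolite == "glucose", ]
  expect_equal(glc$exchange_umol_mg[glc$line == "G93A-NSC"] /
                 glc$exchange_umol_mg[glc$line == "NSC-34"], 1.37)
})

test_that("generation is fully deterministic given config + seed", {
  cfg <- defaultStudyConfig()
  a <- generateMediaDataset(cfg, seed = 17)
  b <- generateMediaDataset(cfg, seed = 17)
  expect_identical(a, b)
  expect_false(identical(a, generateMediaDataset(cfg, seed = 18)))
  ta <- generateTracerDataset(cfg, seed = 17, tracers = "glucose",
                              lines = "NSC-34", metabolites = "pyruvate")
  tb <- generateTracerDataset(cfg, seed = 17, tracers = "glucose",
                              lines = "NSC-34", metabolites = "pyruvate")
  expect_identical(ta$gcms, tb$gcms)
  pa <- generatePoolDataset(cfg, seed = 17)
  pb <- generatePoolDataset(cfg, seed = 17)
  expect_identical(pa, pb)
  expect_error(generateMediaDataset(cfg, seed = NULL), "seed")
})

test_that("generators do not disturb the caller's RNG stream", {
  cfg <- defaultStudyConfig()
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generateMediaDataset(cfg, seed = 1))
  expect_identical(runif(1), before)
})

test_that("zero noise yields the exact configured truths", {
  cfg <- defaultStudyConfig()
  slot(cfg, "cvIntensity") <- 0
  slot(cfg, "cvProtein") <- 0
  m <- mediaExchangeTable(generateMediaDataset(cfg, seed = 2))
  expect_equal(m$exchange_umol_mg, m$true_exchange, tolerance = 1e-9)
  d <- generateTracerDataset(cfg, seed = 2, tracers = "glucose",
                             lines = "NSC-34",
                             metabolites = c("pyruvate", "glutamine", "citrate"))
  enr <- correctMidTable(d$gcms)$enrichments
  truth <- slot(cfg, "enrichments")
  for (met in unique(enr$metabolite)) {
    want <- truth$enrichment[truth$tracer == "glucose" &
                               truth$line == "NSC-34" &
                               truth$metabolite == met]
    got <- mean(enr$enrichmentAtom[enr$metabolite == met])
    expect_equal(got, want, tolerance = 1e-6, label = met)
  }
})

test_that("an unlabeled control line corrects to near-zero enrichment", {
  ## natural-abundance-only forward signal: the raw intensities of a fully
  ## unlabeled fragment must correct to M+0
  lib <- readFragmentLibrary()
  frag <- lib[lib$metabolite == "citrate", ]
  cm <- buildCorrectionMatrix(frag$formula, frag$n_backbone)
  raw <- 1e6 * correctionMatrix(cm)[, 1]
  est <- fractionalEnrichment(correctMid(raw, cm))
  expect_lt(est, 0.005)
})

test_that("media truths are recovered without bias across seeds", {
  cfg <- defaultStudyConfig()
  diffs <- vapply(1:40, function(s) {
    m <- mediaExchangeTable(generateMediaDataset(cfg, seed = 500 + s, n = 8,
                                                 lines = c("WT-NSC", "G93A-NSC")))
    lac <- m[m$metabolite == "lactate", ]
    100 * (mean(lac$exchange_umol_mg[lac$line == "G93A-NSC"]) /
             mean(lac$exchange_umol_mg[lac$line == "WT-NSC"]) - 1)
  }, numeric(1))
  sem <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 46), 3 * sem + 0.5)
})

test_that("enrichment truths are recovered within 3 SEM at study n", {
  cfg <- defaultStudyConfig()
  ests <- vapply(1:25, function(s) {
    d <- generateTracerDataset(cfg, seed = 2000 + s, tracers = "glutamine",
                               lines = "WT-NSC", metabolites = "glutamine")
    mean(correctMidTable(d$gcms)$enrichments$enrichmentAtom)
  }, numeric(1))
  sem <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.67), 3 * sem + 2e-3)
})

test_that("true MID construction hits the target enrichment on the simplex", {
  labeled <- c(0.05, 0, 0.15, 0.8)  # labeled-material MID, e = 0.9
  for (target in c(0.1, 0.45, 0.85)) {
    mid <- sirmtools:::.trueMid(labeled, target)
    expect_true(all(mid >= 0))
    expect_equal(sum(mid), 1, tolerance = 1e-12)
    expect_equal(sum((0:3) * mid) / 3, target, tolerance = 1e-12)
  }
  ## unreachable target falls back to independent per-carbon labeling
  mid <- sirmtools:::.trueMid(c(1, 0, 0, 0), 0.3)
  expect_equal(mid, stats::dbinom(0:3, 3, 0.3), tolerance = 1e-12)
})
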