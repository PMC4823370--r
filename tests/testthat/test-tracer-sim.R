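test_that("the default network is structurally valid", {
  net <- buildDefaultNetwork()
  expect_true(validObject(net))
  pc <- poolCarbons(net)
  expect_equal(unname(pc[["glutamate"]]), 5L)
  expect_equal(unname(pc[["citrate"]]), 6L)
  ## every product carbon maps from exactly one source (validity enforces it;
  ## double-check one reaction by hand)
  cs <- Filter(function(r) r$name == "citrateSynthase", net@reactions)[[1]]
  expect_setequal(cs$map$prodCarbon, 1:6)
  expect_equal(sum(cs$map$source == "OAA"), 4L)
  expect_equal(sum(cs$map$source == "acetylCoA"), 2L)
})

test_that("with glycolysis only, label reaches only the glycolytic branch", {
  net <- buildDefaultNetwork()
  ## all TCA-feeding routes diluted away: g=1 but PDH product never recycled
  cfg <- pathwayConfig("glucose", g = 1, turns = 1)
  pools <- propagateLabels(net, cfg)
  labeled <- names(Filter(function(p) fractions(midOf(p))[1] < 1 - 1e-9, pools))
  expect_true(all(c("PG3", "PEP", "pyruvate", "lactate", "alanine", "serine") %in% labeled))
  expect_false("glutamine" %in% labeled)  # GS off by default
  ## one-carbon-removed pools lag one sweep behind in turn-limited mode
  expect_equal(fractions(midOf(pools$glutamate))[1], 1)
})

test_that("pool distributions stay on the simplex through propagation", {
  net <- buildDefaultNetwork()
  cfg <- pathwayConfig("glucose", g = 0.7, pcFraction = 0.2, oxGln = 0.3,
                       redIdh = 0.1, gsFraction = 0.4, gluFromGln = 0.6,
                       serSynth = 0.8, purity = 0.99, turns = 3)
  pools <- propagateLabels(net, cfg)
  for (p in pools) {
    expect_true(all(poolProbs(p) >= 0))
    expect_equal(sum(poolProbs(p)), 1, tolerance = 1e-9)
  }
})

test_that("glucose entry via PDH gives citrate M+2 on the first condensation", {
  net <- buildDefaultNetwork()
  pools <- propagateLabels(net, pathwayConfig("glucose", turns = 1))
  mid <- fractions(midOf(pools$citrate))
  expect_equal(mid[3], 1)                      # all citrate M+2
  expect_equal(sum(mid[-c(1, 3)]), 0)          # support within {0, 2}
})

test_that("glucose/PDH citrate has exactly zero M+1 through two turns", {
  net <- buildDefaultNetwork()
  for (turns in 1:2) {
    mid <- fractions(midOf(propagateLabels(net,
      pathwayConfig("glucose", turns = turns))$citrate))
    expect_identical(mid[2], 0)
  }
})

test_that("glucose/PDH steady state climbs to citrate M+6", {
  net <- buildDefaultNetwork()
  pools <- propagateLabels(net, pathwayConfig("glucose"))
  mid <- fractions(midOf(pools$citrate))
  expect_equal(max(which(mid > 1e-9)) - 1L, 6L)
  expect_identical(mid[2], 0)  # odd shifts cannot arise without carboxylation
})

test_that("oxidative glutamine entry gives citrate M+4, never M+3", {
  net <- buildDefaultNetwork()
  p1 <- propagateLabels(net, pathwayConfig("glutamine", oxGln = 1, turns = 1))
  mid1 <- fractions(midOf(p1$citrate))
  expect_equal(mid1[5], 1)
  expect_equal(mid1[4], 0)
  expect_equal(mid1[6], 0)
  ## structural impossibility at steady state too, with partial recycling
  for (ox in c(1, 0.6)) {
    ps <- propagateLabels(net, pathwayConfig("glutamine", oxGln = ox))
    expect_identical(fractions(midOf(ps$citrate))[4], 0)
  }
})

test_that("reductive carboxylation switches on citrate M+5", {
  net <- buildDefaultNetwork()
  off <- fractions(midOf(propagateLabels(net,
    pathwayConfig("glutamine", oxGln = 1))$citrate))
  on <- fractions(midOf(propagateLabels(net,
    pathwayConfig("glutamine", oxGln = 1, redIdh = 0.3))$citrate))
  expect_equal(off[6], 0)
  expect_gt(on[6], 0.1)
})

test_that("pyruvate carboxylase adds odd citrate isotopologues from glucose", {
  net <- buildDefaultNetwork()
  pools <- propagateLabels(net, pathwayConfig("glucose", pcFraction = 0.3))
  mid <- fractions(midOf(pools$citrate))
  expect_gt(mid[4] + mid[6], 0.01)  # M+3 or M+5 present
})

test_that("glutamine synthetase transmits glucose label into glutamine M+5", {
  net <- buildDefaultNetwork()
  off <- propagateLabels(net, pathwayConfig("glucose"))
  on <- propagateLabels(net, pathwayConfig("glucose", gsFraction = 0.5,
                                           gluFromGln = 0))
  expect_equal(fractions(midOf(off$glutamine))[6], 0)
  expect_gt(fractions(midOf(on$glutamine))[6], 0.01)
})

test_that("glutamine anaplerosis dilutes succinate below isocitrate", {
  net <- buildDefaultNetwork()
  ## glucose tracer with oxidative glutamine inflow at the AKG node
  pools <- propagateLabels(net, pathwayConfig("glucose", oxGln = 0.5,
                                              gluFromGln = 1))
  eSucc <- fractionalEnrichment(midOf(pools$succinate))
  eIso <- fractionalEnrichment(midOf(pools$isocitrate))
  expect_lt(eSucc, eIso)
})

test_that("scrambling is idempotent, MID-preserving, and guarded", {
  set.seed(3)
  p <- new("CarbonPool", name = "succinate", nCarbons = 4L,
           probs = randomSimplex(16))
  s1 <- scrambleSymmetric(p, "succinate")
  s2 <- scrambleSymmetric(s1, "succinate")
  expect_equal(poolProbs(s1), poolProbs(s2), tolerance = 1e-14)
  expect_equal(fractions(midOf(p)), fractions(midOf(s1)), tolerance = 1e-12)
  ## end-to-end reversal pairs average: 1100 (3) <-> 0011 (12)
  expect_equal(poolProbs(s1)[4], (poolProbs(p)[4] + poolProbs(p)[13]) / 2)
  expect_error(scrambleSymmetric(p, "fumarate"), "not flagged symmetric")
})

test_that("midOf counts set bits", {
  p <- new("CarbonPool", name = "x", nCarbons = 2L, probs = rep(0.25, 4))
  expect_equal(fractions(midOf(p)), c(0.25, 0.5, 0.25))
  p0 <- new("CarbonPool", name = "x", nCarbons = 3L, probs = c(1, rep(0, 7)))
  expect_equal(fractions(midOf(p0)), c(1, 0, 0, 0))
})

test_that("label is conserved per reaction application", {
  net <- buildDefaultNetwork()
  pc <- poolCarbons(net)
  set.seed(9)
  dists <- lapply(names(pc), function(p) randomSimplex(2^pc[[p]]))
  names(dists) <- names(pc)
  expectedLabels <- function(probs, n, carbons) {
    states <- 0:(2^n - 1L)
    sum(vapply(carbons, function(cb)
      sum(probs[bitwAnd(bitwShiftR(states, cb - 1L), 1L) == 1L]), numeric(1)))
  }
  for (rx in net@reactions) {
    prod <- sirmtools:::.reactionProduct(rx, dists, pc)
    np <- pc[[rx$product]]
    eProd <- expectedLabels(prod, np, 1:np)
    eIn <- 0
    m <- rx$map[rx$map$source != "EXT", ]
    for (src in unique(c(m$source, rx$release$source))) {
      carbons <- c(m$sourceCarbon[m$source == src],
                   rx$release$sourceCarbon[rx$release$source == src])
      eIn <- eIn + expectedLabels(dists[[src]], pc[[src]], carbons)
    }
    eRel <- 0
    if (nrow(rx$release))
      for (i in seq_len(nrow(rx$release)))
        eRel <- eRel + expectedLabels(dists[[rx$release$source[i]]],
                                      pc[[rx$release$source[i]]],
                                      rx$release$sourceCarbon[i])
    expect_equal(eProd + eRel, eIn, tolerance = 1e-10, label = rx$name)
  }
})

test_that("steady state is order-independent", {
  net <- buildDefaultNetwork()
  cfg <- pathwayConfig("glucose", g = 0.8, pcFraction = 0.15, oxGln = 0.3,
                       gsFraction = 0.3, purity = 0.99)
  ref <- propagateLabels(net, cfg)
  set.seed(5)
  for (i in 1:3) {
    perm <- sample(net@updateOrder)
    alt <- propagateLabels(net, cfg, order = perm)
    for (p in names(ref))
      expect_equal(poolProbs(alt[[p]]), poolProbs(ref[[p]]), tolerance = 1e-8,
                   label = paste("permutation", i, p))
  }
})

test_that("turn-limited distributions match the ancestry-sampling oracle", {
  cfg <- pathwayConfig("glucose", g = 0.8, pcFraction = 0.2, purity = 1,
                       turns = 2)
  pools <- propagateLabels(buildDefaultNetwork(), cfg)
  set.seed(21)
  for (pool in c("citrate", "succinate", "pyruvate")) {
    mc <- mcOracleMid(pool, 2L, cfg, nSamples = 20000)
    expect_equal(fractions(midOf(pools[[pool]])), mc, tolerance = 0.015,
                 label = pool)
  }
})

test_that("simulateExperiment reports the panel with consistent conventions", {
  sim <- simulateExperiment(pathwayConfig("glucose", turns = 2))
  expect_true(all(c("pyruvate", "citrate", "glutamine", "cystathionine") %in%
                    sim$enrichments$metabolite))
  sums <- tapply(sim$mids$fraction, sim$mids$metabolite, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## atom enrichment of the reported MIDs matches the enrichment table
  for (met in c("pyruvate", "citrate")) {
    mid <- sim$mids[sim$mids$metabolite == met, ]
    e <- sum(mid$shift * mid$fraction) / max(mid$shift)
    expect_equal(e, sim$enrichments$enrichmentAtom[
      sim$enrichments$metabolite == met], tolerance = 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(pathwayConfig(tracer = "acetate"), "glucose")
  expect_error(pathwayConfig(g = 1.2), "\\[0, 1\\]")
  expect_error(pathwayConfig(turns = 0), "turns")
})
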