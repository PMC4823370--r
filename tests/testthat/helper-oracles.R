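## Independent oracles used across the suite.

## Exhaustive enumeration of isotope assignments: every atom independently
## takes one of its isotopes; total shift distribution by brute force.
## Independent of the convolution implementation in the package.
bruteForcePattern <- function(formula, K) {
  if (is.character(formula)) formula <- parseFormula(formula)
  ab <- isotopeAbundances()
  atoms <- list()
  for (el in names(formula))
    for (i in seq_len(formula[[el]])) atoms[[length(atoms) + 1L]] <- ab[[el]]
  if (!length(atoms)) return(c(1, rep(0, K)))
  grid <- as.matrix(expand.grid(lapply(atoms, seq_along)))
  probs <- rep(1, nrow(grid))
  for (j in seq_along(atoms)) probs <- probs * atoms[[j]][grid[, j]]
  shifts <- rowSums(grid - 1L)
  out <- numeric(K + 1L)
  keep <- shifts <= K
  for (s in 0:K) out[s + 1L] <- sum(probs[keep][shifts[keep] == s])
  out
}

## random point on the simplex
randomSimplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

## Monte-Carlo ancestry-sampling oracle for turn-limited label propagation:
## samples single molecules by recursively sampling the producing reaction
## and its substrate molecules, mirroring the Gauss-Seidel turn semantics
## (substrates earlier in the update order are taken at the current turn).
mcOracleMid <- function(pool, turns, cfg, nSamples = 20000,
                        net = buildDefaultNetwork()) {
  pc <- poolCarbons(net)
  w <- sirmtools:::.reactionWeights(cfg)
  producers <- list()
  for (rx in net@reactions) {
    wt <- if (rx$name %in% names(w)) w[[rx$name]] else rx$weight
    if (wt <= 0) next
    rx$weight <- wt
    producers[[rx$product]] <- c(producers[[rx$product]], list(rx))
  }
  inputs <- sirmtools:::.inputDists(net, cfg)
  pos <- stats::setNames(seq_along(net@updateOrder), net@updateOrder)

  sampleState <- function(p, turn) {
    if (p %in% names(inputs))
      return(sample.int(length(inputs[[p]]), 1L, prob = inputs[[p]]) - 1L)
    if (turn <= 0L) return(0L)
    prs <- producers[[p]]
    if (is.null(prs)) return(0L)
    wts <- vapply(prs, function(r) r$weight, numeric(1))
    rx <- prs[[sample.int(length(prs), 1L, prob = wts)]]
    subStates <- list()
    for (sub in rx$substrates) {
      subTurn <- if (sub %in% names(inputs)) turn
                 else if (!is.na(pos[sub]) && pos[sub] < pos[p]) turn
                 else turn - 1L
      subStates[[sub]] <- sampleState(sub, subTurn)
    }
    state <- 0L
    for (k in seq_len(nrow(rx$map))) {
      src <- rx$map$source[k]
      if (src == "EXT") next
      bit <- bitwAnd(bitwShiftR(subStates[[src]], rx$map$sourceCarbon[k] - 1L), 1L)
      state <- state + bitwShiftL(bit, rx$map$prodCarbon[k] - 1L)
    }
    if (p %in% net@symmetric && stats::runif(1) < 0.5) {
      n <- pc[[p]]
      rev <- 0L
      for (i in 1:n)
        rev <- rev + bitwShiftL(bitwAnd(bitwShiftR(state, i - 1L), 1L), n - i)
      state <- rev
    }
    state
  }

  n <- pc[[pool]]
  counts <- numeric(n + 1L)
  for (s in seq_len(nSamples)) {
    st <- sampleState(pool, turns)
    k <- sum(bitwAnd(bitwShiftR(st, 0:(n - 1L)), 1L))
    counts[k + 1L] <- counts[k + 1L] + 1
  }
  counts / nSamples
}

## textbook one-way ANOVA F from explicit sums of squares
textbookF <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

## step-up BH adjustment written from the definition
stepUpBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
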