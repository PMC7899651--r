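# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately share no code with the implementation paths they check.

makeTrain <- function(ts, dur, id = "u") {
  new("SpikeTrain", unitId = id, timestamps = as.numeric(ts),
      sessionDur = dur)
}

# 10 Hz clockwork train: one spike per 100 ms, centred in each bin
regularTrain <- function(dur, rate = 10, id = "reg") {
  step <- 1 / rate
  makeTrain(seq(step / 2, dur - step / 2, by = step), dur, id)
}

# Naive double-loop peri-event counter (left-closed half-open bins)
naiveAlignBin <- function(ts, eventTimes, edges) {
  nb <- length(edges) - 1L
  counts <- matrix(0L, nrow = length(eventTimes), ncol = nb)
  for (i in seq_along(eventTimes)) {
    for (b in seq_len(nb)) {
      lo <- eventTimes[i] + edges[b]
      hi <- eventTimes[i] + edges[b + 1L]
      for (t in ts) if (t >= lo && t < hi)
        counts[i, b] <- counts[i, b] + 1L
    }
  }
  counts
}

# Exhaustive hypergeometric enumeration of the two-sided probability-ordering
# p-value, via stats::dhyper (independent of the lchoose-based implementation)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  p <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(p[p <= pObs * (1 + 1e-7)])
}

# Brute-force Monte-Carlo oracle of the classification rule for homogeneous
# Poisson units: bin counts drawn directly as independent Poissons, the
# z-rule re-coded from scratch (vectorised over units).
nullRuleOracle <- function(nUnits, nEvents = 6L, rateHz = 4, binW = 0.1,
                           nBase = 10L, nResp = 5L, thr = 1.96, minBins = 2L) {
  lam <- rateHz * binW
  nBins <- nBase + nResp
  out <- logical(nUnits)
  done <- 0L
  while (done < nUnits) {
    nb <- min(5000L, nUnits - done)
    arr <- array(rpois(nb * nBins * nEvents, lam), dim = c(nb, nBins, nEvents))
    xbar <- rowMeans(arr, dims = 2)
    mu <- rowMeans(xbar[, seq_len(nBase), drop = FALSE])
    sdv <- apply(xbar[, seq_len(nBase), drop = FALSE], 1L, sd)
    z <- (xbar[, nBase + seq_len(nResp), drop = FALSE] - mu) / sdv
    pos <- rowSums(z > thr)
    neg <- rowSums(z < -thr)
    out[done + seq_len(nb)] <- ifelse(sdv > 0, pos >= minBins | neg >= minBins, NA)
    done <- done + nb
  }
  out
}

# Package-path null/power run: simulate spike trains and classify each with
# the exported pipeline primitives; returns the responsive fraction.
classifiedFraction <- function(nUnits, multiplier, timeline, seedBase,
                               rateHz = 4, params = ClassifierParams()) {
  cs <- eventTimes(timeline, "CS_ON")
  mods <- if (multiplier != 1)
    list(RateModulation("CS_ON", multiplier)) else list()
  resp <- logical(nUnits)
  for (i in seq_len(nUnits)) {
    st <- simulateSpikeTrain(UnitSpec("u", rateHz, mods), timeline,
                             seed = seedBase + i)
    prof <- zscoreProfile(alignAndBin(st, cs, params), params)
    resp[i] <- if (prof@degenerate) NA else
      classifyUnit(prof, params)@responsive
  }
  mean(resp, na.rm = TRUE)
}

# Build a ZScoreProfile directly from a z vector over the response window
profileFromZ <- function(zResp, zBase = rep(0, 10)) {
  z <- c(zBase, zResp)
  edges <- seq(-1, 0.5, by = 0.1)
  new("ZScoreProfile", unitId = "u", eventLabel = "CS_ON",
      binMeans = z, baselineMean = 0, baselineSD = 1, z = z,
      binEdges = edges, baselineBins = 1:10,
      responseBins = as.integer(10 + seq_along(zResp)), nEvents = 1L,
      degenerate = FALSE)
}

# PerieventMatrix from an explicit counts matrix (CS-style edges)
matrixFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  edges <- -1 + 0.1 * (0:ncol(counts))
  new("PerieventMatrix", unitId = "u", eventLabel = "CS_ON",
      counts = counts, binEdges = edges, droppedEvents = numeric())
}
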