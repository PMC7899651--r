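test_that("alignAndBin counts with the half-open left-closed convention", {
  # clockwork 10 Hz train: every 100 ms bin holds exactly one spike
  st <- regularTrain(100)
  m <- alignAndBin(st, eventTimes = c(20, 50.03), ClassifierParams())
  expect_equal(dim(m@counts), c(2L, 15L))
  expect_true(all(m@counts == 1L))

  # spike exactly on an interior bin edge lands in the later bin (bin width
  # 0.25 keeps every edge exactly representable in binary)
  p25 <- ClassifierParams(binWidth = 0.25, responseWindow = 1.25)
  st2 <- makeTrain(16.5, 100)
  m2 <- alignAndBin(st2, eventTimes = 16, p25)
  expect_equal(m2@counts[1, 13], 1L)   # bin [0.5, 0.75)
  expect_equal(m2@counts[1, 12], 0L)   # bin [0.25, 0.5)

  # spike at the event time itself belongs to the first response bin
  st3 <- makeTrain(10, 100)
  m3 <- alignAndBin(st3, eventTimes = 10, ClassifierParams())
  expect_equal(m3@counts[1, 11], 1L)

  # no spikes: zero matrix of correct shape
  m4 <- alignAndBin(makeTrain(numeric(), 100), c(20, 50), ClassifierParams())
  expect_true(all(m4@counts == 0L))
  expect_equal(dim(m4@counts), c(2L, 15L))
})

test_that("events without full window coverage are dropped per event", {
  st <- regularTrain(100)
  m <- alignAndBin(st, eventTimes = c(0.5, 50, 99.8), ClassifierParams())
  expect_equal(nrow(m@counts), 1L)
  expect_equal(m@droppedEvents, c(0.5, 99.8))
  # the freeze-shifted window reaches 1 s further back
  m2 <- alignAndBin(st, eventTimes = c(1.5, 50),
                    ClassifierParams(baselineOffset = 1))
  expect_equal(m2@droppedEvents, 1.5)
  expect_equal(ncol(m2@counts), 25L)
  expect_error(alignAndBin(st, numeric(), ClassifierParams()), "nonempty")
})

test_that("alignAndBin matches a naive double-loop counter", {
  params <- ClassifierParams()
  edges <- c(seq(-1, 0.4, by = 0.1), 0.5)
  set.seed(42)
  for (rep in 1:30) {
    nSpk <- sample(0:20, 1)
    ts <- sort(round(runif(nSpk, 0, 60), 3))
    ev <- sort(round(runif(sample(1:3, 1), 2, 58), 3))
    st <- makeTrain(ts, 60)
    m <- alignAndBin(st, ev, params)
    expect_equal(unname(m@counts), naiveAlignBin(ts, ev, m@binEdges))
  }
})

test_that("zscoreProfile reproduces hand-computed values", {
  # a perfectly flat profile has zero baseline SD: degenerate by the rule,
  # never an all-zero z vector
  flat <- matrixFromCounts(matrix(1L, nrow = 4, ncol = 15))
  expect_true(zscoreProfile(flat, ClassifierParams())@degenerate)

  # response activity equal to the baseline mean gives z exactly 0
  even <- matrix(rep(c(1, 2), length.out = 15), nrow = 1)  # baseline mean 1.5
  even[1, 11] <- 1.5
  zp <- zscoreProfile(matrixFromCounts(even), ClassifierParams())
  expect_equal(unname(zScores(zp)[11]), 0)
  expect_false(zp@degenerate)

  # alternating baseline 0,1,...: mu = 0.5, sd = 0.527046 (n-1), a response
  # bin holding 2 gives z = (2 - 0.5) / 0.5270463 = 2.846050
  counts <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 2, 0, 0, 0, 0), nrow = 1)
  zp2 <- zscoreProfile(matrixFromCounts(counts), ClassifierParams())
  expect_equal(zp2@baselineMean, 0.5)
  expect_equal(zp2@baselineSD, 0.5270463, tolerance = 1e-6)
  expect_equal(unname(zScores(zp2)[11]), 2.8460499, tolerance = 1e-6)

  # constant-zero baseline: degenerate, excluded from classification
  silent <- matrixFromCounts(matrix(c(rep(0, 10), 3, 3, 0, 0, 0), nrow = 1))
  zp3 <- zscoreProfile(silent, ClassifierParams())
  expect_true(zp3@degenerate)
  expect_true(all(is.na(zScores(zp3))))
  expect_error(classifyUnit(zp3), "degenerate")

  # n denominator option
  zp4 <- zscoreProfile(matrixFromCounts(counts),
                       ClassifierParams(sdDenominator = "n"))
  expect_equal(zp4@baselineSD, 0.5, tolerance = 1e-12)
})

test_that("classifyUnit implements the two-same-sign-bins strict rule", {
  cases <- list(
    list(z = c(2.1, 2.3, 0.1, 0.0, -0.5), resp = TRUE, dir = "excited"),
    # per-sign counting: bins 1 and 3 exceed +1.96 regardless of the dips
    list(z = c(2.1, -2.1, 2.0, -2.0, 0), resp = TRUE, dir = "excited"),
    list(z = c(1.96, 1.96, 1.96, 1.96, 1.96), resp = FALSE, dir = "none"),
    list(z = c(-2.5, -3.0, 0, 0, 0), resp = TRUE, dir = "inhibited"),
    list(z = c(2.5, 0, 0, 0, 0), resp = FALSE, dir = "none"),
    list(z = c(-1.96, -1.96, 2, 0, 0), resp = FALSE, dir = "none")
  )
  for (cs in cases) {
    call <- classifyUnit(profileFromZ(cs$z), ClassifierParams())
    expect_equal(call@responsive, cs$resp, info = paste(cs$z, collapse = ","))
    expect_equal(call@direction, cs$dir, info = paste(cs$z, collapse = ","))
  }
  # supra bins are reported for the called direction
  call <- classifyUnit(profileFromZ(c(2.1, -2.1, 2.0, -2.0, 0)),
                       ClassifierParams())
  expect_equal(call@supraBins, c(1L, 3L))
})

test_that("profiles and calls are invariant to event order", {
  st <- makeTrain(sort(runif(200, 0, 300)), 300)
  ev <- c(50, 120, 200, 260)
  params <- ClassifierParams()
  p1 <- zscoreProfile(alignAndBin(st, ev, params), params)
  p2 <- zscoreProfile(alignAndBin(st, rev(ev), params), params)
  expect_equal(zScores(p1), zScores(p2))
  expect_equal(classifyUnit(p1, params)@direction,
               classifyUnit(p2, params)@direction)
})

test_that("meanRate and peakResponseBin follow their closed forms", {
  expect_equal(meanRate(makeTrain(seq(0.1, 24.9, length.out = 100), 25)), 4)
  expect_equal(meanRate(makeTrain(numeric(), 10)), 0)
  expect_equal(meanRate(regularTrain(10)), 10)
  expect_error(meanRate(makeTrain(numeric(), 0)))

  pk <- peakResponseBin(profileFromZ(c(0, 0, 3, 0, 0)))
  expect_equal(unname(pk["bin"]), 3)
  expect_equal(unname(pk["latency_s"]), 0.2)
  expect_equal(unname(pk["z"]), 3)
  # tie goes to the earliest bin
  pk2 <- peakResponseBin(profileFromZ(c(2, 2, 0, 0, 0)))
  expect_equal(unname(pk2["bin"]), 1)
  # largest |z|, sign kept
  pk3 <- peakResponseBin(profileFromZ(c(0, 0, 0, 0, -4)))
  expect_equal(unname(pk3["bin"]), 5)
  expect_equal(unname(pk3["z"]), -4)
})

test_that("classifyAll aligns CS and freeze events with shifted baselines", {
  tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 9)
  unit <- UnitSpec("mod", 4, list(RateModulation("CS_ON", 6)))
  st <- simulateSpikeTrain(unit, tl, seed = 21)
  tr <- BehaviorTrace(start = c(250, 400), end = c(280, 430),
                      sessionDur = totalDur(tl))
  fe <- extractFreezeEvents(tr, tl)
  calls <- classifyAll(list(st), tl, fe)
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$event_label, c("CS_ON", "FREEZE_ON", "FREEZE_OFF"))
  csRow <- calls[calls$event_label == "CS_ON", ]
  expect_true(csRow$responsive)
  expect_equal(csRow$direction, "excited")
  expect_equal(csRow$n_events, 6L)

  # no freeze events: labels reported as excluded with a reason
  feEmpty <- extractFreezeEvents(BehaviorTrace(sessionDur = totalDur(tl)), tl)
  calls2 <- classifyAll(list(st), tl, feEmpty)
  fo <- calls2[calls2$event_label == "FREEZE_ON", ]
  expect_true(fo$excluded)
  expect_match(fo$reason, "no events")

  # NULL freeze events: CS alignment only
  calls3 <- classifyAll(list(st), tl, NULL)
  expect_equal(calls3$event_label, "CS_ON")
})

test_that("a unit modulated only at freeze cessation is not CS-driven", {
  tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 9)
  tr <- simulateBehavior(tl, BehaviorModelParams(), seed = 33)
  unit <- UnitSpec("fo", 4, list(RateModulation("FREEZE_OFF", 8)))
  hits <- 0L
  for (s in 1:20) {
    st <- simulateSpikeTrain(unit, tl, behavior = tr, seed = 500 + s)
    calls <- classifyAll(list(st), tl, extractFreezeEvents(tr, tl))
    if (isTRUE(calls$responsive[calls$event_label == "FREEZE_OFF"])) hits <- hits + 1L
  }
  expect_gt(hits, 15)  # strong effect detected almost always
  csHits <- 0L
  for (s in 1:20) {
    st <- simulateSpikeTrain(unit, tl, behavior = tr, seed = 500 + s)
    calls <- classifyAll(list(st), tl, NULL)
    if (isTRUE(calls$responsive)) csHits <- csHits + 1L
  }
  expect_lt(csHits, 10)  # CS calls stay near the null rate
})
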