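# A 1000 s single-CS session used for rate-law checks
longSession <- function() {
  p <- SessionProtocol("CS_ONLY", csCount = 1, usFlags = FALSE,
                       intervalRange = c(15, 60), baselineDur = 500,
                       csDur = 30, postDur = 470)
  buildTimeline(p, seed = 1)
}

test_that("homogeneous train matches the Poisson mean across replicates", {
  tl <- longSession()
  expect_equal(totalDur(tl), 1000)
  unit <- UnitSpec("u", baselineRate = 4)
  counts <- vapply(1:200, function(s)
    length(timestamps(simulateSpikeTrain(unit, tl, seed = s))), numeric(1))
  # count ~ Poisson(4000): mean within 3 SE, variance on the Poisson scale
  se <- sqrt(4000 / 200)
  expect_lt(abs(mean(counts) - 4000), 3 * se)
  expect_gt(var(counts), 4000 * 0.7)
  expect_lt(var(counts), 4000 * 1.4)
})

test_that("vanishing rate yields an (almost always) empty train", {
  tl <- longSession()
  unit <- UnitSpec("u", baselineRate = 1e-4)
  n <- vapply(1:20, function(s)
    length(timestamps(simulateSpikeTrain(unit, tl, seed = s))), numeric(1))
  expect_lte(sum(n), 3)  # expectation 0.1 per train
})

test_that("CS boxcar modulation scales the response-window rate", {
  tl <- longSession()
  cs <- eventTimes(tl, "CS_ON")
  unit <- UnitSpec("u", 20, list(RateModulation("CS_ON", 3, latency = 0,
                                                duration = 0.5)))
  inWin <- 0; flank <- 0
  for (s in 1:200) {
    ts <- timestamps(simulateSpikeTrain(unit, tl, seed = 400 + s))
    inWin <- inWin + sum(ts >= cs & ts < cs + 0.5)
    flank <- flank + sum(ts >= cs - 0.5 & ts < cs)
  }
  # closed-form: E[inWin] = 3 * E[flank]; compare on the log scale with a
  # delta-method 3-SE band for the ratio of two Poisson totals
  expect_lt(abs(log(inWin / flank) - log(3)),
            3 * sqrt(1 / inWin + 1 / flank))
})

test_that("identical inputs and seed give identical trains", {
  tl <- longSession()
  unit <- UnitSpec("u", 4, list(RateModulation("CS_ON", 2)))
  a <- simulateSpikeTrain(unit, tl, seed = 5)
  b <- simulateSpikeTrain(unit, tl, seed = 5)
  expect_identical(timestamps(a), timestamps(b))
  expect_true(all(timestamps(a) >= 0 & timestamps(a) < totalDur(tl)))
  expect_false(is.unsorted(timestamps(a)))
})

test_that("freeze-locked modulation requires a behavior trace", {
  tl <- longSession()
  unit <- UnitSpec("u", 4, list(RateModulation("FREEZE_ON", 0.3)))
  expect_error(simulateSpikeTrain(unit, tl, seed = 1), "behavior")
  tr <- BehaviorTrace(start = 100, end = 200, sessionDur = totalDur(tl))
  expect_s4_class(simulateSpikeTrain(unit, tl, behavior = tr, seed = 1),
                  "SpikeTrain")
})

test_that("behavior generator respects degenerate rate settings", {
  tl <- longSession()
  none <- BehaviorModelParams(0, 0, 0, 0, minBout = 0)
  expect_equal(nrow(bouts(simulateBehavior(tl, none, seed = 1))), 0L)

  oneWay <- BehaviorModelParams(1e6, 0, 1e6, 0, minBout = 0)
  b <- bouts(simulateBehavior(tl, oneWay, seed = 2))
  expect_equal(nrow(b), 1L)
  expect_lt(b$start_s, 0.01)            # first transition almost immediate
  expect_equal(b$end_s, totalDur(tl))   # never unfreezes
})

test_that("symmetric rates give ~50% long-run freezing", {
  p <- SessionProtocol("CS_ONLY", csCount = 1, usFlags = FALSE,
                       intervalRange = c(15, 60), baselineDur = 2000,
                       csDur = 30, postDur = 970)
  tl <- buildTimeline(p, seed = 1)  # 3000 s, CS negligible
  par <- BehaviorModelParams(0.5, 0.5, 0.5, 0.5, minBout = 0)
  fr <- vapply(1:5, function(s) {
    b <- bouts(simulateBehavior(tl, par, seed = s))
    sum(b$end_s - b$start_s) / totalDur(tl)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("bouts are disjoint, sorted, in-session, and respect minBout", {
  tl <- longSession()
  par <- BehaviorModelParams(0.3, 0.3, 0.3, 0.3, minBout = 2)
  for (s in 1:10) {
    tr <- simulateBehavior(tl, par, seed = 100 + s)
    b <- bouts(tr)
    expect_true(all(b$start_s < b$end_s))
    expect_true(all(b$start_s >= 0 & b$end_s <= totalDur(tl)))
    if (nrow(b) > 1L) {
      expect_false(is.unsorted(b$start_s))
      gaps <- b$start_s[-1L] - b$end_s[-nrow(b)]
      expect_true(all(gaps >= 2 - 1e-9))
    }
    expect_true(all(b$end_s - b$start_s >= 2 - 1e-9))
  }
})

test_that("simulateCohort applies the floor rule and is reproducible", {
  des <- CohortDesign(data.frame(
    group = c("a", "b"), n_units = c(10L, 5L), rate_mean_hz = 4,
    rate_sdlog = 0.4, frac_cs_on = c(0.4, 0), frac_freeze_off = c(0.25, 0),
    cs_multiplier = 3, freeze_multiplier = 3), seed = 77)
  c1 <- simulateCohort(des)
  c2 <- simulateCohort(des)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$groups$a$spikes, timestamps),
                   lapply(c2$groups$a$spikes, timestamps))

  ta <- c1$truth[c1$truth$group == "a", ]
  expect_equal(sum(ta$label == "CS_ON"), 4L)        # floor(0.4 * 10)
  expect_equal(sum(ta$label == "FREEZE_OFF"), 2L)   # floor(0.25 * 10)
  tb <- c1$truth[c1$truth$group == "b", ]
  expect_true(all(tb$label == "none"))
  expect_equal(length(c1$groups$a$spikes), 10L)
  expect_equal(length(c1$groups$b$behavior), 5L)
  expect_true(all(c1$truth$baseline_rate_hz > 0))
})
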