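#' Construct a RateModulation
#'
#' @param eventLabel \code{"CS_ON"}, \code{"FREEZE_ON"} or \code{"FREEZE_OFF"}.
#' @param multiplier rate factor during the response, > 0 (< 1 = decrease).
#' @param latency seconds from the event to modulation onset.
#' @param duration modulation duration, seconds. The default 0.5 s boxcar
#'   matches the analysis response window.
#' @return a [RateModulation-class].
#' @export
#' @examples
#' RateModulation("CS_ON", multiplier = 3)
RateModulation <- function(eventLabel, multiplier, latency = 0,
                           duration = 0.5) {
  new("RateModulation", eventLabel = eventLabel, multiplier = multiplier,
      latency = latency, duration = duration)
}

#' Construct a UnitSpec
#'
#' @param unitId unit identifier.
#' @param baselineRate baseline firing rate, Hz.
#' @param modulations list of [RateModulation-class] (default none).
#' @return a [UnitSpec-class].
#' @export
#' @examples
#' UnitSpec("u1", baselineRate = 4,
#'          modulations = list(RateModulation("CS_ON", 3)))
UnitSpec <- function(unitId, baselineRate, modulations = list()) {
  new("UnitSpec", unitId = as.character(unitId), baselineRate = baselineRate,
      modulations = modulations)
}

#' Construct BehaviorModelParams
#'
#' Defaults give strong CS-evoked freezing (stationary freezing fraction
#' ~0.83 during the CS, ~0.17 outside it) with dwell times on the tens-of-
#' seconds scale typical of conditioned mice.
#'
#' @param moveToFreezeCS,freezeToMoveCS transition rates during CS, per s.
#' @param moveToFreezeOut,freezeToMoveOut rates outside CS, per s.
#' @param minBout minimum dwell retained, seconds; shorter dwells are merged
#'   into the surrounding state.
#' @return a [BehaviorModelParams-class].
#' @export
#' @examples
#' BehaviorModelParams()
BehaviorModelParams <- function(moveToFreezeCS = 0.10, freezeToMoveCS = 0.02,
                                moveToFreezeOut = 0.02, freezeToMoveOut = 0.10,
                                minBout = 1) {
  new("BehaviorModelParams", moveToFreezeCS = moveToFreezeCS,
      freezeToMoveCS = freezeToMoveCS, moveToFreezeOut = moveToFreezeOut,
      freezeToMoveOut = freezeToMoveOut, minBout = minBout)
}

# Piecewise-constant rate function for one unit: returns a list with sorted
# segment breakpoints over [0, totalDur] and the rate on each segment.
# lambda(t) = baselineRate * prod of multipliers of all modulation instances
# active at t (instance = one event occurrence of the modulation's label).
unitRateFunction <- function(unit, timeline, behavior = NULL) {
  total <- timeline@totalDur
  starts <- numeric()
  logm <- numeric()
  ends <- numeric()
  for (m in unit@modulations) {
    evt <- switch(m@eventLabel,
      CS_ON = eventTimes(timeline, "CS_ON"),
      FREEZE_ON = {
        if (is.null(behavior))
          stop("FREEZE_ON modulation requires a behavior trace")
        behavior@bouts$start_s
      },
      FREEZE_OFF = {
        if (is.null(behavior))
          stop("FREEZE_OFF modulation requires a behavior trace")
        behavior@bouts$end_s
      })
    if (!length(evt)) next
    s <- pmin(pmax(evt + m@latency, 0), total)
    e <- pmin(pmax(evt + m@latency + m@duration, 0), total)
    keep <- e > s
    starts <- c(starts, s[keep])
    ends <- c(ends, e[keep])
    logm <- c(logm, rep(log(m@multiplier), sum(keep)))
  }
  brk <- sort(unique(c(0, total, starts, ends)))
  # cumulative log-multiplier: +log(m) at each instance start, -log(m) at end
  delta <- numeric(length(brk))
  if (length(starts)) {
    si <- match(starts, brk); ei <- match(ends, brk)
    for (k in seq_along(si)) {
      delta[si[k]] <- delta[si[k]] + logm[k]
      delta[ei[k]] <- delta[ei[k]] - logm[k]
    }
  }
  segRate <- unit@baselineRate * exp(cumsum(delta))[-length(brk)]
  list(breaks = brk, rates = segRate)
}

#' Simulate an inhomogeneous Poisson spike train
#'
#' Generates one spike train as an inhomogeneous Poisson process with
#' piecewise-constant rate \eqn{\lambda(t) = r_0 \prod_k m_k(t)}, where
#' \eqn{r_0} is the unit's baseline rate and each active boxcar modulation
#' contributes its multiplier. Sampling uses thinning against the maximal
#' rate, which is exact for piecewise-constant rates: candidate spikes are
#' drawn homogeneously at \eqn{\lambda_{max}} and kept with probability
#' \eqn{\lambda(t)/\lambda_{max}}. Identical (inputs, seed) give identical
#' trains.
#'
#' @param unit a [UnitSpec-class].
#' @param timeline a [SessionTimeline-class] supplying CS event times and the
#'   session duration.
#' @param behavior a [BehaviorTrace-class]; required when the unit carries
#'   FREEZE_ON/FREEZE_OFF modulations, otherwise may be NULL.
#' @param seed integer seed.
#' @return a [SpikeTrain-class] with sorted timestamps in
#'   \code{[0, totalDur)}.
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 1)
#' st <- simulateSpikeTrain(UnitSpec("u1", 4), tl, seed = 2)
#' meanRate(st)
simulateSpikeTrain <- function(unit, timeline, behavior = NULL, seed) {
  validObject(unit)
  rf <- unitRateFunction(unit, timeline, behavior)
  total <- timeline@totalDur
  lmax <- max(rf$rates)
  ts <- withSeed(seed, {
    n <- rpois(1L, lmax * total)
    cand <- sort(runif(n, 0, total))
    if (length(cand)) {
      seg <- findInterval(cand, rf$breaks, rightmost.closed = TRUE)
      seg <- pmin(pmax(seg, 1L), length(rf$rates))
      keep <- runif(length(cand)) < rf$rates[seg] / lmax
      cand[keep]
    } else numeric()
  })
  ts <- ts[ts < total]
  new("SpikeTrain", unitId = unit@unitId, timestamps = ts, sessionDur = total)
}

#' Simulate freeze/move behavior as a two-state Markov process
#'
#' Realizes a continuous-time two-state (move/freeze) Markov chain whose
#' transition rates switch between CS and non-CS values according to the
#' timeline. The animal starts in the move state at t = 0. Dwell intervals
#' shorter than \code{minBout} are merged into the surrounding state
#' (shortest first) after simulation; the returned freezing bouts are
#' disjoint, sorted and within \code{[0, totalDur)}.
#'
#' @param timeline a [SessionTimeline-class].
#' @param params a [BehaviorModelParams-class].
#' @param seed integer seed.
#' @return a [BehaviorTrace-class].
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 1)
#' bt <- simulateBehavior(tl, BehaviorModelParams(), seed = 3)
#' head(bouts(bt))
simulateBehavior <- function(timeline, params, seed) {
  validObject(params)
  total <- timeline@totalDur
  csOn <- eventTimes(timeline, "CS_ON")
  csOff <- eventTimes(timeline, "CS_OFF")
  segBrk <- sort(unique(c(0, total, csOn[csOn < total],
                          csOff[csOff < total])))
  segCS <- inAnyInterval(segBrk[-length(segBrk)], csOn, csOff)
  rate <- function(state, inCS) {
    if (state == 0L) { # moving
      if (inCS) params@moveToFreezeCS else params@moveToFreezeOut
    } else {
      if (inCS) params@freezeToMoveCS else params@freezeToMoveOut
    }
  }
  transitions <- withSeed(seed, {
    t <- 0; state <- 0L; seg <- 1L; out <- numeric()
    while (t < total) {
      segEnd <- segBrk[seg + 1L]
      r <- rate(state, segCS[seg])
      if (r <= 0) {
        t <- segEnd
      } else {
        dwell <- rexp(1L, r)
        if (t + dwell < segEnd) {
          t <- t + dwell
          out <- c(out, t)
          state <- 1L - state
        } else t <- segEnd
      }
      if (t >= segEnd - 1e-12 && seg < length(segCS)) seg <- seg + 1L
      if (t >= total) break
    }
    out
  })
  # dwell sequence: states alternate starting from move at 0
  edges <- c(0, transitions, total)
  states <- rep_len(c(0L, 1L), length(edges) - 1L)
  dw <- data.frame(state = states, start = edges[-length(edges)],
                   end = edges[-1L])
  dw <- dw[dw$end > dw$start, , drop = FALSE]
  dw <- mergeShortDwells(dw, params@minBout)
  fr <- dw[dw$state == 1L, , drop = FALSE]
  BehaviorTrace(start = fr$start, end = fr$end, sessionDur = total)
}

# Merge dwell intervals shorter than minBout into the surrounding state,
# shortest first; adjacent same-state dwells are coalesced after each merge.
mergeShortDwells <- function(dw, minBout) {
  if (minBout <= 0) return(dw)
  repeat {
    if (nrow(dw) <= 1L) return(dw)
    dur <- dw$end - dw$start
    short <- which(dur < minBout)
    if (!length(short)) return(dw)
    i <- short[which.min(dur[short])]
    dw$state[i] <- if (i > 1L) dw$state[i - 1L] else dw$state[i + 1L]
    # coalesce runs of equal state
    r <- rle(dw$state)
    idx <- cumsum(r$lengths)
    dw <- data.frame(state = r$values,
                     start = dw$start[c(1L, head(idx, -1L) + 1L)],
                     end = dw$end[idx])
  }
}

#' Construct a BehaviorTrace from bout endpoints
#'
#' @param start,end numeric vectors of bout start/end times, seconds;
#'   half-open \code{[start, end)}, sorted, disjoint.
#' @param sessionDur session duration, seconds.
#' @return a [BehaviorTrace-class].
#' @export
#' @examples
#' BehaviorTrace(start = c(10, 50), end = c(20, 80), sessionDur = 100)
BehaviorTrace <- function(start = numeric(), end = numeric(), sessionDur) {
  new("BehaviorTrace",
      bouts = data.frame(start_s = as.numeric(start), end_s = as.numeric(end)),
      sessionDur = sessionDur)
}

#' Construct a CohortDesign
#'
#' @param groups data.frame with one row per group and columns \code{group},
#'   \code{n_units}, \code{rate_mean_hz}, \code{rate_sdlog},
#'   \code{frac_cs_on}, \code{frac_freeze_off}, \code{cs_multiplier},
#'   \code{freeze_multiplier}.
#' @param behaviorParams a [BehaviorModelParams-class].
#' @param seed master integer seed.
#' @return a [CohortDesign-class].
#' @export
#' @examples
#' CohortDesign(data.frame(group = "ctrl", n_units = 10, rate_mean_hz = 4,
#'                         rate_sdlog = 0.5, frac_cs_on = 0.4,
#'                         frac_freeze_off = 0.3, cs_multiplier = 3,
#'                         freeze_multiplier = 3), seed = 1)
CohortDesign <- function(groups, behaviorParams = BehaviorModelParams(),
                         seed) {
  new("CohortDesign", groups = groups, behaviorParams = behaviorParams,
      seed = as.integer(seed))
}

#' Simulate a multi-group cohort with ground-truth labels
#'
#' Generates, for each group in the design: baseline rates drawn log-normal
#' around the group mean, one retrieval-style timeline, one behavior trace
#' per unit, and one spike train per unit. Exactly
#' \code{floor(frac_cs_on * n)} units carry a CS-onset modulation (the first
#' units in id order) and \code{floor(frac_freeze_off * n)} carry a
#' freeze-cessation modulation (the last units in id order), both as 0.5 s
#' boxcars at zero latency. Ground-truth labels are returned for recovery
#' tests. Fully reproducible from the design seed.
#'
#' @param design a [CohortDesign-class].
#' @param protocol the session protocol for every group's timeline (default
#'   the retrieval protocol, the session in which unit analysis happens).
#' @return a list with elements \code{groups} (named list; each entry has
#'   \code{timeline}, \code{behavior} and \code{spikes}, the latter two
#'   per-unit lists) and \code{truth} (data.frame with columns
#'   \code{unit_id}, \code{group}, \code{baseline_rate_hz}, \code{label},
#'   \code{multiplier}; label is \code{"none"} for unmodulated units).
#' @export
#' @examples
#' des <- CohortDesign(data.frame(group = "g", n_units = 4, rate_mean_hz = 4,
#'                                rate_sdlog = 0.4, frac_cs_on = 0.5,
#'                                frac_freeze_off = 0, cs_multiplier = 3,
#'                                freeze_multiplier = 3), seed = 11)
#' cohort <- simulateCohort(des)
#' cohort$truth
simulateCohort <- function(design, protocol = defaultProtocol("RETRIEVAL")) {
  validObject(design)
  g <- design@groups
  out <- list()
  truthRows <- list()
  for (gi in seq_len(nrow(g))) {
    n <- as.integer(g$n_units[gi])
    grp <- as.character(g$group[gi])
    tl <- buildTimeline(protocol, seed = deriveSeed(design@seed, gi * 10000L + 1L))
    sdlog <- g$rate_sdlog[gi]
    meanlog <- log(g$rate_mean_hz[gi]) - sdlog^2 / 2
    rates <- withSeed(deriveSeed(design@seed, gi * 10000L + 2L),
                      rlnorm(n, meanlog, sdlog))
    nCS <- floor(g$frac_cs_on[gi] * n)
    nFO <- floor(g$frac_freeze_off[gi] * n)
    ids <- sprintf("%s_u%03d", grp, seq_len(n))
    hasCS <- seq_len(n) <= nCS
    hasFO <- seq_len(n) > n - nFO
    behavior <- vector("list", n); names(behavior) <- ids
    spikes <- vector("list", n); names(spikes) <- ids
    for (u in seq_len(n)) {
      mods <- list()
      if (hasCS[u])
        mods <- c(mods, RateModulation("CS_ON", g$cs_multiplier[gi]))
      if (hasFO[u])
        mods <- c(mods, RateModulation("FREEZE_OFF", g$freeze_multiplier[gi]))
      spec <- UnitSpec(ids[u], rates[u], mods)
      behavior[[u]] <- simulateBehavior(tl, design@behaviorParams,
                                        seed = deriveSeed(design@seed, gi * 10000L + 2L * u + 100L))
      spikes[[u]] <- simulateSpikeTrain(spec, tl, behavior[[u]],
                                        seed = deriveSeed(design@seed, gi * 10000L + 2L * u + 101L))
      lab <- c(if (hasCS[u]) "CS_ON", if (hasFO[u]) "FREEZE_OFF")
      mult <- c(if (hasCS[u]) g$cs_multiplier[gi],
                if (hasFO[u]) g$freeze_multiplier[gi])
      if (is.null(lab)) { lab <- "none"; mult <- 1 }
      truthRows[[length(truthRows) + 1L]] <-
        data.frame(unit_id = ids[u], group = grp,
                   baseline_rate_hz = rates[u], label = lab,
                   multiplier = mult)
    }
    out[[grp]] <- list(timeline = tl, behavior = behavior, spikes = spikes)
  }
  list(groups = out, truth = do.call(rbind, truthRows))
}
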