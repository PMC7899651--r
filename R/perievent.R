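#' Construct ClassifierParams
#'
#' Defaults implement the standard rule: 100 ms bins, 500 ms response window
#' (5 bins), 1 s baseline (10 bins) immediately before the event, z threshold
#' 1.96 (strict), at least 2 same-sign supra-threshold bins. For
#' freeze-aligned analysis set \code{baselineOffset = 1} so the baseline
#' spans -2 to -1 s before the event.
#'
#' @param binWidth bin width, seconds.
#' @param responseWindow response window, seconds.
#' @param nBaselineBins number of baseline bins.
#' @param zThreshold z criterion.
#' @param minSupraBins minimum same-sign supra-threshold bins.
#' @param baselineOffset seconds before the event at which the baseline
#'   window ends (0 for CS, 1 for freeze events).
#' @param sdDenominator \code{"n-1"} (default) or \code{"n"}.
#' @return a [ClassifierParams-class].
#' @export
#' @examples
#' ClassifierParams()
#' ClassifierParams(baselineOffset = 1)  # freeze-aligned variant
ClassifierParams <- function(binWidth = 0.1, responseWindow = 0.5,
                             nBaselineBins = 10L, zThreshold = 1.96,
                             minSupraBins = 2L, baselineOffset = 0,
                             sdDenominator = "n-1") {
  new("ClassifierParams", binWidth = binWidth,
      responseWindow = responseWindow,
      nBaselineBins = as.integer(nBaselineBins), zThreshold = zThreshold,
      minSupraBins = as.integer(minSupraBins),
      baselineOffset = baselineOffset, sdDenominator = sdDenominator)
}

# Bin edges relative to the event: from -(baselineOffset + baseline span) to
# +responseWindow in binWidth steps. With baselineOffset > 0 the bins between
# the baseline window and the event are computed but belong to neither the
# baseline nor the response window.
perieventBinEdges <- function(params) {
  left <- -(params@baselineOffset + params@nBaselineBins * params@binWidth)
  nBins <- round((params@responseWindow - left) / params@binWidth)
  left + (0:nBins) * params@binWidth
}

#' Align spikes to events and bin them
#'
#' Counts spikes in half-open (left-closed) 100 ms bins around each event.
#' Bins span from the start of the baseline window,
#' \code{-(baselineOffset + nBaselineBins * binWidth)} s, to the end of the
#' response window, \code{+responseWindow} s, relative to each event. A spike
#' falling exactly on an interior bin edge counts in the later bin; a spike
#' at the event time itself falls in the first response bin. Events whose
#' full window extends outside the recorded session are dropped (per event)
#' and recorded in \code{droppedEvents}.
#'
#' @param spikes a [SpikeTrain-class].
#' @param eventTimes numeric vector of event times, seconds; must be
#'   nonempty.
#' @param params a [ClassifierParams-class].
#' @return a [PerieventMatrix-class] (rows = retained events, cols = bins).
#' @export
#' @examples
#' st <- new("SpikeTrain", unitId = "u", timestamps = seq(0.05, 99.95, 0.1),
#'           sessionDur = 100)
#' m <- alignAndBin(st, eventTimes = c(20, 50), ClassifierParams())
#' m@counts
alignAndBin <- function(spikes, eventTimes, params = ClassifierParams()) {
  stopIfNot(length(eventTimes) > 0, "eventTimes must be nonempty")
  validObject(params)
  edges <- perieventBinEdges(params)
  lo <- edges[1L]; hi <- edges[length(edges)]
  covered <- eventTimes + lo >= 0 & eventTimes + hi <= spikes@sessionDur
  kept <- eventTimes[covered]
  ts <- spikes@timestamps
  counts <- matrix(0L, nrow = length(kept), ncol = length(edges) - 1L)
  for (i in seq_along(kept)) {
    rel <- ts - kept[i]
    rel <- rel[rel >= lo & rel < hi]
    if (length(rel))
      counts[i, ] <- tabulate(findInterval(rel, edges),
                              nbins = length(edges) - 1L)
  }
  new("PerieventMatrix", unitId = spikes@unitId,
      eventLabel = "", counts = counts, binEdges = edges,
      droppedEvents = eventTimes[!covered])
}

#' Trial-averaged, baseline-normalised z profile
#'
#' Averages the peri-event counts across events (one mean count per bin),
#' then z-scores every bin against the mean and SD of the baseline bins
#' (the first \code{nBaselineBins} bins; SD uses the n-1 denominator by
#' default). A zero baseline SD (e.g. a silent baseline) marks the profile
#' degenerate; degenerate profiles carry NA z values and are excluded from
#' classification.
#'
#' @param mat a [PerieventMatrix-class] with at least one retained event.
#' @param params the [ClassifierParams-class] used for binning.
#' @return a [ZScoreProfile-class].
#' @export
#' @examples
#' st <- new("SpikeTrain", unitId = "u", timestamps = seq(0.05, 99.95, 0.1),
#'           sessionDur = 100)
#' zp <- zscoreProfile(alignAndBin(st, c(20, 50)), ClassifierParams())
#' zScores(zp)
zscoreProfile <- function(mat, params = ClassifierParams()) {
  stopIfNot(nrow(mat@counts) >= 1L, "need at least one retained event")
  nb <- params@nBaselineBins
  nBins <- ncol(mat@counts)
  nResp <- round(params@responseWindow / params@binWidth)
  xbar <- colMeans(mat@counts)
  basel <- xbar[seq_len(nb)]
  mu <- mean(basel)
  sdv <- if (params@sdDenominator == "n-1") sd(basel)
         else sqrt(mean((basel - mu)^2))
  degenerate <- !is.finite(sdv) || sdv == 0
  z <- if (degenerate) rep(NA_real_, nBins) else (xbar - mu) / sdv
  new("ZScoreProfile", unitId = mat@unitId, eventLabel = mat@eventLabel,
      binMeans = xbar, baselineMean = mu,
      baselineSD = if (degenerate) 0 else sdv, z = z,
      binEdges = mat@binEdges, baselineBins = seq_len(nb),
      responseBins = as.integer((nBins - nResp + 1L):nBins),
      nEvents = nrow(mat@counts), degenerate = degenerate)
}

#' Classify a unit's responsiveness from its z profile
#'
#' A unit is responsive to the aligned event when at least
#' \code{minSupraBins} response-window bins exceed \code{+zThreshold}
#' (excited) or at least \code{minSupraBins} fall below \code{-zThreshold}
#' (inhibited); inequalities are strict, and the qualifying bins must all lie
#' on one side — positive and negative crossings are counted separately and
#' never jointly qualify. If both directions qualify independently, the
#' direction with more qualifying bins is reported (ties broken by the larger
#' peak |z|).
#'
#' @param profile a non-degenerate [ZScoreProfile-class].
#' @param params a [ClassifierParams-class].
#' @return a [ResponsivenessCall-class]; \code{supraBins} are 1-based indices
#'   within the response window.
#' @export
#' @examples
#' # see classifyAll() for the full pipeline
classifyUnit <- function(profile, params = ClassifierParams()) {
  stopIfNot(!profile@degenerate,
            "degenerate profile (baseline SD = 0) cannot be classified")
  zr <- profile@z[profile@responseBins]
  pos <- which(zr > params@zThreshold)
  neg <- which(zr < -params@zThreshold)
  k <- params@minSupraBins
  posOK <- length(pos) >= k
  negOK <- length(neg) >= k
  if (posOK && negOK) {
    dir <- if (length(pos) != length(neg)) {
      if (length(pos) > length(neg)) "excited" else "inhibited"
    } else if (max(zr[pos]) >= max(-zr[neg])) "excited" else "inhibited"
  } else if (posOK) dir <- "excited"
  else if (negOK) dir <- "inhibited"
  else dir <- "none"
  supra <- switch(dir, excited = pos, inhibited = neg, integer())
  new("ResponsivenessCall", unitId = profile@unitId,
      eventLabel = profile@eventLabel, responsive = dir != "none",
      direction = dir, supraBins = as.integer(supra))
}

#' Classify all units against CS onset, freezing onset and cessation
#'
#' Runs the full per-unit analysis: CS alignment uses the baseline
#' immediately before CS onset (\code{baselineOffset = 0}); freeze onset and
#' cessation alignments shift the baseline to -2..-1 s before the event
#' (\code{baselineOffset = 1}) so the baseline is temporally separate from
#' the event, while the response window stays [0, 0.5) s after it. Units
#' with zero analyzable events for a label, or a degenerate (zero baseline
#' SD) profile, get NA calls with the reason recorded.
#'
#' @param spikesList list of [SpikeTrain-class], one per unit.
#' @param timeline a [SessionTimeline-class] (supplies CS onsets).
#' @param freezeEvents a [FreezeEventSeries-class] from
#'   [extractFreezeEvents()] (with \code{preWindow >= 2}); may be NULL to
#'   classify CS responsiveness only.
#' @param params CS-alignment [ClassifierParams-class]; the freeze-aligned
#'   variant is derived from it by setting \code{baselineOffset = 1}.
#' @return data.frame with one row per unit x event label and columns
#'   \code{unit_id}, \code{event_label}, \code{n_events}, \code{responsive},
#'   \code{direction}, \code{supra_bins} (comma-separated),
#'   \code{peak_z}, \code{peak_latency_s}, \code{excluded}, \code{reason}.
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 1)
#' u <- UnitSpec("u1", 4, list(RateModulation("CS_ON", 5)))
#' st <- simulateSpikeTrain(u, tl, seed = 2)
#' classifyAll(list(st), tl, freezeEvents = NULL)
classifyAll <- function(spikesList, timeline, freezeEvents,
                        params = ClassifierParams()) {
  freezeParams <- ClassifierParams(
    binWidth = params@binWidth, responseWindow = params@responseWindow,
    nBaselineBins = params@nBaselineBins, zThreshold = params@zThreshold,
    minSupraBins = params@minSupraBins, baselineOffset = 1,
    sdDenominator = params@sdDenominator)
  alignments <- list(
    CS_ON = list(times = eventTimes(timeline, "CS_ON"), params = params))
  if (!is.null(freezeEvents)) {
    alignments$FREEZE_ON <- list(times = freezeEvents@onsets,
                                 params = freezeParams)
    alignments$FREEZE_OFF <- list(times = freezeEvents@cessations,
                                  params = freezeParams)
  }
  rows <- list()
  for (st in spikesList) {
    for (lab in names(alignments)) {
      al <- alignments[[lab]]
      row <- data.frame(unit_id = st@unitId, event_label = lab,
                        n_events = 0L, responsive = NA, direction = NA_character_,
                        supra_bins = NA_character_, peak_z = NA_real_,
                        peak_latency_s = NA_real_, excluded = TRUE,
                        reason = NA_character_)
      if (!length(al$times)) {
        row$reason <- "no events of this type"
      } else {
        mat <- alignAndBin(st, al$times, al$params)
        mat@eventLabel <- lab
        if (nrow(mat@counts) == 0L) {
          row$reason <- "no events with full window coverage"
        } else {
          prof <- zscoreProfile(mat, al$params)
          row$n_events <- nrow(mat@counts)
          if (prof@degenerate) {
            row$reason <- "degenerate profile (baseline SD = 0)"
          } else {
            call <- classifyUnit(prof, al$params)
            pk <- peakResponseBin(prof)
            row$responsive <- call@responsive
            row$direction <- call@direction
            row$supra_bins <- paste(call@supraBins, collapse = ",")
            row$peak_z <- pk["z"]
            row$peak_latency_s <- pk["latency_s"]
            row$excluded <- FALSE
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mean firing rate of a spike train
#'
#' @param spikes a [SpikeTrain-class] with positive duration.
#' @return rate in Hz: number of spikes / session duration.
#' @export
#' @examples
#' meanRate(new("SpikeTrain", unitId = "u", timestamps = seq(0, 24.9, 0.25),
#'              sessionDur = 25))
meanRate <- function(spikes) {
  stopIfNot(spikes@sessionDur > 0, "sessionDur must be > 0")
  length(spikes@timestamps) / spikes@sessionDur
}

#' Peak response bin of a z profile
#'
#' The response-window bin with the largest |z|; ties go to the earliest
#' bin. Latency is reported in seconds as the bin's [left, right) interval
#' relative to the event.
#'
#' @param profile a non-degenerate [ZScoreProfile-class].
#' @return named numeric vector: \code{bin} (1-based index within the
#'   response window), \code{latency_s} (bin left edge), \code{z}.
#' @export
#' @examples
#' # peakResponseBin(profile) after zscoreProfile()
peakResponseBin <- function(profile) {
  stopIfNot(!profile@degenerate, "degenerate profile has no peak")
  zr <- profile@z[profile@responseBins]
  i <- which.max(abs(zr))  # which.max returns the earliest maximum
  left <- profile@binEdges[profile@responseBins[i]]
  c(bin = i, latency_s = left, z = zr[i])
}
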