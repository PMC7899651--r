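#' @import methods
NULL

.PROTOCOL_KINDS <- c("PRF", "FRF", "CS_ONLY", "RETRIEVAL")
.EVENT_LABELS <- c("CS_ON", "CS_OFF", "US_ON", "US_OFF")
.MODULATION_LABELS <- c("CS_ON", "FREEZE_ON", "FREEZE_OFF")

#' SessionProtocol: parameterization of one conditioning or retrieval session
#'
#' Holds the stimulus schedule parameters of a Pavlovian fear-conditioning
#' session: the pre-stimulus baseline, the conditioned-stimulus (CS, a 30 s
#' tone) presentations, which of them co-terminate with the unconditioned
#' stimulus (US, a 2 s footshock), the admissible range of inter-trial
#' intervals, and the post-stimulus period. Shock amplitude and tone level are
#' carried as metadata only.
#'
#' @slot kind one of \code{"PRF"} (partially reinforced: 6 CS, 3 reinforced),
#'   \code{"FRF"} (fully reinforced: 3 CS, all reinforced), \code{"CS_ONLY"},
#'   \code{"RETRIEVAL"}.
#' @slot baselineDur baseline duration before the first CS, seconds.
#' @slot csDur CS duration, seconds.
#' @slot csCount number of CS presentations.
#' @slot usFlags logical vector, one per CS; \code{TRUE} means the US
#'   co-terminates with that CS.
#' @slot usDur US duration, seconds.
#' @slot intervalRange length-2 numeric, min/max seconds between one CS offset
#'   and the next CS onset.
#' @slot postDur no-stimulus period after the final trial, seconds.
#' @slot usAmp_mA shock amplitude in milliamps (metadata).
#' @slot csLevel_dB tone level in decibels (metadata).
#'
#' @seealso [defaultProtocol()], [buildTimeline()]
#' @export
setClass("SessionProtocol",
  representation(
    kind = "character",
    baselineDur = "numeric",
    csDur = "numeric",
    csCount = "integer",
    usFlags = "logical",
    usDur = "numeric",
    intervalRange = "numeric",
    postDur = "numeric",
    usAmp_mA = "numeric",
    csLevel_dB = "numeric"
  )
)

setValidity("SessionProtocol", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .PROTOCOL_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.PROTOCOL_KINDS, collapse = ", ")))
  if (length(object@usFlags) != object@csCount)
    msg <- c(msg, "length(usFlags) must equal csCount")
  if (object@csCount < 1L)
    msg <- c(msg, "csCount must be >= 1")
  dur <- c(baselineDur = object@baselineDur, csDur = object@csDur,
           usDur = object@usDur, postDur = object@postDur)
  if (any(!is.finite(dur)) || any(dur <= 0))
    msg <- c(msg, "all durations must be finite and > 0")
  if (length(object@intervalRange) != 2L ||
      object@intervalRange[1L] > object@intervalRange[2L] ||
      any(object@intervalRange < 0))
    msg <- c(msg, "intervalRange must be (min, max) with 0 <= min <= max")
  if (length(msg)) msg else TRUE
})

#' SessionTimeline: realized event schedule for one session
#'
#' An ordered list of stimulus events (CS/US on/off times in seconds from
#' session start) realized from a [SessionProtocol-class], with inter-trial
#' intervals drawn from the protocol's range. All intervals are half-open
#' \code{[on, off)}; session start is time 0.
#'
#' @slot protocol the generating [SessionProtocol-class].
#' @slot events data.frame with columns \code{label} (one of CS_ON, CS_OFF,
#'   US_ON, US_OFF) and \code{time_s}, sorted by time.
#' @slot totalDur session duration in seconds (last event time + post period).
#'
#' @seealso [buildTimeline()], [validateTimeline()], [eventTimes()]
#' @export
setClass("SessionTimeline",
  representation(
    protocol = "SessionProtocol",
    events = "data.frame",
    totalDur = "numeric"
  )
)

setValidity("SessionTimeline", function(object) {
  ev <- object@events
  if (!all(c("label", "time_s") %in% names(ev)))
    return("events must have columns 'label' and 'time_s'")
  if (nrow(ev) && !all(ev$label %in% .EVENT_LABELS))
    return("unknown event label")
  TRUE
})

#' BehaviorTrace: freezing bouts over one session
#'
#' Freezing behaviour represented as sorted, pairwise-disjoint half-open
#' intervals \code{[start_s, end_s)} during which the animal is frozen (no
#' visible movement except breathing); the animal is moving elsewhere.
#'
#' @slot bouts data.frame with numeric columns \code{start_s}, \code{end_s},
#'   sorted and disjoint, within \code{[0, sessionDur]}.
#' @slot sessionDur session duration in seconds.
#'
#' @seealso [simulateBehavior()], [scoreFreezing()], [extractFreezeEvents()]
#' @export
setClass("BehaviorTrace",
  representation(bouts = "data.frame", sessionDur = "numeric")
)

setValidity("BehaviorTrace", function(object) {
  b <- object@bouts
  if (!all(c("start_s", "end_s") %in% names(b)))
    return("bouts must have columns 'start_s' and 'end_s'")
  if (nrow(b)) {
    if (any(b$start_s >= b$end_s)) return("each bout must have start < end")
    if (any(b$start_s < 0) || any(b$end_s > object@sessionDur))
      return("bouts must lie within [0, sessionDur]")
    if (is.unsorted(b$start_s, strictly = TRUE) && nrow(b) > 1L)
      return("bouts must be sorted by start time")
    if (nrow(b) > 1L && any(b$start_s[-1L] < b$end_s[-nrow(b)]))
      return("bouts must be pairwise disjoint")
  }
  TRUE
})

#' SpikeTrain: sorted spike timestamps for one unit
#'
#' @slot unitId unit identifier (character).
#' @slot timestamps nondecreasing spike times in seconds, in
#'   \code{[0, sessionDur)}.
#' @slot sessionDur recording duration in seconds.
#'
#' @seealso [simulateSpikeTrain()], [meanRate()], [alignAndBin()]
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", timestamps = "numeric",
                 sessionDur = "numeric")
)

setValidity("SpikeTrain", function(object) {
  ts <- object@timestamps
  if (length(ts)) {
    if (is.unsorted(ts)) return("timestamps must be nondecreasing")
    if (ts[1L] < 0 || ts[length(ts)] >= object@sessionDur)
      return("timestamps must lie in [0, sessionDur)")
  }
  if (object@sessionDur <= 0) return("sessionDur must be > 0")
  TRUE
})

#' ClassifierParams: peri-event binning and responsiveness thresholds
#'
#' Parameters of the fixed threshold-crossing responsiveness rule: spikes are
#' binned in 100 ms bins, a 1 s (10-bin) pre-event window supplies the
#' baseline mean and SD for z-normalisation, and a unit is responsive when at
#' least \code{minSupraBins} same-sign bins in the 500 ms response window
#' exceed \code{zThreshold} in absolute value (strict inequality). For
#' freeze-aligned events the baseline is shifted back by \code{baselineOffset}
#' = 1 s (baseline spans -2 to -1 s) so that pre-event freezing/movement does
#' not contaminate the baseline.
#'
#' @slot binWidth bin width, seconds (default 0.1).
#' @slot responseWindow response window after the event, seconds (default 0.5).
#' @slot nBaselineBins number of baseline bins (default 10).
#' @slot zThreshold z criterion (default 1.96).
#' @slot minSupraBins minimum same-sign supra-threshold bins (default 2).
#' @slot baselineOffset seconds before the event at which the baseline window
#'   ends: 0 for CS alignment, 1 for freeze onset/cessation alignment.
#' @slot sdDenominator \code{"n-1"} (default) or \code{"n"} for the baseline
#'   SD.
#'
#' @export
setClass("ClassifierParams",
  representation(
    binWidth = "numeric",
    responseWindow = "numeric",
    nBaselineBins = "integer",
    zThreshold = "numeric",
    minSupraBins = "integer",
    baselineOffset = "numeric",
    sdDenominator = "character"
  )
)

setValidity("ClassifierParams", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  nResp <- object@responseWindow / object@binWidth
  if (abs(nResp - round(nResp)) > 1e-9)
    msg <- c(msg, "responseWindow must be an integer multiple of binWidth")
  if (object@nBaselineBins < 2L)
    msg <- c(msg, "nBaselineBins must be >= 2 (SD needs at least 2 bins)")
  if (object@zThreshold <= 0) msg <- c(msg, "zThreshold must be > 0")
  if (object@minSupraBins < 1L) msg <- c(msg, "minSupraBins must be >= 1")
  if (object@baselineOffset < 0) msg <- c(msg, "baselineOffset must be >= 0")
  if (!object@sdDenominator %in% c("n-1", "n"))
    msg <- c(msg, "sdDenominator must be 'n-1' or 'n'")
  if (length(msg)) msg else TRUE
})

#' PerieventMatrix: events-by-bins spike counts around one event type
#'
#' @slot unitId unit identifier.
#' @slot eventLabel the alignment event type.
#' @slot counts integer matrix, one row per retained event, one column per
#'   time bin (half-open, left-closed).
#' @slot binEdges numeric vector of bin edges relative to the event, seconds
#'   (length \code{ncol(counts) + 1}).
#' @slot droppedEvents event times excluded for incomplete window coverage.
#'
#' @seealso [alignAndBin()], [zscoreProfile()]
#' @export
setClass("PerieventMatrix",
  representation(
    unitId = "character",
    eventLabel = "character",
    counts = "matrix",
    binEdges = "numeric",
    droppedEvents = "numeric"
  )
)

setValidity("PerieventMatrix", function(object) {
  if (length(object@binEdges) != ncol(object@counts) + 1L)
    return("binEdges must have length ncol(counts) + 1")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    return("binEdges must be strictly increasing")
  TRUE
})

#' ZScoreProfile: trial-averaged, baseline-normalised per-bin activity
#'
#' Per-bin spike counts averaged across events, z-scored against the mean and
#' SD of the 10 baseline bins. A profile is degenerate when the baseline SD is
#' zero (e.g. a silent baseline); degenerate profiles are excluded from
#' classification rather than assigned infinite z.
#'
#' @slot unitId unit identifier.
#' @slot eventLabel alignment event type.
#' @slot binMeans trial-averaged counts per bin (spikes/bin).
#' @slot baselineMean,baselineSD mean and SD over the baseline bins.
#' @slot z per-bin z values (NA when degenerate).
#' @slot binEdges bin edges relative to the event, seconds.
#' @slot baselineBins,responseBins column indices of the baseline and
#'   response bins.
#' @slot nEvents number of events averaged.
#' @slot degenerate TRUE when baselineSD == 0.
#'
#' @seealso [zscoreProfile()], [classifyUnit()], [peakResponseBin()]
#' @export
setClass("ZScoreProfile",
  representation(
    unitId = "character",
    eventLabel = "character",
    binMeans = "numeric",
    baselineMean = "numeric",
    baselineSD = "numeric",
    z = "numeric",
    binEdges = "numeric",
    baselineBins = "integer",
    responseBins = "integer",
    nEvents = "integer",
    degenerate = "logical"
  )
)

#' ResponsivenessCall: one unit's responsiveness to one event type
#'
#' @slot unitId unit identifier.
#' @slot eventLabel alignment event type.
#' @slot responsive TRUE when the threshold-crossing rule is met.
#' @slot direction \code{"excited"}, \code{"inhibited"}, or \code{"none"}.
#' @slot supraBins response-bin indices (1-based within the response window)
#'   that exceed the threshold in the reported direction.
#'
#' @seealso [classifyUnit()], [classifyAll()]
#' @export
setClass("ResponsivenessCall",
  representation(
    unitId = "character",
    eventLabel = "character",
    responsive = "logical",
    direction = "character",
    supraBins = "integer"
  )
)

setValidity("ResponsivenessCall", function(object) {
  if (!object@direction %in% c("excited", "inhibited", "none"))
    return("direction must be 'excited', 'inhibited' or 'none'")
  if (object@responsive && length(object@supraBins) < 1L)
    return("responsive calls must carry supra-threshold bins")
  TRUE
})

#' RateModulation: event-locked multiplicative rate change for the simulator
#'
#' A boxcar rate modulation: for \code{duration} seconds starting
#' \code{latency} seconds after each occurrence of \code{eventLabel}, the
#' unit's firing rate is multiplied by \code{multiplier} (values < 1 model
#' firing-rate decreases such as those seen at freezing onset).
#'
#' @slot eventLabel one of \code{"CS_ON"}, \code{"FREEZE_ON"},
#'   \code{"FREEZE_OFF"}.
#' @slot multiplier dimensionless rate factor, > 0.
#' @slot latency seconds from the event to modulation onset, >= 0.
#' @slot duration modulation duration, seconds, > 0.
#'
#' @seealso [simulateSpikeTrain()]
#' @export
setClass("RateModulation",
  representation(eventLabel = "character", multiplier = "numeric",
                 latency = "numeric", duration = "numeric")
)

setValidity("RateModulation", function(object) {
  msg <- character()
  if (!object@eventLabel %in% .MODULATION_LABELS)
    msg <- c(msg, sprintf("eventLabel must be one of %s",
                          paste(.MODULATION_LABELS, collapse = ", ")))
  if (object@multiplier <= 0) msg <- c(msg, "multiplier must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@latency < 0) msg <- c(msg, "latency must be >= 0")
  if (length(msg)) msg else TRUE
})

#' UnitSpec: ground-truth description of one synthetic unit
#'
#' @slot unitId unit identifier.
#' @slot baselineRate baseline firing rate, Hz, > 0.
#' @slot modulations list of [RateModulation-class] (possibly empty).
#'
#' @seealso [simulateSpikeTrain()], [simulateCohort()]
#' @export
setClass("UnitSpec",
  representation(unitId = "character", baselineRate = "numeric",
                 modulations = "list")
)

setValidity("UnitSpec", function(object) {
  if (object@baselineRate <= 0) return("baselineRate must be > 0")
  ok <- vapply(object@modulations, is, logical(1), class2 = "RateModulation")
  if (!all(ok)) return("modulations must all be RateModulation objects")
  TRUE
})

#' BehaviorModelParams: two-state freeze/move Markov model parameters
#'
#' Transition rates (per second) of a continuous-time two-state Markov
#' process, conditional on whether a CS is playing, emulating CS-evoked
#' freezing. Dwell intervals shorter than \code{minBout} are merged into the
#' surrounding state after simulation.
#'
#' @slot moveToFreezeCS,freezeToMoveCS rates during CS, per second.
#' @slot moveToFreezeOut,freezeToMoveOut rates outside CS, per second.
#' @slot minBout minimum dwell duration retained, seconds.
#'
#' @seealso [simulateBehavior()]
#' @export
setClass("BehaviorModelParams",
  representation(
    moveToFreezeCS = "numeric",
    freezeToMoveCS = "numeric",
    moveToFreezeOut = "numeric",
    freezeToMoveOut = "numeric",
    minBout = "numeric"
  )
)

setValidity("BehaviorModelParams", function(object) {
  r <- c(object@moveToFreezeCS, object@freezeToMoveCS,
         object@moveToFreezeOut, object@freezeToMoveOut)
  if (any(r < 0) || any(!is.finite(r))) return("rates must be finite and >= 0")
  if (object@minBout < 0) return("minBout must be >= 0")
  TRUE
})

#' FreezeEventSeries: freezing onsets and cessations with exclusion log
#'
#' @slot onsets times of move-to-freeze transitions, seconds, sorted.
#' @slot cessations times of freeze-to-move transitions, seconds, sorted.
#' @slot exclusionLog data.frame (type, time_s, reason) of dropped events.
#'
#' @seealso [extractFreezeEvents()]
#' @export
setClass("FreezeEventSeries",
  representation(onsets = "numeric", cessations = "numeric",
                 exclusionLog = "data.frame")
)

setValidity("FreezeEventSeries", function(object) {
  if (is.unsorted(object@onsets) || is.unsorted(object@cessations))
    return("onsets and cessations must be sorted")
  TRUE
})

#' CohortDesign: design of a synthetic multi-group recording cohort
#'
#' Each row of \code{groups} describes one group of units: how many, the
#' log-normal baseline-rate distribution (given by its mean rate in Hz and the
#' log-scale SD), what fraction carry a CS-onset modulation and what fraction
#' carry a freeze-cessation modulation, and the effect multipliers. Exactly
#' \code{floor(fraction * n)} units per group carry each modulation, and
#' ground-truth labels are retained for recovery tests.
#'
#' @slot groups data.frame with columns \code{group}, \code{n_units},
#'   \code{rate_mean_hz}, \code{rate_sdlog}, \code{frac_cs_on},
#'   \code{frac_freeze_off}, \code{cs_multiplier}, \code{freeze_multiplier}.
#' @slot behaviorParams a [BehaviorModelParams-class].
#' @slot seed master seed for the cohort.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("CohortDesign",
  representation(groups = "data.frame", behaviorParams = "BehaviorModelParams",
                 seed = "integer")
)

setValidity("CohortDesign", function(object) {
  g <- object@groups
  need <- c("group", "n_units", "rate_mean_hz", "rate_sdlog", "frac_cs_on",
            "frac_freeze_off", "cs_multiplier", "freeze_multiplier")
  if (!all(need %in% names(g)))
    return(sprintf("groups must have columns: %s", paste(need, collapse = ", ")))
  if (any(g$n_units < 1L)) return("each group needs n_units >= 1")
  fr <- c(g$frac_cs_on, g$frac_freeze_off)
  if (any(fr < 0) || any(fr > 1)) return("fractions must lie in [0, 1]")
  if (any(duplicated(g$group))) return("group labels must be unique")
  TRUE
})
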