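#' Accessors for perifreeze classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{events()} and \code{totalDur()} for timelines, \code{bouts()} and
#' \code{sessionDur()} for behaviour traces and spike trains,
#' \code{timestamps()} and \code{unitId()} for spike trains, \code{zScores()}
#' for z profiles, \code{onsets()}/\code{cessations()} for freeze event
#' series.
#'
#' @param x an object of the documented class.
#' @return the slot contents (a data.frame or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("totalDur", function(x) standardGeneric("totalDur"))

#' @rdname accessors
#' @export
setGeneric("bouts", function(x) standardGeneric("bouts"))

#' @rdname accessors
#' @export
setGeneric("sessionDur", function(x) standardGeneric("sessionDur"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("cessations", function(x) standardGeneric("cessations"))

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname accessors
#' @export
setMethod("events", "SessionTimeline", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("totalDur", "SessionTimeline", function(x) x@totalDur)

#' @rdname accessors
#' @export
setMethod("bouts", "BehaviorTrace", function(x) x@bouts)

#' @rdname accessors
#' @export
setMethod("sessionDur", "BehaviorTrace", function(x) x@sessionDur)

#' @rdname accessors
#' @export
setMethod("sessionDur", "SpikeTrain", function(x) x@sessionDur)

#' @rdname accessors
#' @export
setMethod("timestamps", "SpikeTrain", function(x) x@timestamps)

#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(x) x@unitId)

#' @rdname accessors
#' @export
setMethod("unitId", "UnitSpec", function(x) x@unitId)

#' @rdname accessors
#' @export
setMethod("zScores", "ZScoreProfile", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("onsets", "FreezeEventSeries", function(x) x@onsets)

#' @rdname accessors
#' @export
setMethod("cessations", "FreezeEventSeries", function(x) x@cessations)

#' @rdname accessors
#' @export
setMethod("exclusionLog", "FreezeEventSeries", function(x) x@exclusionLog)

setMethod("show", "SessionProtocol", function(object) {
  cat(sprintf("SessionProtocol <%s>: %d CS x %gs (%d reinforced), baseline %gs, post %gs,\n  inter-trial [%g, %g]s, US %gs/%g mA, CS %g dB\n",
              object@kind, object@csCount, object@csDur, sum(object@usFlags),
              object@baselineDur, object@postDur,
              object@intervalRange[1L], object@intervalRange[2L],
              object@usDur, object@usAmp_mA, object@csLevel_dB))
  invisible(object)
})

setMethod("show", "SessionTimeline", function(object) {
  cat(sprintf("SessionTimeline <%s>: %d events over %.1f s (%d CS, %d US)\n",
              object@protocol@kind, nrow(object@events), object@totalDur,
              sum(object@events$label == "CS_ON"),
              sum(object@events$label == "US_ON")))
  invisible(object)
})

setMethod("show", "BehaviorTrace", function(object) {
  tot <- sum(object@bouts$end_s - object@bouts$start_s)
  cat(sprintf("BehaviorTrace: %d freezing bouts, %.1f of %.1f s frozen (%.1f%%)\n",
              nrow(object@bouts), tot, object@sessionDur,
              if (object@sessionDur > 0) 100 * tot / object@sessionDur else NA))
  invisible(object)
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (%.2f Hz)\n",
              object@unitId, length(object@timestamps), object@sessionDur,
              length(object@timestamps) / object@sessionDur))
  invisible(object)
})

setMethod("show", "ZScoreProfile", function(object) {
  if (object@degenerate) {
    cat(sprintf("ZScoreProfile '%s' / %s: degenerate (baseline SD = 0)\n",
                object@unitId, object@eventLabel))
  } else {
    zr <- object@z[object@responseBins]
    cat(sprintf("ZScoreProfile '%s' / %s: %d events, peak response z = %.2f\n",
                object@unitId, object@eventLabel, object@nEvents,
                zr[which.max(abs(zr))]))
  }
  invisible(object)
})

setMethod("show", "ResponsivenessCall", function(object) {
  cat(sprintf("ResponsivenessCall '%s' / %s: %s%s\n",
              object@unitId, object@eventLabel,
              if (object@responsive) "responsive" else "not responsive",
              if (object@responsive)
                sprintf(" (%s; bins %s)", object@direction,
                        paste(object@supraBins, collapse = ",")) else ""))
  invisible(object)
})

setMethod("show", "FreezeEventSeries", function(object) {
  cat(sprintf("FreezeEventSeries: %d onsets, %d cessations (%d excluded)\n",
              length(object@onsets), length(object@cessations),
              nrow(object@exclusionLog)))
  invisible(object)
})
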