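#' Score freezing percentages per session epoch
#'
#' Samples the instantaneous freeze/move state every \code{sampleInterval}
#' seconds within each epoch and converts counts to percentages as
#' 100 x (freezing observations / total observations), emulating manual
#' scoring every 5 s. Sampling uses the end of each interval: observations
#' fall at epoch_start + k * sampleInterval for k = 1..floor(epoch_dur /
#' sampleInterval), so the epoch-start instant is never counted twice across
#' adjacent epochs. Epochs are derived from the timeline: the pre-CS baseline,
#' each CS period (\code{CS1}, \code{CS2}, ...), and all CS periods pooled
#' (\code{CS_all}).
#'
#' @param trace a [BehaviorTrace-class].
#' @param timeline a [SessionTimeline-class].
#' @param sampleInterval sampling interval, seconds (default 5).
#' @return data.frame with columns \code{epoch}, \code{n_obs},
#'   \code{n_frozen}, \code{percent}; \code{percent} is NA (not 0) when an
#'   epoch is shorter than one sampling interval.
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("FRF"), seed = 1)
#' tr <- BehaviorTrace(start = 0, end = 90, sessionDur = totalDur(tl))
#' scoreFreezing(tr, tl)
scoreFreezing <- function(trace, timeline, sampleInterval = 5) {
  stopIfNot(sampleInterval > 0, "sampleInterval must be > 0")
  csOn <- eventTimes(timeline, "CS_ON")
  csOff <- eventTimes(timeline, "CS_OFF")
  epochs <- data.frame(
    epoch = c("baseline", sprintf("CS%d", seq_along(csOn))),
    start = c(0, csOn),
    end = c(if (length(csOn)) csOn[1L] else timeline@totalDur, csOff)
  )
  b <- trace@bouts
  scoreEpoch <- function(start, end) {
    k <- floor((end - start) / sampleInterval)
    if (k < 1L) return(c(n = 0L, frozen = 0L))
    pts <- start + seq_len(k) * sampleInterval
    c(n = k, frozen = sum(inAnyInterval(pts, b$start_s, b$end_s)))
  }
  sc <- t(mapply(scoreEpoch, epochs$start, epochs$end))
  res <- data.frame(epoch = epochs$epoch, n_obs = as.integer(sc[, "n"]),
                    n_frozen = as.integer(sc[, "frozen"]))
  csRows <- grepl("^CS\\d+$", res$epoch)
  res <- rbind(res, data.frame(epoch = "CS_all",
                               n_obs = sum(res$n_obs[csRows]),
                               n_frozen = sum(res$n_frozen[csRows])))
  res$percent <- ifelse(res$n_obs > 0, 100 * res$n_frozen / res$n_obs, NA_real_)
  rownames(res) <- NULL
  res
}

#' Extract freezing onset and cessation events
#'
#' Freezing onset is the transition from movement to no visible movement
#' (a bout start); freezing cessation is the transition from freezing back to
#' movement (a bout end). Events with less than \code{preWindow} seconds of
#' session before them cannot support the shifted pre-event baseline and are
#' excluded and logged; exclusions never alter the times of retained events.
#' Optionally, consecutive events of the same type closer than
#' \code{minSeparation} are thinned (keeping the earlier event), and events
#' falling inside CS periods can be excluded.
#'
#' @param trace a [BehaviorTrace-class].
#' @param timeline a [SessionTimeline-class].
#' @param preWindow seconds of session required before an event (default 2,
#'   the span of the shifted baseline window for freeze-aligned analysis).
#' @param minSeparation minimum separation between consecutive retained
#'   events of one type, seconds (default 0 = keep all).
#' @param excludeDuringCS drop events falling inside a CS period (default
#'   FALSE).
#' @return a [FreezeEventSeries-class].
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("RETRIEVAL"), seed = 1)
#' tr <- BehaviorTrace(start = c(100, 200), end = c(150, 230),
#'                     sessionDur = totalDur(tl))
#' extractFreezeEvents(tr, tl)
extractFreezeEvents <- function(trace, timeline, preWindow = 2,
                                minSeparation = 0, excludeDuringCS = FALSE) {
  b <- trace@bouts
  log <- data.frame(type = character(), time_s = numeric(),
                    reason = character())
  filterEvents <- function(times, type) {
    early <- times < preWindow
    if (any(early))
      log <<- rbind(log, data.frame(type = type, time_s = times[early],
                                    reason = sprintf("< %g s of session before event", preWindow)))
    times <- times[!early]
    if (excludeDuringCS) {
      inCS <- inAnyInterval(times, eventTimes(timeline, "CS_ON"),
                            eventTimes(timeline, "CS_OFF"))
      if (any(inCS))
        log <<- rbind(log, data.frame(type = type, time_s = times[inCS],
                                      reason = "inside CS period"))
      times <- times[!inCS]
    }
    if (minSeparation > 0 && length(times) > 1L) {
      keep <- logical(length(times))
      last <- -Inf
      for (i in seq_along(times)) {
        keep[i] <- times[i] - last >= minSeparation
        if (keep[i]) last <- times[i]
      }
      if (any(!keep))
        log <<- rbind(log, data.frame(type = type, time_s = times[!keep],
                                      reason = sprintf("< %g s after previous event", minSeparation)))
      times <- times[keep]
    }
    times
  }
  on <- filterEvents(b$start_s, "onset")
  off <- filterEvents(b$end_s, "cessation")
  new("FreezeEventSeries", onsets = on, cessations = off, exclusionLog = log)
}
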