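#' Construct a SessionProtocol
#'
#' Low-level constructor; most users want [defaultProtocol()] which supplies
#' the standard parameterization for each session kind.
#'
#' @param kind session kind: \code{"PRF"}, \code{"FRF"}, \code{"CS_ONLY"} or
#'   \code{"RETRIEVAL"}.
#' @param baselineDur baseline before the first CS, seconds.
#' @param csDur CS duration, seconds.
#' @param csCount number of CS presentations.
#' @param usFlags logical vector (one per CS); TRUE = US co-terminates.
#' @param usDur US duration, seconds.
#' @param intervalRange length-2 numeric (min, max) seconds between CS offset
#'   and the next CS onset.
#' @param postDur no-stimulus period after the last trial, seconds.
#' @param usAmp_mA shock amplitude, mA (metadata).
#' @param csLevel_dB tone level, dB (metadata).
#' @return a validated [SessionProtocol-class].
#' @export
#' @examples
#' SessionProtocol("FRF", csCount = 3, usFlags = rep(TRUE, 3),
#'                 intervalRange = c(60, 90))
SessionProtocol <- function(kind, baselineDur = 180, csDur = 30, csCount,
                            usFlags, usDur = 2, intervalRange, postDur = 120,
                            usAmp_mA = 0.6, csLevel_dB = 75) {
  new("SessionProtocol", kind = kind, baselineDur = baselineDur,
      csDur = csDur, csCount = as.integer(csCount), usFlags = usFlags,
      usDur = usDur, intervalRange = as.numeric(intervalRange),
      postDur = postDur, usAmp_mA = usAmp_mA, csLevel_dB = csLevel_dB)
}

#' Standard session protocols
#'
#' Returns the standard parameterization for each session kind. All sessions
#' start with a 180 s baseline and use a 30 s, 75 dB white-noise CS; the US is
#' a 2 s, 0.6 mA footshock that co-terminates with reinforced CS trials.
#'
#' \describe{
#'   \item{FRF}{fully reinforced: 3 CS, all reinforced, 60-90 s variable
#'     inter-CS interval, 120 s post period.}
#'   \item{PRF}{partially reinforced: 6 CS in the order CS+US, CS+US, CS-noUS,
#'     CS-noUS, CS+US, CS-noUS, 15-60 s inter-stimulus interval, 120 s post
#'     period. PRF and FRF thus deliver the same number (3) of CS-US
#'     pairings.}
#'   \item{CS_ONLY}{6 CS, none reinforced, matching PRF timing.}
#'   \item{RETRIEVAL}{6 CS, none reinforced, 20-60 s interval, 20 s post
#'     period.}
#' }
#'
#' @param kind one of \code{"PRF"}, \code{"FRF"}, \code{"CS_ONLY"},
#'   \code{"RETRIEVAL"}.
#' @return a [SessionProtocol-class].
#' @export
#' @examples
#' defaultProtocol("PRF")
#' defaultProtocol("RETRIEVAL")
defaultProtocol <- function(kind = c("PRF", "FRF", "CS_ONLY", "RETRIEVAL")) {
  kind <- match.arg(kind)
  switch(kind,
    FRF = SessionProtocol("FRF", csCount = 3,
                          usFlags = rep(TRUE, 3),
                          intervalRange = c(60, 90)),
    PRF = SessionProtocol("PRF", csCount = 6,
                          usFlags = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                          intervalRange = c(15, 60)),
    CS_ONLY = SessionProtocol("CS_ONLY", csCount = 6,
                              usFlags = rep(FALSE, 6),
                              intervalRange = c(15, 60)),
    RETRIEVAL = SessionProtocol("RETRIEVAL", csCount = 6,
                                usFlags = rep(FALSE, 6),
                                intervalRange = c(20, 60), postDur = 20)
  )
}

#' Build a session timeline from a protocol
#'
#' Realizes a [SessionProtocol-class] into an ordered event schedule. The
#' first CS starts at \code{baselineDur}; inter-trial intervals (CS offset to
#' next CS onset) are drawn uniform-continuous from the protocol's
#' \code{intervalRange} under \code{seed}; on reinforced trials the US
#' co-terminates with the CS (US_OFF == CS_OFF, US_ON == CS_OFF - usDur).
#' Identical (protocol, seed) give identical timelines.
#'
#' @param protocol a [SessionProtocol-class].
#' @param seed integer seed for the interval draws.
#' @return a [SessionTimeline-class].
#' @export
#' @examples
#' tl <- buildTimeline(defaultProtocol("FRF"), seed = 1)
#' events(tl)
buildTimeline <- function(protocol, seed) {
  validObject(protocol)
  n <- protocol@csCount
  gaps <- if (n > 1L) {
    withSeed(seed, runif(n - 1L, protocol@intervalRange[1L],
                         protocol@intervalRange[2L]))
  } else numeric()
  csOn <- protocol@baselineDur +
    cumsum(c(0, gaps + protocol@csDur))
  csOff <- csOn + protocol@csDur
  ev <- data.frame(label = character(), time_s = numeric())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- c("CS_ON", "CS_OFF")
    tms <- c(csOn[i], csOff[i])
    if (protocol@usFlags[i]) {
      lab <- c(lab, "US_ON", "US_OFF")
      tms <- c(tms, csOff[i] - protocol@usDur, csOff[i])
    }
    rows[[i]] <- data.frame(label = lab, time_s = tms)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s, match(ev$label, .EVENT_LABELS)), , drop = FALSE]
  rownames(ev) <- NULL
  new("SessionTimeline", protocol = protocol, events = ev,
      totalDur = max(ev$time_s) + protocol@postDur)
}

#' Check a timeline against its structural invariants
#'
#' Returns a character vector of violation descriptions (empty when the
#' timeline is well formed). Checked invariants: events sorted by time; each
#' CS_ON paired with a CS_OFF exactly \code{csDur} later; US co-termination on
#' reinforced trials (US_OFF == CS_OFF, US_ON == US_OFF - usDur); first CS_ON
#' at \code{baselineDur}; inter-trial gaps within \code{intervalRange};
#' \code{totalDur} == last event time + \code{postDur}. Each violation names
#' the invariant and the offending event or trial index.
#'
#' @param timeline a [SessionTimeline-class].
#' @param tol numeric comparison tolerance, seconds.
#' @return character vector of violations; empty iff all invariants hold.
#' @export
#' @examples
#' validateTimeline(buildTimeline(defaultProtocol("PRF"), seed = 7))
validateTimeline <- function(timeline, tol = 1e-9) {
  ev <- timeline@events
  p <- timeline@protocol
  bad <- character()
  if (is.unsorted(ev$time_s))
    bad <- c(bad, sprintf("ordering: events not sorted by time (first descent at index %d)",
                          which(diff(ev$time_s) < 0)[1L] + 1L))
  csOn <- ev$time_s[ev$label == "CS_ON"]
  csOff <- ev$time_s[ev$label == "CS_OFF"]
  usOn <- ev$time_s[ev$label == "US_ON"]
  usOff <- ev$time_s[ev$label == "US_OFF"]
  if (length(csOn) != p@csCount)
    bad <- c(bad, sprintf("cs-count: %d CS_ON events, protocol says %d",
                          length(csOn), p@csCount))
  if (length(csOn) != length(csOff)) {
    bad <- c(bad, "cs-pairing: unequal CS_ON and CS_OFF counts")
  } else if (length(csOn) && any(abs(csOff - csOn - p@csDur) > tol)) {
    i <- which(abs(csOff - csOn - p@csDur) > tol)[1L]
    bad <- c(bad, sprintf("cs-duration: CS trial %d is not csDur long", i))
  }
  nFlag <- sum(p@usFlags[seq_len(min(p@csCount, length(csOn)))])
  if (length(usOn) != nFlag || length(usOff) != nFlag) {
    bad <- c(bad, sprintf("us-count: %d US_ON / %d US_OFF events, protocol flags %d",
                          length(usOn), length(usOff), nFlag))
  } else if (nFlag > 0 && length(csOff) == p@csCount) {
    flaggedOff <- csOff[p@usFlags]
    if (any(abs(usOff - flaggedOff) > tol)) {
      i <- which(abs(usOff - flaggedOff) > tol)[1L]
      bad <- c(bad, sprintf("co-termination: US_OFF != CS_OFF on reinforced trial %d", i))
    }
    if (any(abs(usOff - usOn - p@usDur) > tol)) {
      i <- which(abs(usOff - usOn - p@usDur) > tol)[1L]
      bad <- c(bad, sprintf("us-duration: US %d is not usDur long", i))
    }
  }
  if (length(csOn) && abs(csOn[1L] - p@baselineDur) > tol)
    bad <- c(bad, "baseline: first CS_ON does not fall at baselineDur")
  if (length(csOn) > 1L && length(csOff) == length(csOn)) {
    gap <- csOn[-1L] - csOff[-length(csOff)]
    out <- gap < p@intervalRange[1L] - tol | gap > p@intervalRange[2L] + tol
    if (any(out))
      bad <- c(bad, sprintf("interval-range: gap before CS trial %d outside [%g, %g]",
                            which(out)[1L] + 1L, p@intervalRange[1L],
                            p@intervalRange[2L]))
  }
  if (nrow(ev) && abs(timeline@totalDur - (max(ev$time_s) + p@postDur)) > tol)
    bad <- c(bad, "total-duration: totalDur != last event time + postDur")
  bad
}

#' CS onset (or other event) times of a timeline
#'
#' @param timeline a [SessionTimeline-class].
#' @param label event label, default \code{"CS_ON"}.
#' @return numeric vector of event times in seconds.
#' @export
#' @examples
#' eventTimes(buildTimeline(defaultProtocol("FRF"), seed = 1))
eventTimes <- function(timeline, label = "CS_ON") {
  ev <- timeline@events
  ev$time_s[ev$label == label]
}
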