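## Critical-window sonar-jamming assessment. For each bat call produced
## between search phases: the bat-moth distance at the call midpoint
## gives the echo return time (two-way travel at 343 m/s); the critical
## window is the echo return time +/- 2 ms; an echo is overlapped iff
## any moth click arrival time (one-way travel from the click's
## emission distance) falls inside the closed window.

CRITICAL_HALF_WINDOW_S <- 0.002

#' Echo return time of a bat call
#'
#' Time at which the echo of a call returns to the bat, assuming a speed
#' of sound of 343 m/s and a travel distance of twice the bat-moth
#' distance (out to the moth and back).
#'
#' @param call_midpoint_s call midpoint time (s).
#' @param distance_m bat-moth distance at emission (m), >= 0.
#' @return echo return time (s).
#' @examples
#' echoReturnTime(1.0, 1.715)   # 1.010 s
#' @export
echoReturnTime <- function(call_midpoint_s, distance_m) {
  if (any(distance_m < 0)) stop("distance_m must be >= 0")
  call_midpoint_s + 2 * distance_m / SPEED_OF_SOUND
}

#' Arrival time of a moth click at the bat
#'
#' One-way travel time from the moth to the bat, with the distance
#' evaluated at the click's emission instant.
#'
#' @param click_s click emission time (s).
#' @param distance_m bat-moth distance at emission (m), >= 0.
#' @return arrival time (s).
#' @examples
#' clickArrivalTime(2.0, 0.343)   # 2.001 s
#' @export
clickArrivalTime <- function(click_s, distance_m) {
  if (any(distance_m < 0)) stop("distance_m must be >= 0")
  click_s + distance_m / SPEED_OF_SOUND
}

#' Select the attack-phase calls of an interaction
#'
#' Calls produced after the search phase ended (preceding IPI below
#' 50 ms) and before the next search phase began (preceding IPI at or
#' above 50 ms again). By default only the first attack bout is used;
#' \code{allBouts = TRUE} pools every below-50 ms call.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param allBouts pool all attack bouts instead of the first.
#' @return data.frame with columns \code{index}, \code{onset_s},
#'   \code{midpoint_s}; zero rows when the bat never leaves search.
#' @export
selectAttackCalls <- function(stream, allBouts = FALSE) {
  idx <- attackCallIndices(stream, allBouts = allBouts)
  data.frame(index = idx,
             onset_s = stream@callOnsets[idx],
             midpoint_s = stream@callOnsets[idx] +
               stream@callDurations[idx] / 2)
}

#' Critical-window jamming assessment of one interaction
#'
#' For each selected attack-phase call, computes the bat-moth distance
#' at the call midpoint from the smoothed paths, the echo return time,
#' and the +/- 2 ms critical window; the echo is scored as potentially
#' jammed iff any moth click arrival time falls inside the closed
#' window. Calls (or clicks) whose times lack 3-D coverage are excluded
#' with a recorded reason rather than extrapolated. An interaction with
#' zero usable echoes yields \code{fractionUnaffected = NA}, not an
#' error.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param batPath,mothPath \linkS4class{SmoothedPath} objects.
#' @param allBouts see \code{\link{selectAttackCalls}}.
#' @return A \linkS4class{JammingReport}.
#' @export
assessJamming <- function(stream, batPath, mothPath, allBouts = FALSE) {
  stopifnot(is(stream, "EventStream"),
            is(batPath, "SmoothedPath"), is(mothPath, "SmoothedPath"))
  lo <- max(batPath@range[1], mothPath@range[1])
  hi <- min(batPath@range[2], mothPath@range[2])
  dist_at <- function(t) {
    sqrt(rowSums((positionAt(batPath, t) - positionAt(mothPath, t))^2))
  }

  clicks <- stream@clickTimes
  clickCovered <- clicks >= lo & clicks <= hi
  arrivals <- if (any(clickCovered))
    clickArrivalTime(clicks[clickCovered], dist_at(clicks[clickCovered]))
  else numeric()

  calls <- selectAttackCalls(stream, allBouts = allBouts)
  n <- nrow(calls)
  windows <- data.frame(
    call_index = calls$index, call_midpoint_s = calls$midpoint_s,
    distance_m = NA_real_, echo_return_s = NA_real_,
    window_lo_s = NA_real_, window_hi_s = NA_real_,
    overlapped = NA, excluded = FALSE, reason = "",
    stringsAsFactors = FALSE)
  if (n > 0) {
    covered <- calls$midpoint_s >= lo & calls$midpoint_s <= hi
    windows$excluded <- !covered
    windows$reason[!covered] <- "no 3-D coverage at call time"
    if (any(covered)) {
      d <- dist_at(calls$midpoint_s[covered])
      ret <- echoReturnTime(calls$midpoint_s[covered], d)
      windows$distance_m[covered] <- d
      windows$echo_return_s[covered] <- ret
      windows$window_lo_s[covered] <- ret - CRITICAL_HALF_WINDOW_S
      windows$window_hi_s[covered] <- ret + CRITICAL_HALF_WINDOW_S
      windows$overlapped[covered] <- vapply(ret, function(r) {
        any(arrivals >= r - CRITICAL_HALF_WINDOW_S &
            arrivals <= r + CRITICAL_HALF_WINDOW_S)
      }, logical(1))
    }
  }
  used <- !windows$excluded
  nUsed <- sum(used)
  nUnaff <- sum(used & !windows$overlapped, na.rm = TRUE)
  new("JammingReport", interactionId = stream@interactionId,
      windows = windows, nEchoesUsed = as.integer(nUsed),
      nUnaffected = as.integer(nUnaff),
      fractionUnaffected = if (nUsed > 0) nUnaff / nUsed else NA_real_)
}
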