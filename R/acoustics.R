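## Acoustic event statistics: IPI series, attack-phase labels, the IPI
## immediately preceding the first moth click, pulse repetition rates,
## and call counts between search phases.

#' Inter-pulse intervals of a call sequence
#'
#' The inter-pulse interval (IPI) is the time elapsed between the onsets
#' of two sequential bat calls. One record is produced per consecutive
#' call pair; the record's time is the onset of the later call.
#'
#' @param stream an \linkS4class{EventStream}.
#' @return data.frame with columns \code{time_s}, \code{ipi_ms},
#'   \code{phase} (see \code{\link{classifyPhase}}); zero rows for fewer
#'   than two calls.
#' @examples
#' s <- EventStream(callOnsets = c(0, 0.05, 0.09))
#' computeIpis(s)   # IPIs 50 and 40 ms
#' @export
computeIpis <- function(stream) {
  stopifnot(is(stream, "EventStream"))
  on <- stream@callOnsets
  if (length(on) < 2L)
    return(data.frame(time_s = numeric(), ipi_ms = numeric(),
                      phase = character(), stringsAsFactors = FALSE))
  ipi <- 1000 * diff(on)
  data.frame(time_s = on[-1], ipi_ms = ipi,
             phase = vapply(ipi, classifyPhase, character(1)),
             stringsAsFactors = FALSE)
}

#' Attack-phase label of an inter-pulse interval
#'
#' Bat attack phases in terms of IPI: buzz below 8 ms, late approach
#' [8, 21) ms, early approach [21, 50) ms, search at or above 50 ms.
#' The field-reported phase ranges leave the values 7-8, 20-21 and 49-50 ms
#' unassigned; this function closes those gaps with half-open intervals,
#' consistent with the approach phase starting below 50 ms IPI.
#'
#' @param ipi_ms positive IPI in milliseconds (vectorised).
#' @return character vector of phase labels.
#' @examples
#' classifyPhase(c(60, 30, 15, 6))
#' @export
classifyPhase <- function(ipi_ms) {
  if (any(!is.finite(ipi_ms)) || any(ipi_ms <= 0))
    stop("ipi_ms must be positive and finite")
  out <- character(length(ipi_ms))
  out[ipi_ms < 8] <- "buzz"
  out[ipi_ms >= 8 & ipi_ms < 21] <- "late_approach"
  out[ipi_ms >= 21 & ipi_ms < 50] <- "early_approach"
  out[ipi_ms >= 50] <- "search"
  out
}

#' Pulse repetition rate at a given IPI
#'
#' Number of calls (pulses) that would occur in one second at a given
#' inter-pulse interval.
#'
#' @param ipi_ms positive IPI in milliseconds (vectorised).
#' @return pulses per second, \code{1000 / ipi_ms}.
#' @examples
#' pulseRepetitionRate(20)   # 50 pulses/s
#' @export
pulseRepetitionRate <- function(ipi_ms) {
  if (any(!is.finite(ipi_ms)) || any(ipi_ms <= 0))
    stop("ipi_ms must be positive and finite")
  1000 / ipi_ms
}

#' IPI immediately preceding the first moth click
#'
#' The IPI between the two bat calls immediately preceding the first
#' detected moth click: the last call pair whose second onset is at or
#' before the first click time (ties at exact equality count as
#' preceding).
#'
#' @param stream an \linkS4class{EventStream}.
#' @return \code{NULL} if there are no clicks or fewer than two calls
#'   precede the first click; otherwise a list with \code{ipi_ms} and
#'   \code{phase}.
#' @examples
#' s <- EventStream(callOnsets = c(0, 0.060, 0.104),
#'                  clickTimes = 0.110)
#' ipiBeforeFirstClick(s)   # 44 ms, early approach
#' @export
ipiBeforeFirstClick <- function(stream) {
  stopifnot(is(stream, "EventStream"))
  if (length(stream@clickTimes) == 0L) return(NULL)
  t1 <- stream@clickTimes[1]
  on <- stream@callOnsets[stream@callOnsets <= t1]
  if (length(on) < 2L) return(NULL)
  ipi <- 1000 * (on[length(on)] - on[length(on) - 1L])
  list(ipi_ms = ipi, phase = classifyPhase(ipi))
}

#' Clicks emitted strictly before a time point
#'
#' Used, e.g., to restrict analyses to interactions where clicks were
#' detected before the bat-moth minimum distance.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param t_s time point (s); the comparison is strict.
#' @return numeric vector of click times < \code{t_s}.
#' @export
clicksBeforeTime <- function(stream, t_s) {
  stopifnot(is(stream, "EventStream"), is.finite(t_s))
  stream@clickTimes[stream@clickTimes < t_s]
}

#' Number of calls between search phases
#'
#' Counts echolocation calls from the start of the approach phase (first
#' call whose preceding IPI falls below 50 ms, inclusive of that call)
#' until the bat returns to search phase (preceding IPI at or above
#' 50 ms again) or the stream ends. Fewer calls indicate an aborted
#' attack (no terminal buzz). Returns 0 if no IPI ever drops below
#' 50 ms.
#'
#' @param stream an \linkS4class{EventStream}.
#' @return integer call count for the first attack bout.
#' @examples
#' # IPI sequence 60, 40, 30, 10, 6, 70 ms -> 4 calls counted
#' on <- cumsum(c(0, 60, 40, 30, 10, 6, 70)) / 1000
#' countCallsBetweenSearchPhases(EventStream(callOnsets = on))
#' @export
countCallsBetweenSearchPhases <- function(stream) {
  idx <- attackCallIndices(stream, allBouts = FALSE)
  length(idx)
}

## Indices (into callOnsets) of calls whose preceding IPI is below
## 50 ms, for the first attack bout or for all bouts pooled. A call
## belongs to a bout iff the interval ending at it is < 50 ms; the bout
## ends when the preceding IPI first returns to >= 50 ms.
attackCallIndices <- function(stream, allBouts = FALSE) {
  stopifnot(is(stream, "EventStream"))
  on <- stream@callOnsets
  if (length(on) < 2L) return(integer())
  ipi <- 1000 * diff(on)
  inAttack <- ipi < 50            # interval i ends at call i + 1
  if (!any(inAttack)) return(integer())
  if (allBouts) return(which(inAttack) + 1L)
  first <- which(inAttack)[1]
  stop_at <- which(!inAttack & seq_along(ipi) > first)
  last <- if (length(stop_at)) stop_at[1] - 1L else length(ipi)
  seq.int(first, last) + 1L
}
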