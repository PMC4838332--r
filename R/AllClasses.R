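#' @import methods
#' @importFrom stats predict runif rnorm qbeta pbinom dhyper uniroot optimize
#'   t.test wilcox.test ks.test quantile splinefun smooth.spline setNames
#'   rmultinom sd median
NULL

SPECIES_LEVELS <- c("P_roseicapitis", "C_martini", "other")
TREATMENT_LEVELS <- c("T+", "T-", "S")
OUTCOME_LEVELS <- c("non_capture", "capture_drop", "consume")
EVASION_LEVELS <- c("dive", "turn_away", "no_evasion")
PHASE_LEVELS <- c("search", "early_approach", "late_approach", "buzz")

## Speed of sound (m/s) and 3-D reconstruction contact floor (m) used
## throughout the jamming and kinematics code.
SPEED_OF_SOUND <- 343
CONTACT_FLOOR_M <- 0.037

#' Trajectory3D: time-stamped 3-D positions of one entity
#'
#' Positions of a single flying animal (bat or moth) sampled at a nominal
#' frame rate. Coordinates are metres in a right-handed frame with z
#' pointing up; times are seconds on the shared audio/video time base.
#'
#' @slot entity character, \code{"bat"} or \code{"moth"}.
#' @slot time numeric vector of sample times (s), strictly increasing.
#' @slot coords numeric matrix with one row per sample and columns
#'   \code{x}, \code{y}, \code{z} (m).
#' @slot frameRate nominal sampling rate (Hz).
#' @export
setClass("Trajectory3D",
  representation(entity = "character", time = "numeric",
                 coords = "matrix", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@entity %in% c("bat", "moth")))
      msg <- c(msg, "entity must be 'bat' or 'moth'")
    if (length(object@time) != nrow(object@coords))
      msg <- c(msg, "time and coords disagree in length")
    if (ncol(object@coords) != 3L)
      msg <- c(msg, "coords must have 3 columns (x, y, z)")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (any(!is.finite(object@time)) || any(!is.finite(object@coords)))
      msg <- c(msg, "times and coordinates must be finite")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a Trajectory3D
#'
#' @param entity \code{"bat"} or \code{"moth"}.
#' @param time sample times (s), strictly increasing.
#' @param x,y,z coordinates (m), z up.
#' @param frameRate nominal sampling rate (Hz), default 60.
#' @return A \linkS4class{Trajectory3D}.
#' @examples
#' tr <- Trajectory3D("moth", time = 0:9 / 60, x = 1:10 / 10,
#'                    y = rep(0, 10), z = rep(2, 10))
#' tr
#' @export
Trajectory3D <- function(entity, time, x, y, z, frameRate = 60) {
  coords <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  new("Trajectory3D", entity = entity, time = as.numeric(time),
      coords = coords, frameRate = frameRate)
}

setMethod("show", "Trajectory3D", function(object) {
  cat(sprintf("Trajectory3D of %s: %d samples, t = [%.3f, %.3f] s @ %g Hz\n",
              object@entity, length(object@time),
              min(object@time), max(object@time), object@frameRate))
})

#' @rdname batmoth-generics
#' @export
setMethod("timeRange", "Trajectory3D", function(x) range(x@time))

#' EventStream: bat calls and moth clicks of one interaction
#'
#' Ordered acoustic events for one bat-moth interaction: bat echolocation
#' call onsets with durations, and moth tymbal click emission times.
#'
#' @slot interactionId character identifier.
#' @slot callOnsets numeric, strictly increasing call onset times (s).
#' @slot callDurations numeric, call durations (s), same length, all >= 0.
#' @slot clickTimes numeric, non-decreasing click emission times (s).
#' @export
setClass("EventStream",
  representation(interactionId = "character", callOnsets = "numeric",
                 callDurations = "numeric", clickTimes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@callOnsets) != length(object@callDurations))
      msg <- c(msg, "callOnsets and callDurations disagree in length")
    if (length(object@callOnsets) > 1) {
      bad <- which(diff(object@callOnsets) <= 0)
      if (length(bad))
        msg <- c(msg, sprintf(
          "call onsets must be strictly increasing (first violation at index %d)",
          bad[1] + 1L))
    }
    if (any(object@callDurations < 0))
      msg <- c(msg, "call durations must be >= 0")
    if (length(object@clickTimes) > 1 && any(diff(object@clickTimes) < 0))
      msg <- c(msg, "click times must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Construct an EventStream
#'
#' @param callOnsets strictly increasing call onset times (s).
#' @param callDurations call durations (s); recycled scalar allowed.
#' @param clickTimes moth click emission times (s); default none.
#' @param interactionId identifier, default \code{"1"}.
#' @return An \linkS4class{EventStream}.
#' @examples
#' EventStream(callOnsets = c(0, 0.05, 0.09), callDurations = 0.002)
#' @export
EventStream <- function(callOnsets, callDurations = 0.002,
                        clickTimes = numeric(), interactionId = "1") {
  n <- length(callOnsets)
  if (length(callDurations) == 1L) callDurations <- rep(callDurations, n)
  new("EventStream", interactionId = interactionId,
      callOnsets = as.numeric(callOnsets),
      callDurations = as.numeric(callDurations),
      clickTimes = as.numeric(clickTimes))
}

setMethod("show", "EventStream", function(object) {
  cat(sprintf("EventStream '%s': %d calls, %d clicks\n",
              object@interactionId, length(object@callOnsets),
              length(object@clickTimes)))
})

#' @rdname batmoth-generics
#' @export
setMethod("interactionId", "EventStream", function(x) x@interactionId)
#' @rdname batmoth-generics
#' @export
setMethod("callOnsets", "EventStream", function(x) x@callOnsets)
#' @rdname batmoth-generics
#' @export
setMethod("callDurations", "EventStream", function(x) x@callDurations)
#' @rdname batmoth-generics
#' @export
setMethod("clickTimes", "EventStream", function(x) x@clickTimes)

#' Interaction: the unit of analysis
#'
#' One bat-moth encounter: two 3-D trajectories, the acoustic event
#' stream, and metadata (species, tymbal treatment, scored outcome).
#' Treatments follow the tymbal-ablation design: \code{"T+"} tymbals
#' intact, \code{"T-"} tymbals ablated (silenced), \code{"S"} sham
#' operated. Ablated moths never click, and the validity method enforces
#' that.
#'
#' @slot interactionId,mothId character identifiers.
#' @slot species one of \code{"P_roseicapitis"}, \code{"C_martini"},
#'   \code{"other"}.
#' @slot treatment one of \code{"T+"}, \code{"T-"}, \code{"S"}.
#' @slot outcome one of \code{"non_capture"}, \code{"capture_drop"},
#'   \code{"consume"}, or \code{NA} if unscored.
#' @slot evasion optional hand-scored label (\code{"dive"},
#'   \code{"turn_away"}, \code{"no_evasion"}) or \code{NA}.
#' @slot bat,moth \linkS4class{Trajectory3D} objects on a shared time base.
#' @slot events the \linkS4class{EventStream}.
#' @slot provenance list (e.g. seed or source file).
#' @export
setClass("Interaction",
  representation(interactionId = "character", mothId = "character",
                 species = "character", treatment = "character",
                 outcome = "character", evasion = "character",
                 bat = "Trajectory3D", moth = "Trajectory3D",
                 events = "EventStream", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (!(object@species %in% SPECIES_LEVELS))
      msg <- c(msg, sprintf("unknown species '%s'", object@species))
    if (!(object@treatment %in% TREATMENT_LEVELS))
      msg <- c(msg, sprintf("unknown treatment '%s'", object@treatment))
    if (!is.na(object@outcome) && !(object@outcome %in% OUTCOME_LEVELS))
      msg <- c(msg, sprintf("unknown outcome '%s'", object@outcome))
    if (!is.na(object@evasion) && !(object@evasion %in% EVASION_LEVELS))
      msg <- c(msg, sprintf("unknown evasion label '%s'", object@evasion))
    if (object@treatment == "T-" && length(object@events@clickTimes) > 0)
      msg <- c(msg, "ablated (T-) moths cannot have clicks")
    if (length(msg)) msg else TRUE
  })

#' Construct an Interaction
#'
#' @param interactionId,mothId identifiers.
#' @param species,treatment,outcome,evasion metadata; see
#'   \linkS4class{Interaction}.
#' @param bat,moth \linkS4class{Trajectory3D} objects.
#' @param events an \linkS4class{EventStream}.
#' @param provenance free-form list.
#' @return An \linkS4class{Interaction}.
#' @export
Interaction <- function(interactionId, mothId, species, treatment,
                        bat, moth, events, outcome = NA_character_,
                        evasion = NA_character_, provenance = list()) {
  new("Interaction", interactionId = as.character(interactionId),
      mothId = as.character(mothId), species = species,
      treatment = treatment, outcome = as.character(outcome),
      evasion = as.character(evasion), bat = bat, moth = moth,
      events = events, provenance = provenance)
}

setMethod("show", "Interaction", function(object) {
  cat(sprintf("Interaction '%s' (moth %s, %s, %s): outcome %s\n",
              object@interactionId, object@mothId, object@species,
              object@treatment, object@outcome))
  show(object@events)
  show(object@bat)
  show(object@moth)
})

#' @rdname batmoth-generics
#' @export
setMethod("interactionId", "Interaction", function(x) x@interactionId)
#' @rdname batmoth-generics
#' @export
setMethod("mothId", "Interaction", function(x) x@mothId)
#' @rdname batmoth-generics
#' @export
setMethod("mothSpecies", "Interaction", function(x) x@species)
#' @rdname batmoth-generics
#' @export
setMethod("treatment", "Interaction", function(x) x@treatment)
#' @rdname batmoth-generics
#' @export
setMethod("outcome", "Interaction", function(x) x@outcome)
#' @rdname batmoth-generics
#' @export
setMethod("eventStream", "Interaction", function(x) x@events)

#' @rdname batmoth-generics
#' @param which \code{"bat"} or \code{"moth"}.
#' @export
setMethod("trajectory", "Interaction", function(x, which = c("bat", "moth")) {
  which <- match.arg(which)
  slot(x, which)
})

#' InteractionSet: a collection of interactions plus ground truth
#'
#' Container returned by the synthetic generator and the dataset readers.
#' \code{groundTruth} is empty for field data.
#'
#' @slot interactions list of \linkS4class{Interaction}.
#' @slot groundTruth data.frame, one row per generated interaction (empty
#'   for observational data).
#' @slot metadata list (seed, config, source paths).
#' @export
setClass("InteractionSet",
  representation(interactions = "list", groundTruth = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    ok <- vapply(object@interactions, is, logical(1), class2 = "Interaction")
    if (!all(ok)) return("all elements must be Interaction objects")
    if (nrow(object@groundTruth) > 0 &&
        nrow(object@groundTruth) != length(object@interactions))
      return("groundTruth rows must match the number of interactions")
    TRUE
  })

#' @export
#' @describeIn InteractionSet-class number of interactions.
#' @param x an \code{InteractionSet}.
setMethod("length", "InteractionSet", function(x) length(x@interactions))

#' @export
#' @describeIn InteractionSet-class extract one \code{Interaction}.
#' @param i index.
#' @param j,... unused.
setMethod("[[", "InteractionSet", function(x, i, j, ...) x@interactions[[i]])

setMethod("show", "InteractionSet", function(object) {
  cat(sprintf("InteractionSet with %d interactions (%s ground truth)\n",
              length(object), if (nrow(object@groundTruth)) "with" else "no"))
})

#' Ground-truth table of an InteractionSet
#'
#' @param x an \linkS4class{InteractionSet}.
#' @return data.frame with one row per generated interaction.
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "InteractionSet"))
  x@groundTruth
}

#' Metadata table of an InteractionSet
#'
#' One row per interaction: id, moth id, species, treatment, outcome,
#' evasion label and a timestamp used by the first-interaction filter.
#'
#' @param x an \linkS4class{InteractionSet}.
#' @return data.frame.
#' @export
interactionMetadata <- function(x) {
  stopifnot(is(x, "InteractionSet"))
  do.call(rbind, lapply(seq_along(x@interactions), function(i) {
    it <- x@interactions[[i]]
    ts <- it@provenance$timestamp
    data.frame(interaction_id = it@interactionId, moth_id = it@mothId,
               species = it@species, treatment = it@treatment,
               outcome = it@outcome, evasion = it@evasion,
               timestamp = if (is.null(ts)) i else ts,
               stringsAsFactors = FALSE)
  }))
}

#' SmoothedPath: a continuous smoothed flight path
#'
#' Piecewise-polynomial position function fitted to a
#' \linkS4class{Trajectory3D}, evaluable (with first derivative) at any
#' time in its domain. Created by \code{\link{smoothTrajectory}}.
#'
#' @slot fits list of three functions \code{f(t, deriv)} for x, y, z.
#' @slot range numeric(2), the time domain (s).
#' @slot entity character, copied from the source trajectory.
#' @export
setClass("SmoothedPath",
  representation(fits = "list", range = "numeric", entity = "character"),
  validity = function(object) {
    if (length(object@fits) != 3L) return("fits must hold 3 axis functions")
    if (length(object@range) != 2L || diff(object@range) <= 0)
      return("range must be an increasing pair of times")
    TRUE
  })

#' @rdname path-evaluation
#' @export
setMethod("timeRange", "SmoothedPath", function(x) x@range)

#' @rdname path-evaluation
#' @export
setMethod("positionAt", "SmoothedPath", function(x, t) {
  out <- vapply(x@fits, function(f) f(t, 0L), numeric(length(t)))
  out <- matrix(out, nrow = length(t), dimnames = list(NULL, c("x", "y", "z")))
  out
})

#' @rdname path-evaluation
#' @export
setMethod("velocityAt", "SmoothedPath", function(x, t) {
  out <- vapply(x@fits, function(f) f(t, 1L), numeric(length(t)))
  matrix(out, nrow = length(t), dimnames = list(NULL, c("x", "y", "z")))
})

setMethod("show", "SmoothedPath", function(object) {
  cat(sprintf("SmoothedPath (%s) over t = [%.3f, %.3f] s\n",
              object@entity, object@range[1], object@range[2]))
})

#' JammingReport: critical-window assessment of one interaction
#'
#' Per-echo critical windows and the fraction of echoes whose +/- 2 ms
#' window around the echo return time contains no moth click arrival.
#'
#' @slot interactionId character.
#' @slot windows data.frame with one row per selected call: call midpoint,
#'   bat-moth distance at emission, echo return time, window bounds,
#'   overlap flag, exclusion flag and reason.
#' @slot nEchoesUsed,nUnaffected integer counts over non-excluded echoes.
#' @slot fractionUnaffected numeric in [0, 1]; \code{NA} when no usable
#'   echoes.
#' @export
setClass("JammingReport",
  representation(interactionId = "character", windows = "data.frame",
                 nEchoesUsed = "integer", nUnaffected = "integer",
                 fractionUnaffected = "numeric"),
  validity = function(object) {
    if (object@nEchoesUsed > 0) {
      f <- object@nUnaffected / object@nEchoesUsed
      if (!isTRUE(all.equal(f, object@fractionUnaffected)))
        return("fractionUnaffected must equal nUnaffected / nEchoesUsed")
    } else if (!is.na(object@fractionUnaffected)) {
      return("fractionUnaffected must be NA when no echoes are usable")
    }
    TRUE
  })

setMethod("show", "JammingReport", function(object) {
  cat(sprintf("JammingReport '%s': %d echoes used, %d unaffected (%s)\n",
              object@interactionId, object@nEchoesUsed, object@nUnaffected,
              ifelse(is.na(object@fractionUnaffected), "NA",
                     sprintf("%.2f", object@fractionUnaffected))))
})

#' @rdname batmoth-generics
#' @export
setMethod("interactionId", "JammingReport", function(x) x@interactionId)
#' @rdname batmoth-generics
#' @export
setMethod("fractionUnaffected", "JammingReport", function(x) x@fractionUnaffected)

#' ContingencyTable2x2: non-capture vs captured counts for two groups
#'
#' Statistical comparisons pool the "capture, drop" and "consume"
#' outcomes into a single "captured" column.
#'
#' @slot groups character(2), group labels (rows).
#' @slot counts integer 2 x 2 matrix, columns \code{non_capture} and
#'   \code{captured}.
#' @export
setClass("ContingencyTable2x2",
  representation(groups = "character", counts = "matrix"),
  validity = function(object) {
    if (length(object@groups) != 2L) return("exactly two groups required")
    if (any(dim(object@counts) != 2L)) return("counts must be 2 x 2")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' Construct a 2x2 non-capture/captured table from counts
#'
#' @param a,b non-capture and captured counts in group 1.
#' @param c,d non-capture and captured counts in group 2.
#' @param groups character(2) group labels.
#' @return A \linkS4class{ContingencyTable2x2}.
#' @examples
#' contingencyTable2x2(25, 25, 3, 22, groups = c("T+", "T-"))
#' @export
contingencyTable2x2 <- function(a, b, c, d, groups = c("group1", "group2")) {
  counts <- matrix(as.integer(c(a, b, c, d)), nrow = 2, byrow = TRUE,
                   dimnames = list(groups, c("non_capture", "captured")))
  new("ContingencyTable2x2", groups = groups, counts = counts)
}

#' Counts matrix of a ContingencyTable2x2
#' @param x a \linkS4class{ContingencyTable2x2}.
#' @return integer 2 x 2 matrix.
#' @export
tableCounts <- function(x) {
  stopifnot(is(x, "ContingencyTable2x2"))
  x@counts
}

setMethod("show", "ContingencyTable2x2", function(object) {
  cat("2 x 2 outcome table (non-capture vs captured)\n")
  print(object@counts)
})

#' FisherResult: exact inference on a 2x2 table
#'
#' @slot pTwoSided two-sided exact p-value (hypergeometric mass rule).
#' @slot orCmle conditional maximum-likelihood odds ratio; may be 0 or
#'   \code{Inf} with boundary tables.
#' @slot ci95 numeric(2), exact conditional 95\% confidence bounds.
#' @slot pAdjusted Bonferroni-adjusted p (capped at 1); \code{NA} until
#'   \code{\link{bonferroni}} is applied.
#' @export
setClass("FisherResult",
  representation(pTwoSided = "numeric", orCmle = "numeric",
                 ci95 = "numeric", pAdjusted = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pTwoSided <= 0 || object@pTwoSided > 1 + 1e-12)
      msg <- c(msg, "p must lie in (0, 1]")
    if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must be length 2")
    else if (!(object@ci95[1] <= object@orCmle + 1e-8 &&
               object@orCmle <= object@ci95[2] + 1e-8))
      msg <- c(msg, "orCmle must lie within ci95")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FisherResult", function(object) {
  cat(sprintf(
    "Fisher exact: p = %.4g, OR (CMLE) = %.4g, 95%% CI [%.4g, %.4g]%s\n",
    object@pTwoSided, object@orCmle, object@ci95[1], object@ci95[2],
    if (is.na(object@pAdjusted)) ""
    else sprintf(", adj. p = %.4g", object@pAdjusted)))
})

#' ExactBinomialResult: one-sided exact binomial test of rejection rate
#'
#' @slot x,n successes and trials.
#' @slot proportion x / n.
#' @slot pValue one-sided p versus the null proportion (see
#'   \code{\link{exactBinomialRejection}}); 0 under a degenerate null
#'   p0 = 0 with x > 0.
#' @slot ci95 numeric(2), one-sided exact (Clopper-Pearson) interval
#'   (lower bound, 1).
#' @slot degenerateNull flag: the null p0 = 0 makes any x > 0 reject
#'   trivially; the informative output is the lower confidence bound.
#' @export
setClass("ExactBinomialResult",
  representation(x = "integer", n = "integer", proportion = "numeric",
                 pValue = "numeric", ci95 = "numeric",
                 degenerateNull = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@x > object@n) msg <- c(msg, "x cannot exceed n")
    if (object@ci95[1] > object@proportion + 1e-12)
      msg <- c(msg, "lower bound cannot exceed the point estimate")
    if (object@x == 0L && object@ci95[1] != 0)
      msg <- c(msg, "lower bound must be 0 when x = 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ExactBinomialResult", function(object) {
  cat(sprintf(
    "Exact binomial: %d/%d = %.0f%%, one-sided p = %.3g, 95%% CI [%.2f, 1.0]%s\n",
    object@x, object@n, 100 * object@proportion, object@pValue,
    object@ci95[1],
    if (object@degenerateNull) " (degenerate null p0 = 0)" else ""))
})

#' SimulationConfig: parameters of the synthetic interaction generator
#'
#' The generator emulates the structure of field-recorded bat-moth
#' interactions: phase-structured echolocation call sequences (search
#' through terminal buzz), species-specific moth click triggering,
#' clustered low-duty-cycle click trains, pure-pursuit bat flight with
#' level or diving moth flight, positional noise at the scale of 3-D
#' reconstruction error, and treatment-conditional outcome draws.
#'
#' @slot phaseIpiRanges named list mapping each attack phase to
#'   \code{c(min_ms, max_ms)}; IPIs are drawn uniformly within the active
#'   phase's range.
#' @slot phaseDurations named numeric, dwell time (s) per phase.
#' @slot callDurationMs bat call duration (ms).
#' @slot triggerIpiMs named numeric per species: mean IPI at which the
#'   moth starts clicking (defaults 44 and 21 ms).
#' @slot responseIpiSdMs between-moth SD of the response threshold (ms).
#' @slot clicksPerModulationCycle clicks per tymbal modulation cycle.
#' @slot modulationCycleRateHz modulation cycle rate (Hz).
#' @slot modulationActiveFraction fraction of the cycle over which the
#'   clicks of one cycle are spread.
#' @slot clickDurationMs duration of a single click (ms), used for the
#'   duty-cycle bound.
#' @slot maxDutyCycleFraction maximum click-on time per second; default
#'   0.06 (these species are ~6\% duty-cycle moths, far below proven
#'   jammers).
#' @slot batSpeedMps,mothSpeedMps flight speeds (m/s).
#' @slot diveZSpeedMps mean dive z-speed (m/s, negative = downward);
#'   default -1.01.
#' @slot diveZSpeedSdMps between-moth SD of the dive z-speed.
#' @slot pEvasion named numeric per species: probability of an evasive
#'   dive (defaults 0.43 and 0.17).
#' @slot outcomeProbs data.frame with columns species, treatment,
#'   p_non_capture, p_capture_drop, p_consume; rows must sum to 1.
#' @slot treatmentProbs named numeric over \code{c("T+", "T-", "S")}.
#' @slot speciesProbs named numeric over the two modelled species.
#' @slot abortProbabilityGivenClicks probability the bat aborts (no buzz,
#'   returns to search-range IPIs) in a non-capture interaction with a
#'   clicking moth.
#' @slot clickMissProbability probability a clicking moth's train is
#'   missed entirely (field microphones miss about half); default 0.
#' @slot frameRateHz video frame rate (Hz), default 60.
#' @slot positionNoiseSdM per-axis positional noise SD (m); default
#'   0.037/sqrt(3) so the expected 3-D error matches the 3.7 cm
#'   reconstruction error floor.
#' @slot nonCaptureStandoffM closest approach (m) of aborted/failed
#'   attacks; default 0.33.
#' @slot seed integer seed recorded in outputs.
#' @export
setClass("SimulationConfig",
  representation(
    phaseIpiRanges = "list", phaseDurations = "numeric",
    callDurationMs = "numeric", triggerIpiMs = "numeric",
    responseIpiSdMs = "numeric", clicksPerModulationCycle = "integer",
    modulationCycleRateHz = "numeric", modulationActiveFraction = "numeric",
    clickDurationMs = "numeric", maxDutyCycleFraction = "numeric",
    batSpeedMps = "numeric", mothSpeedMps = "numeric",
    diveZSpeedMps = "numeric", diveZSpeedSdMps = "numeric",
    pEvasion = "numeric", outcomeProbs = "data.frame",
    treatmentProbs = "numeric", speciesProbs = "numeric",
    abortProbabilityGivenClicks = "numeric", clickMissProbability = "numeric",
    frameRateHz = "numeric", positionNoiseSdM = "numeric",
    nonCaptureStandoffM = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    need <- PHASE_LEVELS
    if (!all(need %in% names(object@phaseIpiRanges)))
      msg <- c(msg, "phaseIpiRanges must name all four phases")
    else {
      for (ph in need) {
        r <- object@phaseIpiRanges[[ph]]
        if (length(r) != 2L || r[1] > r[2])   # degenerate (min == max) allowed
          msg <- c(msg, sprintf("invalid IPI range for phase '%s' (min > max)", ph))
      }
      if (!length(msg)) {
        lo <- vapply(object@phaseIpiRanges[need], `[`, numeric(1), 1L)
        if (!(lo["search"] > lo["early_approach"] &&
              lo["early_approach"] > lo["late_approach"] &&
              lo["late_approach"] > lo["buzz"]))
          msg <- c(msg, "phase IPI ranges must be ordered search > early > late > buzz")
      }
    }
    if (!all(need %in% names(object@phaseDurations)) ||
        any(object@phaseDurations <= 0))
      msg <- c(msg, "phaseDurations must be positive for all four phases")
    if (object@maxDutyCycleFraction <= 0 || object@maxDutyCycleFraction >= 1)
      msg <- c(msg, "maxDutyCycleFraction must lie in (0, 1)")
    dc <- object@clicksPerModulationCycle * object@clickDurationMs / 1000 *
      object@modulationCycleRateHz
    if (dc > object@maxDutyCycleFraction + 1e-12)
      msg <- c(msg, sprintf(
        "click-train settings imply duty cycle %.3f above maxDutyCycleFraction %.3f",
        dc, object@maxDutyCycleFraction))
    op <- object@outcomeProbs
    needCols <- c("species", "treatment", "p_non_capture", "p_capture_drop",
                  "p_consume")
    if (!all(needCols %in% names(op)))
      msg <- c(msg, "outcomeProbs must have species, treatment and three probability columns")
    else {
      s <- op$p_non_capture + op$p_capture_drop + op$p_consume
      if (any(abs(s - 1) > 1e-8))
        msg <- c(msg, "outcome probabilities must sum to 1 in every row")
    }
    if (abs(sum(object@treatmentProbs) - 1) > 1e-8)
      msg <- c(msg, "treatmentProbs must sum to 1")
    if (abs(sum(object@speciesProbs) - 1) > 1e-8)
      msg <- c(msg, "speciesProbs must sum to 1")
    if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be > 0")
    if (object@batSpeedMps <= 0 || object@mothSpeedMps <= 0)
      msg <- c(msg, "speeds must be > 0")
    if (object@diveZSpeedMps >= 0)
      msg <- c(msg, "diveZSpeedMps must be negative (downward)")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  trigger IPIs (ms): %s\n",
              paste(sprintf("%s=%g", names(object@triggerIpiMs),
                            object@triggerIpiMs), collapse = ", ")))
  cat(sprintf("  dive z-speed: %g m/s; p(evasion): %s\n",
              object@diveZSpeedMps,
              paste(sprintf("%s=%g", names(object@pEvasion), object@pEvasion),
                    collapse = ", ")))
  cat(sprintf("  frame rate %g Hz, position noise sd %.4f m, seed %d\n",
              object@frameRateHz, object@positionNoiseSdM, object@seed))
})
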