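## File dialects. All CSV files are UTF-8 with a header row and '.'
## decimal separator.
##
##   trajectories.csv  interaction_id, entity (bat|moth), t_s, x_m, y_m, z_m
##   events.csv        interaction_id, event_type (call|click), onset_s,
##                     duration_s (empty for clicks)
##   interactions.csv  interaction_id, moth_id, species, treatment,
##                     outcome, evasion, timestamp
##   ground_truth.json generator ground truth (synthetic data only)
##   config.yaml       SimulationConfig including the seed

#' Write an InteractionSet to disk
#'
#' Writes the trajectory, event and metadata CSV files, the
#' ground-truth JSON (when present) and the simulation config YAML
#' (seed included) into a directory.
#'
#' @param x an \linkS4class{InteractionSet}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(x, dir) {
  stopifnot(is(x, "InteractionSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trajectories = file.path(dir, "trajectories.csv"),
             events = file.path(dir, "events.csv"),
             interactions = file.path(dir, "interactions.csv"))

  traj <- do.call(rbind, lapply(x@interactions, function(it) {
    do.call(rbind, lapply(c("bat", "moth"), function(e) {
      tr <- slot(it, e)
      data.frame(interaction_id = it@interactionId, entity = e,
                 t_s = tr@time, x_m = tr@coords[, 1], y_m = tr@coords[, 2],
                 z_m = tr@coords[, 3], stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(traj, paths["trajectories"], row.names = FALSE)

  ev <- do.call(rbind, lapply(x@interactions, function(it) {
    s <- it@events
    rbind(
      if (length(s@callOnsets))
        data.frame(interaction_id = it@interactionId, event_type = "call",
                   onset_s = s@callOnsets, duration_s = s@callDurations,
                   stringsAsFactors = FALSE),
      if (length(s@clickTimes))
        data.frame(interaction_id = it@interactionId, event_type = "click",
                   onset_s = s@clickTimes, duration_s = NA_real_,
                   stringsAsFactors = FALSE))
  }))
  utils::write.csv(ev, paths["events"], row.names = FALSE)

  utils::write.csv(interactionMetadata(x), paths["interactions"],
                   row.names = FALSE)

  if (nrow(x@groundTruth)) {
    paths["ground_truth"] <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(x@groundTruth, paths["ground_truth"],
                         dataframe = "rows", digits = NA, na = "null")
  }
  cfg <- x@metadata$config
  if (!is.null(cfg)) {
    paths["config"] <- file.path(dir, "config.yaml")
    writeSimulationConfig(cfg, paths["config"])
  }
  invisible(paths)
}

#' Read an InteractionSet from disk
#'
#' Inverse of \code{\link{writeDataset}}: reads the CSV dialect (and
#' ground truth, if present) back into an \linkS4class{InteractionSet}.
#'
#' @param dir directory holding \code{trajectories.csv},
#'   \code{events.csv} and \code{interactions.csv}.
#' @return An \linkS4class{InteractionSet}.
#' @export
readDataset <- function(dir) {
  traj <- utils::read.csv(file.path(dir, "trajectories.csv"),
                          stringsAsFactors = FALSE)
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "interactions.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(interaction_id = "character",
                                         moth_id = "character"))
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtPath))
    jsonlite::fromJSON(gtPath) else data.frame()

  traj$interaction_id <- as.character(traj$interaction_id)
  ev$interaction_id <- as.character(ev$interaction_id)
  ints <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    tr <- traj[traj$interaction_id == m$interaction_id, ]
    if (nrow(tr) == 0)
      stop("no trajectories for interaction ", m$interaction_id)
    mk <- function(e) {
      d <- tr[tr$entity == e, ]
      Trajectory3D(e, d$t_s, d$x_m, d$y_m, d$z_m)
    }
    ee <- ev[ev$interaction_id == m$interaction_id, ]
    calls <- ee[ee$event_type == "call", ]
    clicks <- ee[ee$event_type == "click", ]
    events <- EventStream(callOnsets = calls$onset_s,
                          callDurations = if (nrow(calls)) calls$duration_s
                            else numeric(),
                          clickTimes = clicks$onset_s,
                          interactionId = m$interaction_id)
    Interaction(interactionId = m$interaction_id, mothId = m$moth_id,
                species = m$species, treatment = m$treatment,
                bat = mk("bat"), moth = mk("moth"), events = events,
                outcome = m$outcome, evasion = m$evasion,
                provenance = list(timestamp = m$timestamp, source = dir))
  })
  new("InteractionSet", interactions = ints, groundTruth = gt,
      metadata = list(source = dir))
}

#' Serialize a SimulationConfig to YAML
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  sl <- slotNames(config)
  out <- setNames(lapply(sl, function(s) {
    v <- slot(config, s)
    if (is.data.frame(v)) as.list(v)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)  # keep names in YAML
    else v
  }), sl)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a SimulationConfig from YAML
#'
#' @param path a YAML file written by \code{\link{writeSimulationConfig}}
#'   (or hand-edited with the same fields).
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$outcomeProbs))
    raw$outcomeProbs <- as.data.frame(raw$outcomeProbs,
                                      stringsAsFactors = FALSE)
  for (f in c("phaseDurations", "triggerIpiMs", "pEvasion",
              "treatmentProbs", "speciesProbs"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(simulationConfig, raw)
}
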