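## End-to-end orchestration: simulate -> analyze -> stats. Each stage is
## a plain function so stages can be run and tested independently;
## exclusions are recorded per interaction in the metrics table rather
## than dropped silently.

#' Simulate a dataset and write it to disk
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param n number of interactions.
#' @param outDir output directory for the CSV/JSON/YAML files.
#' @param seed integer seed (recorded in the config file).
#' @return invisibly, the generated \linkS4class{InteractionSet}.
#' @export
runSimulate <- function(config, n, outDir, seed = config@seed) {
  if (n < 1) stop("n must be >= 1")
  cfg <- config
  cfg@seed <- as.integer(seed)
  ds <- generateDataset(n, cfg, seed = seed)
  ds@metadata$config <- cfg
  writeDataset(ds, outDir)
  invisible(ds)
}

#' Per-interaction analysis metrics
#'
#' Runs the acoustic, kinematic and jamming analyses over every
#' interaction of a set: IPI before the first click (with its attack
#' phase), bat-moth distance at the first click, number of calls
#' between search phases, minimum bat-moth distance with contact flag,
#' mean pre-encounter z-speed, evasion label, and the fraction of
#' unaffected echoes. Interactions that cannot be analysed are kept as
#' flagged rows with the failure reason in \code{note}, never dropped.
#'
#' @param x an \linkS4class{InteractionSet} or a directory readable by
#'   \code{\link{readDataset}}.
#' @param contactFloor contact floor (m), default 0.037.
#' @param window_s pre-encounter window (s), default 0.333.
#' @param diveThreshold,turnThreshold see \code{\link{classifyEvasion}}.
#' @param smoothTolerance total squared-residual budget (m^2) passed to
#'   \code{\link{smoothTrajectory}}; NULL uses that function's default.
#' @return data.frame, one row per interaction.
#' @export
runAnalyze <- function(x, contactFloor = CONTACT_FLOOR_M, window_s = 0.333,
                       diveThreshold = -0.5, turnThreshold = 90,
                       smoothTolerance = NULL) {
  if (is.character(x)) x <- readDataset(x)
  stopifnot(is(x, "InteractionSet"))
  rows <- lapply(x@interactions, function(it) {
    base <- data.frame(
      interaction_id = it@interactionId, moth_id = it@mothId,
      species = it@species, treatment = it@treatment, outcome = it@outcome,
      ipi_before_first_click_ms = NA_real_,
      phase_before_first_click = NA_character_,
      distance_at_first_click_m = NA_real_,
      n_calls_between_search = NA_integer_,
      mbmd_m = NA_real_, t_min_dist_s = NA_real_, contact = NA,
      mean_z_speed_mps = NA_real_, evasion = NA_character_,
      n_echoes_used = NA_integer_, fraction_unaffected = NA_real_,
      note = "", stringsAsFactors = FALSE)
    tryCatch({
      s <- it@events
      ib <- ipiBeforeFirstClick(s)
      if (!is.null(ib)) {
        base$ipi_before_first_click_ms <- ib$ipi_ms
        base$phase_before_first_click <- ib$phase
      }
      if (length(s@callOnsets) >= 2L)
        base$n_calls_between_search <- countCallsBetweenSearchPhases(s)

      smoothOne <- function(tr) {
        if (is.null(smoothTolerance)) smoothTrajectory(tr)
        else smoothTrajectory(tr, tolerance = smoothTolerance)
      }
      batP <- smoothOne(it@bat)
      mothP <- smoothOne(it@moth)
      md <- minBatMothDistance(batP, mothP, contactFloor = contactFloor)
      base$mbmd_m <- md$mbmd_m
      base$t_min_dist_s <- md$t_min_dist_s
      base$contact <- md$contact
      base$mean_z_speed_mps <-
        as.numeric(preEncounterZSpeed(mothP, md$t_min_dist_s, window_s))
      base$evasion <- classifyEvasion(mothP, md$t_min_dist_s, window_s,
                                      diveThreshold, turnThreshold)
      if (length(s@clickTimes)) {
        t1 <- s@clickTimes[1]
        lo <- max(batP@range[1], mothP@range[1])
        hi <- min(batP@range[2], mothP@range[2])
        if (t1 >= lo && t1 <= hi)
          base$distance_at_first_click_m <-
            sqrt(sum((positionAt(batP, t1) - positionAt(mothP, t1))^2))
      }
      jr <- assessJamming(s, batP, mothP)
      base$n_echoes_used <- jr@nEchoesUsed
      base$fraction_unaffected <- jr@fractionUnaffected
      base
    }, error = function(e) {
      base$note <- conditionMessage(e)
      base
    })
  })
  do.call(rbind, rows)
}

## Mean and standard error of a numeric vector, NA-safe.
meanSem <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  list(mean = if (n) mean(v) else NA_real_,
       sem = if (n > 1) sd(v) / sqrt(n) else NA_real_, n = n)
}

#' Outcome and treatment statistics of an analysed dataset
#'
#' Reproduces the standard report over a metrics table: per-species
#' outcome tabulation by treatment, tymbaled-vs-ablated relative risks
#' and Fisher exact results (with Bonferroni-adjusted companions over
#' the per-species comparison family), exact binomial palatability of
#' captured ablated moths, IPI-before-first-click and z-speed group
#' summaries, and the species evasion comparison. The
#' first-interaction pseudoreplication filter is applied to the
#' metadata before tabulation.
#'
#' @param metrics data.frame from \code{\link{runAnalyze}}.
#' @param meta metadata data.frame (see
#'   \code{\link{interactionMetadata}}); when NULL the metadata columns
#'   of \code{metrics} are used with the evasion labels computed by the
#'   analysis.
#' @return nested list (serializable with
#'   \code{\link{writeStatsReport}}).
#' @export
runStats <- function(metrics, meta = NULL) {
  if (is.null(meta)) {
    meta <- metrics[, c("interaction_id", "moth_id", "species", "treatment",
                        "outcome", "evasion")]
    meta$timestamp <- seq_len(nrow(meta))
  }
  meta <- firstInteractionFilter(meta)
  metrics <- metrics[metrics$interaction_id %in% meta$interaction_id, ,
                     drop = FALSE]
  report <- list()

  perSpecies <- list()
  for (sp in intersect(SPECIES_LEVELS, unique(meta$species))) {
    m <- meta[meta$species == sp, , drop = FALSE]
    tab <- table(factor(m$treatment, TREATMENT_LEVELS),
                 factor(m$outcome, OUTCOME_LEVELS))
    entry <- list(outcome_counts = as.data.frame.matrix(tab))
    present <- rownames(tab)[rowSums(tab) > 0]
    pairs <- list(c("T+", "T-"), c("S", "T-"), c("T+", "S"))
    pairs <- Filter(function(p) all(p %in% present), pairs)
    comps <- list()
    ps <- numeric()
    for (p in pairs) {
      ct <- buildContingency(m, groups = p)
      fr <- fisherExact(ct)
      comps[[paste(p, collapse = "_vs_")]] <- list(
        table = tableCounts(ct),
        relative_risk = relativeRiskCapture(ct),
        p = fr@pTwoSided, or_cmle = fr@orCmle, ci95 = fr@ci95)
      ps <- c(ps, fr@pTwoSided)
    }
    if (length(comps)) {
      adj <- bonferroni(ps, m = max(3, length(ps)))
      for (i in seq_along(comps)) comps[[i]]$p_adjusted <- adj[i]
    }
    entry$treatment_comparisons <- comps

    capT <- m[m$treatment == "T-" &
              m$outcome %in% c("capture_drop", "consume"), , drop = FALSE]
    if (nrow(capT) > 0) {
      xRej <- sum(capT$outcome == "capture_drop")
      eb <- exactBinomialRejection(xRej, nrow(capT))
      entry$palatability <- list(rejected = xRej, captured = nrow(capT),
                                 proportion = eb@proportion,
                                 p_one_sided = eb@pValue,
                                 ci95_lower = eb@ci95[1])
    }
    perSpecies[[sp]] <- entry
  }
  report$per_species <- perSpecies

  ms <- metrics[is.finite(metrics$ipi_before_first_click_ms), , drop = FALSE]
  report$ipi_before_first_click <- lapply(split(
    ms$ipi_before_first_click_ms, ms$species), function(v) meanSem(v))
  sps <- names(report$ipi_before_first_click)
  if (length(sps) >= 2) {
    a <- ms$ipi_before_first_click_ms[ms$species == sps[1]]
    b <- ms$ipi_before_first_click_ms[ms$species == sps[2]]
    if (length(a) >= 2 && length(b) >= 2)
      report$ipi_species_welch <- welchT(a, b)
  }

  zz <- metrics[is.finite(metrics$mean_z_speed_mps), , drop = FALSE]
  zz$captured <- zz$outcome %in% c("capture_drop", "consume")
  report$z_speed <- lapply(
    split(zz$mean_z_speed_mps,
          interaction(zz$species, ifelse(zz$captured, "captured",
                                         "non_captured"), drop = TRUE)),
    meanSem)

  cc <- metrics[is.finite(metrics$n_calls_between_search) &
                metrics$n_calls_between_search > 0, , drop = FALSE]
  tym <- cc$n_calls_between_search[cc$treatment %in% c("T+", "S")]
  abl <- cc$n_calls_between_search[cc$treatment == "T-"]
  report$call_counts <- list(tymbaled = meanSem(tym), ablated = meanSem(abl))
  if (length(tym) >= 2 && length(abl) >= 2)
    report$call_counts$mww <- mwwTest(tym, abl)

  mb <- metrics[is.finite(metrics$mbmd_m), , drop = FALSE]
  mb$captured <- mb$outcome %in% c("capture_drop", "consume")
  report$mbmd <- lapply(
    split(mb$mbmd_m, ifelse(mb$captured, "captured", "non_captured")),
    meanSem)
  if (length(unique(mb$captured)) == 2 && nrow(mb) >= 4)
    report$mbmd$ks <- ksTest(mb$mbmd_m[mb$captured], mb$mbmd_m[!mb$captured])

  report$fraction_unaffected <-
    meanSem(metrics$fraction_unaffected[
      is.finite(metrics$fraction_unaffected) &
      metrics$n_echoes_used > 0 &
      vapply(seq_len(nrow(metrics)), function(i)
        metrics$treatment[i] %in% c("T+", "S"), logical(1))])

  evMeta <- meta
  if (all(is.na(evMeta$evasion)) && "evasion" %in% names(metrics)) {
    evMeta$evasion <- metrics$evasion[
      match(evMeta$interaction_id, metrics$interaction_id)]
  }
  twoSp <- c("P_roseicapitis", "C_martini")
  okEv <- vapply(twoSp, function(sp) {
    any(evMeta$species == sp & !is.na(evMeta$evasion) &
        evMeta$evasion != "turn_away")
  }, logical(1))
  if (all(okEv)) {
    ec <- evasionComparison(evMeta, species = twoSp)
    report$evasion <- list(
      table = ec$table,
      fraction = ec$table[, "dive"] / rowSums(ec$table),
      p = ec$fisher@pTwoSided, or_cmle = ec$fisher@orCmle,
      ci95 = ec$fisher@ci95)
  }
  report
}

#' Write a stats report as JSON
#'
#' @param report list from \code{\link{runStats}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeStatsReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
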