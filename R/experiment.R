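#' Preset names
#'
#' @return character vector of the named simulation experiments.
#' @export
presetNames <- function() {
  c("wild_type", "reduced_death_L12", "reduced_death_L10", "adhesion_flat",
    "adhesion_anti", "no_expansion", "no_death", "no_expansion_no_death",
    "growing_ipcs", "blocked_single_oc", "blocked_half_oc")
}

#' Build a named experiment preset
#'
#' The wild-type preset pins the published operating point: motility
#' `T = 60`, `J_OC,IPC = 35`, `J_IPC,IPC = 55`, survival threshold `L = 16`,
#' death onset 10,000 MCS, 50,000 MCS total and linear doubling of
#' ommatidial-core targets. Every other preset changes exactly the
#' parameters its name describes (see [presetNames()]).
#'
#' @param name one of [presetNames()].
#' @param fieldSpec a [SyntheticFieldSpec-class] (default 4 x 4 ommatidia).
#' @param totalMCS run length override.
#' @param temperature motility override.
#' @return An [ExperimentPreset-class].
#' @examples
#' eyePreset("reduced_death_L12")
#' @export
eyePreset <- function(name = "wild_type", fieldSpec = syntheticFieldSpec(),
                      totalMCS = 50000L, temperature = 60) {
  name <- match.arg(name, presetNames())
  base <- new("ExperimentPreset", name = name,
              params = engineParameters(temperature = temperature,
                                        totalMCS = totalMCS),
              energies = contactEnergyTable(),
              death = deathRule(),
              expansion = expansionSchedule(),
              variant = variantSpec(),
              fieldSpec = fieldSpec)
  variant <- switch(name,
    wild_type = variantSpec(),
    reduced_death_L12 = variantSpec(deathL = 12),
    reduced_death_L10 = variantSpec(deathL = 10),
    adhesion_flat = variantSpec(adhesionMode = "flat"),
    adhesion_anti = variantSpec(adhesionMode = "anti_preferential"),
    no_expansion = variantSpec(ocExpansion = "none"),
    no_death = variantSpec(deathEnabled = FALSE),
    no_expansion_no_death = variantSpec(ocExpansion = "none",
                                        deathEnabled = FALSE),
    growing_ipcs = variantSpec(ipcGrowth = TRUE),
    blocked_single_oc = variantSpec(ocExpansion = "all_but_one"),
    blocked_half_oc = variantSpec(ocExpansion = "half_of_one"))
  applyVariant(base, variant)
}

#' Run one simulation experiment
#'
#' Builds the initial field from the preset's specification, applies the
#' variant's cell-level effects, flags margin IPCs as death-exempt, then
#' iterates Monte Carlo Steps with the per-MCS hooks in fixed order
#' (expansion, death, scoring). A time-series record is taken every
#' `reportInterval` MCS (including MCS 0).
#'
#' @param preset an [ExperimentPreset-class], or a preset name.
#' @param seed integer RNG seed; identical `(preset, seed)` pairs reproduce
#'   identical trajectories.
#' @param outDir optional directory; when set, the time series
#'   (`timeseries.csv`), final registry (`final_registry.csv`), final label
#'   image (`final_field.png`) and run manifest (`manifest.json`) are
#'   written there.
#' @param snapshotEvery optional MCS interval at which label-image
#'   snapshots are written to `outDir`.
#' @param verbose print progress every 1,000 MCS.
#' @return A [SimulationResult-class].
#' @export
runExperiment <- function(preset = "wild_type", seed = 1L, outDir = NULL,
                          snapshotEvery = NULL, verbose = FALSE) {
  if (is.character(preset)) preset <- eyePreset(preset)
  seed <- as.integer(seed)
  set.seed(seed)
  params <- preset@params
  eye <- generateSyntheticField(preset@fieldSpec, params)
  eye <- .applyVariantToField(eye, preset@variant, params)
  registry <- markBorderExempt(eye@field, eye@registry, params)
  st <- .stateFromObjects(eye@field, registry, preset@energies, params)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  records <- vector("list", params@totalMCS %/% params@reportInterval + 1L)
  records[[1]] <- .scoreState(st, params)
  ri <- 1L
  accAcc <- 0; accAtt <- 0
  onFail <- function(e, mcs) {
    if (!is.null(outDir))
      try(exportField(.fieldFromState(st), .registryFromState(st),
                      file.path(outDir, sprintf("crash_mcs%07d.png", mcs))),
          silent = TRUE)
    stop(sprintf("experiment aborted at MCS %d: %s", mcs,
                 conditionMessage(e)), call. = FALSE)
  }
  for (m in seq_len(params@totalMCS)) {
    tryCatch({
      blk <- .stepState(st)
      accAcc <- accAcc + blk$accepted; accAtt <- accAtt + blk$attempts
      .expansionHook(st, preset@expansion)
      .deathHook(st, preset@death)
    }, error = function(e) onFail(e, m))
    if (m %% params@reportInterval == 0) {
      ri <- ri + 1L
      records[[ri]] <- .scoreState(st, params)
    }
    if (!is.null(snapshotEvery) && !is.null(outDir) &&
        m %% snapshotEvery == 0)
      exportField(.fieldFromState(st), .registryFromState(st),
                  file.path(outDir, sprintf("snapshot_mcs%07d.png", m)))
    if (verbose && m %% 1000 == 0) {
      e <- cpp_total_energy(st$owner, st$ncells, st$typeOf, st$J, st$AT,
                            st$PT, st$lamA, st$lamP, params@boundaryOrder)
      message(sprintf("MCS %6d: H = %.0f, %d cells, acceptance %.3f", m,
                      sum(e), sum(st$registered & st$alive),
                      accAcc / max(accAtt, 1)))
      accAcc <- 0; accAtt <- 0
    }
  }
  ts <- do.call(rbind, records[seq_len(ri)])
  rownames(ts) <- NULL
  field <- .fieldFromState(st)
  registry <- .registryFromState(st)
  manifest <- list(
    preset = preset@name, seed = seed,
    package_version = as.character(utils::packageVersion("eyeCPM")),
    engine = list(temperature = params@temperature,
                  boundary_order = params@boundaryOrder,
                  copy_order = params@copyOrder,
                  total_mcs = params@totalMCS,
                  seconds_per_mcs = params@secondsPerMCS,
                  report_interval = params@reportInterval),
    energies = preset@energies@J,
    death = list(L = preset@death@thresholdLength,
                 lambda_death = preset@death@lambdaDeath,
                 p_max = preset@death@pMax,
                 onset_mcs = preset@death@onsetMCS,
                 enabled = preset@death@enabled),
    expansion = list(entries = preset@expansion@entries,
                     enabled = preset@expansion@enabled),
    variant = list(adhesion_mode = preset@variant@adhesionMode,
                   death_L = preset@variant@deathL,
                   death_enabled = preset@variant@deathEnabled,
                   oc_expansion = preset@variant@ocExpansion,
                   ipc_growth = preset@variant@ipcGrowth),
    field_spec = list(rows = preset@fieldSpec@rows,
                      cols = preset@fieldSpec@cols,
                      oc_radius = preset@fieldSpec@ocRadius,
                      spacing = preset@fieldSpec@spacing,
                      ipc_band_cells = preset@fieldSpec@ipcBandCells,
                      medium_margin = preset@fieldSpec@mediumMargin))
  res <- new("SimulationResult", timeseries = ts, field = field,
             registry = registry, preset = preset, seed = seed,
             manifest = manifest)
  if (!is.null(outDir)) {
    write.csv(ts, file.path(outDir, "timeseries.csv"), row.names = FALSE)
    write.csv(registry@cells, file.path(outDir, "final_registry.csv"),
              row.names = FALSE)
    exportField(field, registry, file.path(outDir, "final_field.png"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  res
}

.scoreState <- function(st, params) {
  scoreField(.fieldFromState(st), .registryFromState(st), params)
}

#' First MCS at which a time-series column reaches its final value
#'
#' Scans a recorded time series for the first report at which the column
#' equals its run-end value and never changes afterwards. Used to measure
#' when patterning is complete.
#'
#' @param timeseries data.frame as returned by [timeSeries()].
#' @param column column name (default central-ommatidia tertiary count).
#' @return MCS of the first stable record.
#' @export
plateauMCS <- function(timeseries, column = "n_tertiary_central") {
  v <- timeseries[[column]]
  final <- v[length(v)]
  bad <- which(v != final)
  if (!length(bad)) return(timeseries$mcs[1])
  timeseries$mcs[max(bad) + 1L]
}

#' Run a parameter sweep
#'
#' One run per grid point per seed, aggregating final metrics. Supported
#' grid variables: `preset` (preset name), `temperature`, `deathL`,
#' `adhesionMode`, `ocExpansion`, `ipcGrowth`, `deathEnabled`, `totalMCS`.
#' Failed runs are recorded (`error` column) and the sweep continues.
#'
#' @param grid data.frame (or named list, expanded via [expand.grid()]) of
#'   parameter combinations.
#' @param seeds integer vector of seeds.
#' @param fieldSpec a [SyntheticFieldSpec-class] shared by all runs.
#' @param basePreset preset name used where the grid does not say otherwise.
#' @param totalMCS default run length for the sweep.
#' @return data.frame with one row per run: grid variables, `seed`, final
#'   time-series record, `plateau_mcs` and `error`.
#' @export
runSweep <- function(grid, seeds = 1:5, fieldSpec = syntheticFieldSpec(),
                     basePreset = "wild_type", totalMCS = 50000L) {
  if (!is.data.frame(grid))
    grid <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    for (s in seeds) {
      row <- grid[g, , drop = FALSE]
      res <- tryCatch({
        preset <- .presetFromGridRow(row, fieldSpec, basePreset, totalMCS)
        sim <- runExperiment(preset, seed = s)
        ts <- sim@timeseries
        cbind(row, seed = s, ts[nrow(ts), ],
              plateau_mcs = plateauMCS(ts), error = NA_character_,
              row.names = NULL)
      }, error = function(e) {
        cbind(row, seed = s, error = conditionMessage(e), row.names = NULL)
      })
      out[[length(out) + 1L]] <- res
    }
  }
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
    df[cols]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.presetFromGridRow <- function(row, fieldSpec, basePreset, totalMCS) {
  nameArg <- if ("preset" %in% names(row)) as.character(row$preset) else basePreset
  tempArg <- if ("temperature" %in% names(row)) row$temperature else 60
  mcsArg <- if ("totalMCS" %in% names(row)) row$totalMCS else totalMCS
  p <- eyePreset(nameArg, fieldSpec = fieldSpec, totalMCS = mcsArg,
                 temperature = tempArg)
  v <- p@variant
  if ("deathL" %in% names(row)) v@deathL <- row$deathL
  if ("adhesionMode" %in% names(row)) v@adhesionMode <- as.character(row$adhesionMode)
  if ("ocExpansion" %in% names(row)) v@ocExpansion <- as.character(row$ocExpansion)
  if ("ipcGrowth" %in% names(row)) v@ipcGrowth <- row$ipcGrowth
  if ("deathEnabled" %in% names(row)) v@deathEnabled <- row$deathEnabled
  ## re-derive from an unmodified base so variant application is idempotent
  base <- eyePreset("wild_type", fieldSpec = fieldSpec, totalMCS = mcsArg,
                    temperature = tempArg)
  applyVariant(base, v)
}
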