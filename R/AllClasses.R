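#' @useDynLib eyeCPM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats runif setNames aggregate dist
#' @importFrom utils write.csv read.csv
NULL

.CELL_TYPES <- c("Medium", "OC", "IPC", "OC_compartment")

## type codes used by the C++ kernel: Medium = 0, OC = 1, IPC = 2,
## OC_compartment = 3 (a half of a compartment-split ommatidial core)
.typeCode <- function(type) match(type, .CELL_TYPES) - 1L

## which type codes count as "OC" for contact aggregation and scoring
.isOCCode <- c(FALSE, TRUE, FALSE, TRUE)

#' Cell field: the simulation lattice
#'
#' A `CellField` is a two-dimensional periodic square lattice in which every
#' site is owned by exactly one cell. Site ownership is stored as an integer
#' matrix indexed `[x, y]`; the value 0 is reserved for Medium, the
#' unconstrained "cell" representing the space outside the tissue margin.
#' Opposite lattice edges are identified (periodic boundary conditions).
#'
#' @slot owner integer matrix of cell identifiers, `owner[x, y] >= 0`.
#' @slot mcs integer, elapsed Monte Carlo Steps.
#'
#' @export
setClass("CellField",
  representation(owner = "matrix", mcs = "integer"),
  validity = function(object) {
    ow <- object@owner
    if (!is.numeric(ow)) return("owner must be an integer matrix")
    if (any(ow < 0)) return("cell identifiers must be >= 0 (0 is Medium)")
    if (any(ow != round(ow))) return("owner must contain integers")
    if (nrow(ow) < 3 || ncol(ow) < 3)
      return("lattice must be at least 3x3 for periodic neighborhoods")
    if (length(object@mcs) != 1 || is.na(object@mcs) || object@mcs < 0)
      return("mcs must be a single non-negative integer")
    TRUE
  }
)

#' Construct a cell field
#'
#' @param owner integer matrix of cell identifiers (0 = Medium), indexed
#'   `[x, y]`.
#' @param mcs elapsed Monte Carlo Steps (default 0).
#' @return A [CellField-class] object.
#' @examples
#' f <- cellField(matrix(0L, 8, 8))
#' dim(f)
#' @export
cellField <- function(owner, mcs = 0L) {
  storage.mode(owner) <- "integer"
  new("CellField", owner = owner, mcs = as.integer(mcs))
}

#' Cell registry: per-cell bookkeeping
#'
#' One row per living cell (Medium is implicit and never listed). Columns:
#' `cell_id`, `type` (one of `"OC"`, `"IPC"`, `"OC_compartment"`), `area`,
#' `perimeter`, `target_area`, `target_perimeter`, `lambda_area`,
#' `lambda_perimeter`, `initial_target_area`, `initial_target_perimeter`,
#' `death_exempt`, `expansion_enabled`, `dying`, `group_id`, `central_oc`.
#' The `group_id` column identifies compartment-split ommatidial cores that
#' are merged for scoring; for ordinary cells it equals `cell_id`.
#' `central_oc` records, for core rows, whether the ommatidium is "central"
#' (no contacting IPC lies on the exempt eye margin); it is fixed at
#' initialization so that time-series counts are comparable across a run.
#'
#' @slot cells data.frame as described above.
#' @export
setClass("CellRegistry",
  representation(cells = "data.frame"),
  validity = function(object) {
    df <- object@cells
    need <- c("cell_id", "type", "area", "perimeter", "target_area",
              "target_perimeter", "lambda_area", "lambda_perimeter",
              "initial_target_area", "initial_target_perimeter",
              "death_exempt", "expansion_enabled", "dying", "group_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(df$cell_id)) return("duplicate cell_id")
    if (any(df$cell_id < 1)) return("cell_id must be >= 1 (0 is Medium)")
    if (!all(df$type %in% .CELL_TYPES[-1]))
      return("type must be one of OC, IPC, OC_compartment")
    if (any(df$area < 0)) return("areas must be non-negative")
    bad <- df$dying & df$target_area != 0
    if (any(bad))
      return(paste0("dying cell must have target_area 0 (cell ",
                    df$cell_id[which(bad)[1]], ")"))
    TRUE
  }
)

#' Construct a cell registry
#'
#' Fills derived and optional columns with defaults: targets default to the
#' current area/perimeter, initial targets to the targets, flags to `FALSE`
#' and `group_id` to `cell_id`.
#'
#' @param cells data.frame with at least `cell_id`, `type`, `area`,
#'   `perimeter`.
#' @return A [CellRegistry-class] object.
#' @export
cellRegistry <- function(cells) {
  df <- as.data.frame(cells)
  if (is.null(df$target_area)) df$target_area <- df$area
  if (is.null(df$target_perimeter)) df$target_perimeter <- df$perimeter
  ## cores are strongly shape-constrained (round, stiff); IPCs are given
  ## minimal constraints so they can be crowded into polygonal shapes
  if (is.null(df$lambda_area))
    df$lambda_area <- ifelse(df$type == "IPC", 1, 6)
  if (is.null(df$lambda_perimeter))
    df$lambda_perimeter <- ifelse(df$type == "IPC", 0, 1)
  if (is.null(df$initial_target_area)) df$initial_target_area <- df$target_area
  if (is.null(df$initial_target_perimeter))
    df$initial_target_perimeter <- df$target_perimeter
  n <- nrow(df)
  if (is.null(df$death_exempt)) df$death_exempt <- rep(FALSE, n)
  if (is.null(df$expansion_enabled)) df$expansion_enabled <- df$type != "IPC"
  if (is.null(df$dying)) df$dying <- rep(FALSE, n)
  if (is.null(df$group_id)) df$group_id <- df$cell_id
  if (is.null(df$central_oc)) df$central_oc <- rep(NA, n)
  df$cell_id <- as.integer(df$cell_id)
  df$group_id <- as.integer(df$group_id)
  rownames(df) <- NULL
  new("CellRegistry", cells = df)
}

#' Contact energy table
#'
#' Symmetric boundary-energy coefficients `J` per unit contact length for
#' every unordered pair of cell types, Medium included. Lower `J` means
#' stronger adhesion. The wild-type preset follows the hierarchy
#' `J_OC,OC >> J_OC,Medium >> J_IPC,Medium > J_IPC,IPC >= J_IPC,OC`.
#'
#' @slot J named symmetric numeric matrix with rows/columns drawn from
#'   `Medium`, `OC`, `IPC`, `OC_compartment`.
#' @export
setClass("ContactEnergyTable",
  representation(J = "matrix"),
  validity = function(object) {
    J <- object@J
    if (is.null(rownames(J)) || is.null(colnames(J)) ||
        !identical(rownames(J), colnames(J)))
      return("J must have identical row and column names")
    if (!all(rownames(J) %in% .CELL_TYPES))
      return("J types must be among Medium, OC, IPC, OC_compartment")
    if (!"Medium" %in% rownames(J)) return("J must include Medium")
    if (!isTRUE(all.equal(J, t(J)))) return("J must be symmetric")
    TRUE
  }
)

#' Construct a contact energy table
#'
#' Defaults are the wild-type values: the two printed coefficients
#' (`J_OC,IPC = 35`, `J_IPC,IPC = 55`) plus declared values for the rest of
#' the hierarchy. `J_OC,OC` is very large because cores never touch in the
#' wild type.
#'
#' @param oc_ipc,ipc_ipc,oc_medium,ipc_medium,oc_oc,medium_medium boundary
#'   energies per link.
#' @return A [ContactEnergyTable-class] object.
#' @examples
#' J <- contactEnergyTable()
#' contactEnergy(J, "OC", "IPC")
#' @export
contactEnergyTable <- function(oc_ipc = 35, ipc_ipc = 55, oc_medium = 90,
                               ipc_medium = 70, oc_oc = 200,
                               medium_medium = 0) {
  ty <- c("Medium", "OC", "IPC")
  J <- matrix(0, 3, 3, dimnames = list(ty, ty))
  J["Medium", "Medium"] <- medium_medium
  J["Medium", "OC"] <- J["OC", "Medium"] <- oc_medium
  J["Medium", "IPC"] <- J["IPC", "Medium"] <- ipc_medium
  J["OC", "OC"] <- oc_oc
  J["OC", "IPC"] <- J["IPC", "OC"] <- oc_ipc
  J["IPC", "IPC"] <- ipc_ipc
  new("ContactEnergyTable", J = J)
}

#' Engine parameters
#'
#' @slot temperature numeric, the motility parameter `T` scaling acceptance
#'   of energy-raising copies (wild type 60).
#' @slot boundaryOrder integer, neighborhood order (1 or 2) for boundary
#'   energy, perimeter and contact counting; default 2 (8-neighborhood),
#'   which reduces lattice anisotropy.
#' @slot copyOrder integer, neighborhood order for copy-attempt proposals;
#'   default 1 (4-neighborhood).
#' @slot totalMCS integer, default run length (50,000 MCS).
#' @slot secondsPerMCS numeric, developmental seconds represented by one
#'   MCS (2 s).
#' @slot reportInterval integer, MCS between time-series records (500).
#' @export
setClass("EngineParameters",
  representation(temperature = "numeric", boundaryOrder = "integer",
                 copyOrder = "integer", totalMCS = "integer",
                 secondsPerMCS = "numeric", reportInterval = "integer"),
  validity = function(object) {
    if (object@temperature <= 0) return("temperature must be > 0")
    if (!object@boundaryOrder %in% c(1L, 2L))
      return("boundaryOrder must be 1 or 2")
    if (object@copyOrder != 1L)
      return("only order-1 copy neighborhoods are supported")
    if (object@totalMCS < 0) return("totalMCS must be >= 0")
    if (object@secondsPerMCS <= 0) return("secondsPerMCS must be > 0")
    if (object@reportInterval < 1) return("reportInterval must be >= 1")
    TRUE
  }
)

#' Construct engine parameters
#'
#' @param temperature motility `T` (default 60).
#' @param boundaryOrder neighborhood order for boundary energy/perimeter.
#' @param copyOrder neighborhood order for copy proposals (1).
#' @param totalMCS default run length.
#' @param secondsPerMCS seconds of developmental time per MCS.
#' @param reportInterval MCS between time-series records.
#' @return An [EngineParameters-class] object.
#' @export
engineParameters <- function(temperature = 60, boundaryOrder = 2L,
                             copyOrder = 1L, totalMCS = 50000L,
                             secondsPerMCS = 2, reportInterval = 500L) {
  new("EngineParameters", temperature = temperature,
      boundaryOrder = as.integer(boundaryOrder),
      copyOrder = as.integer(copyOrder), totalMCS = as.integer(totalMCS),
      secondsPerMCS = secondsPerMCS,
      reportInterval = as.integer(reportInterval))
}

#' Energy breakdown
#'
#' Total effective energy and its three components: boundary (adhesion),
#' area-constraint and perimeter-constraint terms.
#'
#' @slot boundary,area,perimeter,total numeric energies.
#' @export
setClass("EnergyBreakdown",
  representation(boundary = "numeric", area = "numeric",
                 perimeter = "numeric", total = "numeric"))

#' Programmed cell death rule
#'
#' IPCs die stochastically when their contact length with ommatidial cores
#' falls below a threshold `L`. The probability per MCS is
#' `P_MAX * (1 - cs/L)^lambdaDeath` for contact `cs < L` and exactly 0 at
#' and above `L`. All simulations use `lambdaDeath = 1.2` and
#' `pMax = 0.01`; death is switched on only after `onsetMCS` (10,000 MCS)
#' to let cell sizes equilibrate.
#'
#' @slot thresholdLength numeric, survival threshold `L` in boundary links
#'   (wild type 16; perturbations 12, 10).
#' @slot lambdaDeath numeric shape exponent.
#' @slot pMax numeric, maximum death probability per MCS.
#' @slot onsetMCS integer, first MCS at which death is evaluated.
#' @slot enabled logical.
#' @export
setClass("DeathRule",
  representation(thresholdLength = "numeric", lambdaDeath = "numeric",
                 pMax = "numeric", onsetMCS = "integer", enabled = "logical"),
  validity = function(object) {
    if (object@pMax < 0 || object@pMax > 1) return("pMax must be in [0, 1]")
    if (object@thresholdLength < 0) return("thresholdLength must be >= 0")
    if (object@lambdaDeath < 0) return("lambdaDeath must be >= 0")
    if (object@onsetMCS < 0) return("onsetMCS must be >= 0")
    TRUE
  }
)

#' Construct a death rule
#'
#' @param thresholdLength survival contact threshold `L` (links).
#' @param lambdaDeath shape exponent (1.2).
#' @param pMax maximum per-MCS death probability (0.01).
#' @param onsetMCS first MCS at which death applies (10,000).
#' @param enabled logical switch.
#' @return A [DeathRule-class] object.
#' @examples
#' deathProbability(c(0, 8, 16, 20), deathRule())
#' @export
deathRule <- function(thresholdLength = 16, lambdaDeath = 1.2, pMax = 0.01,
                      onsetMCS = 10000L, enabled = TRUE) {
  new("DeathRule", thresholdLength = thresholdLength,
      lambdaDeath = lambdaDeath, pMax = pMax,
      onsetMCS = as.integer(onsetMCS), enabled = enabled)
}

#' Apical expansion schedule
#'
#' Target area and target perimeter of expansion-enabled cells of the listed
#' types are incremented linearly in MCS until the target area reaches
#' `max_multiplier` times its initial value. The wild-type schedule doubles
#' ommatidial-core targets (`max_multiplier = 2`) linearly over
#' `completion_mcs = 10000` MCS, stepping every `interval_mcs = 100` MCS
#' (the in-vivo core doubling spans about 5.5 h = 10,000 MCS, and death is
#' delayed to the same point so that cell sizes have equilibrated first).
#'
#' @slot entries data.frame with columns `type`, `interval_mcs`,
#'   `completion_mcs`, `max_multiplier` and `perim_multiplier` (the
#'   perimeter analogue; defaults to `sqrt(max_multiplier)`, the scaling
#'   that keeps a growing disc round).
#' @slot enabled logical.
#' @export
setClass("ExpansionSchedule",
  representation(entries = "data.frame", enabled = "logical"),
  validity = function(object) {
    df <- object@entries
    need <- c("type", "interval_mcs", "completion_mcs", "max_multiplier",
              "perim_multiplier")
    if (!all(need %in% names(df)))
      return(paste("entries needs columns:", paste(need, collapse = ", ")))
    if (nrow(df) && any(df$max_multiplier < 1))
      return("max_multiplier must be >= 1")
    if (nrow(df) && any(df$interval_mcs < 1 | df$completion_mcs < 1))
      return("interval_mcs and completion_mcs must be >= 1")
    TRUE
  }
)

#' Construct an expansion schedule
#'
#' @param types cell types whose targets expand (default `"OC"`, which also
#'   covers compartment-split cores).
#' @param interval_mcs MCS between increments.
#' @param completion_mcs MCS at which the schedule completes.
#' @param max_multiplier ratio of final to initial target area (2 = doubling).
#' @param perim_multiplier ratio of final to initial target perimeter
#'   (default `sqrt(max_multiplier)`).
#' @param enabled logical switch.
#' @return An [ExpansionSchedule-class] object.
#' @export
expansionSchedule <- function(types = c("OC", "OC_compartment"),
                              interval_mcs = 100L, completion_mcs = 10000L,
                              max_multiplier = 2,
                              perim_multiplier = sqrt(max_multiplier),
                              enabled = TRUE) {
  entries <- data.frame(type = types, interval_mcs = as.integer(interval_mcs),
                        completion_mcs = as.integer(completion_mcs),
                        max_multiplier = max_multiplier,
                        perim_multiplier = perim_multiplier,
                        stringsAsFactors = FALSE)
  new("ExpansionSchedule", entries = entries, enabled = enabled)
}

#' Perturbation variant specification
#'
#' @slot adhesionMode `"preferential"` (`J_OC,IPC < J_IPC,IPC`), `"flat"`
#'   (equal) or `"anti_preferential"` (`J_IPC,IPC < J_OC,IPC`).
#' @slot deathL numeric override of the survival threshold (NA = keep).
#' @slot deathEnabled logical.
#' @slot ocExpansion `"all"`, `"none"`, `"all_but_one"` or `"half_of_one"`.
#' @slot ipcGrowth logical; if TRUE, IPC targets double linearly over the
#'   whole run.
#' @export
setClass("VariantSpec",
  representation(adhesionMode = "character", deathL = "numeric",
                 deathEnabled = "logical", ocExpansion = "character",
                 ipcGrowth = "logical"),
  validity = function(object) {
    if (!object@adhesionMode %in% c("preferential", "flat", "anti_preferential"))
      return("adhesionMode must be preferential, flat or anti_preferential")
    if (!object@ocExpansion %in% c("all", "none", "all_but_one", "half_of_one"))
      return("ocExpansion must be all, none, all_but_one or half_of_one")
    TRUE
  }
)

#' Construct a variant specification
#'
#' @param adhesionMode,deathL,deathEnabled,ocExpansion,ipcGrowth see
#'   [VariantSpec-class].
#' @return A [VariantSpec-class] object.
#' @export
variantSpec <- function(adhesionMode = "preferential", deathL = NA_real_,
                        deathEnabled = TRUE, ocExpansion = "all",
                        ipcGrowth = FALSE) {
  new("VariantSpec", adhesionMode = adhesionMode, deathL = deathL,
      deathEnabled = deathEnabled, ocExpansion = ocExpansion,
      ipcGrowth = ipcGrowth)
}

#' Synthetic eye-field specification
#'
#' Geometry of the generated initial condition: a hexagonally offset grid of
#' disc-shaped ommatidial cores, interstitial space tiled by IPCs one to two
#' cells deep, a bounding ring of IPCs, and Medium outside. The default
#' core radius is calibrated so that an initial core circumference
#' (order-2 links) is roughly 10-12 times the wild-type death threshold
#' L = 16, placing each abutting IPC's initial core contact near the
#' threshold.
#'
#' @slot rows,cols integer ommatidia counts (>= 2).
#' @slot ocRadius numeric core radius in lattice units.
#' @slot spacing numeric center-to-center distance (> 2 * ocRadius so cores
#'   never touch at initialization).
#' @slot ipcBandCells integer IPCs seeded per inter-core corridor.
#' @slot mediumMargin numeric width of the Medium margin.
#' @slot seed integer or NA; if set, the generator seeds R's RNG locally.
#' @export
setClass("SyntheticFieldSpec",
  representation(rows = "integer", cols = "integer", ocRadius = "numeric",
                 spacing = "numeric", ipcBandCells = "integer",
                 mediumMargin = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@rows < 2 || object@cols < 2) return("rows and cols must be >= 2")
    if (object@spacing <= 2 * object@ocRadius)
      return("spacing must exceed 2 * ocRadius (cores must not touch)")
    if (object@ipcBandCells < 1) return("ipcBandCells must be >= 1")
    if (object@mediumMargin < 2) return("mediumMargin must be >= 2")
    TRUE
  }
)

#' Construct a synthetic field specification
#'
#' @param rows,cols ommatidia grid size (default 4 x 4).
#' @param ocRadius core radius (9).
#' @param spacing center-to-center spacing (26).
#' @param ipcBandCells IPCs seeded per inter-core corridor (2).
#' @param mediumMargin Medium margin width (32; wide enough that the
#'   tissue can expand without exhausting the Medium).
#' @param seed optional integer seed for the generator's jitter.
#' @return A [SyntheticFieldSpec-class] object.
#' @export
syntheticFieldSpec <- function(rows = 4L, cols = 4L, ocRadius = 9,
                               spacing = 25, ipcBandCells = 2L,
                               mediumMargin = 32, seed = NA_integer_) {
  new("SyntheticFieldSpec", rows = as.integer(rows), cols = as.integer(cols),
      ocRadius = ocRadius, spacing = spacing,
      ipcBandCells = as.integer(ipcBandCells), mediumMargin = mediumMargin,
      seed = as.integer(seed))
}

#' Eye field: lattice plus registry
#'
#' Container pairing a [CellField-class] with its [CellRegistry-class] and,
#' when known, the ommatidial-core centers used for hexagon scoring.
#'
#' @slot field a [CellField-class].
#' @slot registry a [CellRegistry-class].
#' @slot centers numeric matrix (one row per core, columns x, y) or
#'   0-row matrix when unknown.
#' @export
setClass("EyeField",
  representation(field = "CellField", registry = "CellRegistry",
                 centers = "matrix"))

#' Experiment preset
#'
#' A fully resolved run configuration: engine parameters, contact energies,
#' death rule, expansion schedule, variant and field specification.
#'
#' @slot name character preset name.
#' @slot params an [EngineParameters-class].
#' @slot energies a [ContactEnergyTable-class].
#' @slot death a [DeathRule-class].
#' @slot expansion an [ExpansionSchedule-class].
#' @slot variant a [VariantSpec-class].
#' @slot fieldSpec a [SyntheticFieldSpec-class].
#' @export
setClass("ExperimentPreset",
  representation(name = "character", params = "EngineParameters",
                 energies = "ContactEnergyTable", death = "DeathRule",
                 expansion = "ExpansionSchedule", variant = "VariantSpec",
                 fieldSpec = "SyntheticFieldSpec"))

#' Simulation result
#'
#' @slot timeseries data.frame of per-interval records (see
#'   [runExperiment()]).
#' @slot field final [CellField-class].
#' @slot registry final [CellRegistry-class] (dead cells dropped).
#' @slot preset the [ExperimentPreset-class] that was run.
#' @slot seed integer RNG seed.
#' @slot manifest list of fully resolved settings sufficient to reproduce
#'   the run.
#' @export
setClass("SimulationResult",
  representation(timeseries = "data.frame", field = "CellField",
                 registry = "CellRegistry", preset = "ExperimentPreset",
                 seed = "integer", manifest = "list"))
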