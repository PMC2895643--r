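#' @describeIn CellField-class lattice dimensions (width, height).
#' @param x a `CellField`.
#' @export
setMethod("dim", "CellField", function(x) dim(x@owner))

#' Site-ownership matrix
#'
#' @param object a [CellField-class] or [EyeField-class].
#' @return integer matrix of cell identifiers indexed `[x, y]`.
#' @export
setGeneric("siteOwner", function(object) standardGeneric("siteOwner"))

#' @rdname siteOwner
#' @export
setMethod("siteOwner", "CellField", function(object) object@owner)

#' @rdname siteOwner
#' @export
setMethod("siteOwner", "EyeField", function(object) object@field@owner)

#' Elapsed Monte Carlo Steps
#'
#' @param object a [CellField-class].
#' @return integer MCS counter.
#' @export
setGeneric("mcsCount", function(object) standardGeneric("mcsCount"))

#' @rdname mcsCount
#' @export
setMethod("mcsCount", "CellField", function(object) object@mcs)

#' Registry table accessors
#'
#' `cellTable()` returns the per-cell data.frame; `cellIds()`, `cellTypes()`
#' and `nCells()` are convenience accessors.
#'
#' @param object a [CellRegistry-class] or [EyeField-class].
#' @return `cellTable()`: data.frame; `cellIds()`: integer vector;
#'   `cellTypes()`: named character vector; `nCells()`: integer.
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))

#' @rdname cellTable
#' @export
setMethod("cellTable", "CellRegistry", function(object) object@cells)

#' @rdname cellTable
#' @export
setMethod("cellTable", "EyeField", function(object) object@registry@cells)

#' @rdname cellTable
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname cellTable
#' @export
setMethod("cellIds", "CellRegistry", function(object) object@cells$cell_id)

#' @rdname cellTable
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname cellTable
#' @export
setMethod("cellTypes", "CellRegistry",
          function(object) setNames(object@cells$type,
                                    object@cells$cell_id))

#' @rdname cellTable
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname cellTable
#' @export
setMethod("nCells", "CellRegistry", function(object) nrow(object@cells))

#' Look up a boundary-energy coefficient
#'
#' @param object a [ContactEnergyTable-class].
#' @param type1,type2 cell type names.
#' @return numeric `J(type1, type2)`.
#' @export
setGeneric("contactEnergy",
           function(object, type1, type2) standardGeneric("contactEnergy"))

#' @rdname contactEnergy
#' @export
setMethod("contactEnergy", "ContactEnergyTable", function(object, type1, type2) {
  object@J[type1, type2]
})

#' Total of an energy breakdown
#'
#' @param object an [EnergyBreakdown-class].
#' @return numeric total energy.
#' @export
setGeneric("energyTotal", function(object) standardGeneric("energyTotal"))

#' @rdname energyTotal
#' @export
setMethod("energyTotal", "EnergyBreakdown", function(object) object@total)

#' Time series of a simulation result
#'
#' @param object a [SimulationResult-class].
#' @return data.frame of per-interval records.
#' @export
setGeneric("timeSeries", function(object) standardGeneric("timeSeries"))

#' @rdname timeSeries
#' @export
setMethod("timeSeries", "SimulationResult", function(object) object@timeseries)

setMethod("show", "CellField", function(object) {
  d <- dim(object@owner)
  cat(sprintf("CellField: %d x %d periodic lattice, %d cells + Medium, %d MCS\n",
              d[1], d[2], length(setdiff(unique(as.vector(object@owner)), 0L)),
              object@mcs))
})

setMethod("show", "CellRegistry", function(object) {
  df <- object@cells
  cat(sprintf("CellRegistry: %d cells (%s)\n", nrow(df),
              paste(sprintf("%s=%d", names(table(df$type)), table(df$type)),
                    collapse = ", ")))
})

setMethod("show", "ContactEnergyTable", function(object) {
  cat("ContactEnergyTable (boundary energy per link):\n")
  print(object@J)
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown: H = %.6g (boundary %.6g + area %.6g + perimeter %.6g)\n",
              object@total, object@boundary, object@area, object@perimeter))
})

setMethod("show", "DeathRule", function(object) {
  cat(sprintf(
    "DeathRule: L = %g links, lambda = %g, P_MAX = %g/MCS, onset %d MCS%s\n",
    object@thresholdLength, object@lambdaDeath, object@pMax, object@onsetMCS,
    if (object@enabled) "" else " (disabled)"))
})

setMethod("show", "ExpansionSchedule", function(object) {
  if (!object@enabled || nrow(object@entries) == 0) {
    cat("ExpansionSchedule: disabled\n")
  } else {
    cat("ExpansionSchedule:\n")
    print(object@entries)
  }
})

setMethod("show", "EyeField", function(object) {
  show(object@field)
  show(object@registry)
})

setMethod("show", "ExperimentPreset", function(object) {
  cat(sprintf("ExperimentPreset '%s': T = %g, L = %g%s, %d MCS, %dx%d ommatidia\n",
              object@name, object@params@temperature,
              object@death@thresholdLength,
              if (object@death@enabled) "" else " (death off)",
              object@params@totalMCS, object@fieldSpec@rows,
              object@fieldSpec@cols))
})

setMethod("show", "SimulationResult", function(object) {
  ts <- object@timeseries
  last <- ts[nrow(ts), ]
  cat(sprintf(
    "SimulationResult '%s' (seed %d): %d MCS, %d cells, %d 2deg, %d 3deg (central %d/%d)\n",
    object@preset@name, object@seed, last$mcs, last$n_cells,
    last$n_secondary, last$n_tertiary, last$n_secondary_central,
    last$n_tertiary_central))
})
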