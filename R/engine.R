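#' Total effective energy of a configuration
#'
#' Evaluates the Glazier-Graner-Hogeweg effective energy
#' \deqn{H = \sum_{links} J(\tau_i, \tau_j) + \sum_c \lambda_A (A_c - A_{T,c})^2
#'       + \sum_c \lambda_P (P_c - P_{T,c})^2}
#' where the boundary sum runs over all neighbor links (within
#' `boundaryOrder`) joining sites of different cells, and the shape sums run
#' over registered non-Medium cells. Medium contributes boundary links only.
#'
#' @param field a [CellField-class].
#' @param registry a [CellRegistry-class] consistent with `field`; an
#'   inconsistent registry raises an integrity error naming the offending
#'   cell.
#' @param energies a [ContactEnergyTable-class].
#' @param params an [EngineParameters-class].
#' @return An [EnergyBreakdown-class].
#' @examples
#' ow <- matrix(0L, 6, 6); ow[3:4, 3:4] <- 1L
#' reg <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 4,
#'                                perimeter = 8, lambda_perimeter = 0))
#' totalEnergy(cellField(ow), reg, contactEnergyTable(ipc_medium = 10),
#'             engineParameters(boundaryOrder = 1))
#' @export
totalEnergy <- function(field, registry, energies, params = engineParameters()) {
  .checkConsistency(field, registry, params)
  st <- .stateFromObjects(field, registry, energies, params)
  e <- cpp_total_energy(st$owner, st$ncells, st$typeOf, st$J, st$AT, st$PT,
                        st$lamA, st$lamP, params@boundaryOrder)
  new("EnergyBreakdown", boundary = e[["boundary"]], area = e[["area"]],
      perimeter = e[["perimeter"]], total = sum(e))
}

#' Energy change of a proposed copy attempt
#'
#' Returns `H(after) - H(before)` for hypothetically copying the owner of
#' `source` onto `target`, computed incrementally from local information.
#' The field is not modified. A proposal whose source and target already
#' share an owner is a no-op and returns 0.
#'
#' @inheritParams totalEnergy
#' @param source,target length-2 integer vectors `c(x, y)` of 1-based
#'   lattice coordinates; they must be neighbors within the copy
#'   neighborhood (order 1, periodic).
#' @return numeric energy difference.
#' @export
deltaH <- function(field, registry, energies, params = engineParameters(),
                   source, target) {
  ow <- field@owner
  W <- nrow(ow); H <- ncol(ow)
  s <- as.integer(source); t <- as.integer(target)
  if (any(s < 1) || any(t < 1) || s[1] > W || t[1] > W || s[2] > H || t[2] > H)
    stop("source/target coordinates outside the lattice")
  dx <- (s[1] - t[1]) %% W; dy <- (s[2] - t[2]) %% H
  dx <- min(dx, W - dx); dy <- min(dy, H - dy)
  if (dx + dy != 1L)
    stop("source and target must be order-1 neighbors (periodic)")
  st <- .stateFromObjects(field, registry, energies, params)
  cpp_delta_h(st$owner, st$ncells, st$typeOf, st$J, st$area, st$perim,
              st$AT, st$PT, st$lamA, st$lamP,
              s[1] - 1L, s[2] - 1L, t[1] - 1L, t[2] - 1L,
              params@boundaryOrder)
}

#' Metropolis acceptance
#'
#' Accepts an energy-lowering or energy-neutral copy with probability 1 and
#' an energy-raising copy with probability `exp(-dH/T)`. Exactly one uniform
#' variate is drawn when `dH > 0` and none otherwise.
#'
#' @param dH numeric energy difference of the proposal.
#' @param temperature motility parameter `T > 0`.
#' @return logical: accept?
#' @export
metropolisAccept <- function(dH, temperature) {
  stopifnot(temperature > 0)
  if (dH <= 0) return(TRUE)
  runif(1) < exp(-dH / temperature)
}

#' Advance the simulation by whole Monte Carlo Steps
#'
#' One MCS performs `width * height` copy attempts. Each attempt picks a
#' uniformly random target site and one of its four order-1 neighbors as
#' source, proposing to copy the source's owner onto the target; attempts
#' whose sites share an owner count as no-ops. Acceptance follows
#' [metropolisAccept()]. Cached areas, perimeters and core-contact lengths
#' are updated incrementally. After the lattice sweep of each MCS the hooks
#' are invoked in fixed order: `expansion`, `death`, `scoring`. Each hook is
#' a function receiving the internal state environment.
#'
#' @inheritParams totalEnergy
#' @param n number of MCS to run.
#' @param hooks optional named list of per-MCS hook functions (`expansion`,
#'   `death`, `scoring`).
#' @return list with updated `field` and `registry` (cells whose area
#'   reached 0 are removed from the registry).
#' @export
runMCS <- function(field, registry, energies, params = engineParameters(),
                   n = 1L, hooks = list()) {
  st <- .stateFromObjects(field, registry, energies, params)
  for (i in seq_len(n)) {
    .stepState(st)
    for (h in c("expansion", "death", "scoring"))
      if (!is.null(hooks[[h]])) hooks[[h]](st)
  }
  list(field = .fieldFromState(st), registry = .registryFromState(st))
}

## single-MCS kernel call on a state environment
.stepState <- function(st) {
  blk <- cpp_mcs_block(st$owner, st$ncells, st$typeOf, st$J, st$area,
                       st$perim, st$AT, st$PT, st$lamA, st$lamP, st$alive,
                       st$ocContact, .isOCCode, st$params@temperature, 1L,
                       st$params@boundaryOrder)
  st$mcs <- st$mcs + 1L
  invisible(blk)
}

#' Contact lengths of one cell
#'
#' Counts shared boundary links (within `boundaryOrder`) between the given
#' cell and each of its neighbors, plus aggregates by neighbor type. The
#' count is symmetric: `contact(a, b) == contact(b, a)`.
#'
#' @inheritParams totalEnergy
#' @param cellId identifier of a cell with positive area.
#' @return list with `cells` (named numeric vector, names are neighbor cell
#'   ids, `"0"` is Medium) and `types` (named numeric aggregate per neighbor
#'   type, including `"OC_total"`, the aggregate over ommatidial-core types
#'   used by the death rule).
#' @export
contactLengths <- function(field, registry, params = engineParameters(),
                           cellId) {
  df <- registry@cells
  if (!cellId %in% df$cell_id)
    stop("unknown cell_id: ", cellId)
  n <- max(df$cell_id)
  M <- cpp_contact_matrix(field@owner, n, params@boundaryOrder)
  row <- M[cellId + 1L, ]
  nb <- which(row > 0) - 1L
  cells <- setNames(row[nb + 1L], nb)
  typeOf <- c("Medium", df$type[match(seq_len(n), df$cell_id)])
  types <- c(Medium = 0, OC = 0, IPC = 0, OC_compartment = 0)
  for (i in seq_along(nb)) {
    ty <- typeOf[nb[i] + 1L]
    if (!is.na(ty)) types[ty] <- types[ty] + cells[i]
  }
  types <- c(types, OC_total = unname(types["OC"] + types["OC_compartment"]))
  list(cells = cells, types = types)
}

## full contact matrix for a functional field (internal)
.contactMatrix <- function(field, registry, params) {
  n <- max(c(registry@cells$cell_id, 0L))
  cpp_contact_matrix(field@owner, n, params@boundaryOrder)
}
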