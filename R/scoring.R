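## Cell-cell contact for classification is measured in lattice units:
## order-1 (edge) links, matching the death rule's contact lengths. A
## contact of a single edge link is a transient pinch between jiggling
## membranes; two or more links count as a real contact.
.MIN_SCORE_CONTACT <- 2

## Shared scoring core: from a contact matrix, per-cell OC-neighbor counts
## with compartment-split cores merged, tertiary/secondary flags and the
## central-ommatidium restriction.
.scoringContactMatrix <- function(field, registry) {
  n <- max(c(registry@cells$cell_id, 0L))
  cpp_contact_matrix(field@owner, n, 1L)
}

.scoreContacts <- function(M, registry) {
  M <- M * (M >= .MIN_SCORE_CONTACT)
  df <- registry@cells
  n <- nrow(df)
  ids <- df$cell_id
  isOCType <- df$type %in% c("OC", "OC_compartment")
  ocIds <- ids[isOCType]
  ocGroups <- df$group_id[isOCType]
  ipcIds <- ids[df$type == "IPC"]

  ## distinct OC groups contacted by each cell
  ocGroupCount <- function(id) {
    row <- M[id + 1L, ocIds + 1L]
    length(unique(ocGroups[row > 0]))
  }
  nOCnb <- setNames(vapply(ids, ocGroupCount, numeric(1)), ids)

  tertiary <- ipcIds[nOCnb[as.character(ipcIds)] == 3]
  secondary <- integer(0)
  for (id in ipcIds) {
    if (nOCnb[as.character(id)] != 2) next
    row <- M[id + 1L, ]
    nbs <- which(row > 0) - 1L
    if (sum(nbs %in% tertiary) == 2) secondary <- c(secondary, id)
  }

  ## central ommatidia: cores none of whose contacting IPCs is
  ## border-exempt (i.e. away from the non-dying eye margin); frozen at
  ## initialization when the registry carries the central_oc flag
  if (!is.null(df$central_oc) && any(!is.na(df$central_oc))) {
    centralGroups <- unique(df$group_id[isOCType &
                                        df$central_oc %in% TRUE])
  } else {
    exemptIds <- df$cell_id[df$death_exempt]
    centralGroups <- unique(ocGroups[vapply(ocIds, function(id) {
      row <- M[id + 1L, ]
      nbs <- which(row > 0) - 1L
      !any(nbs %in% exemptIds)
    }, logical(1))])
  }
  allOCofCell <- function(id) {
    row <- M[id + 1L, ocIds + 1L]
    unique(ocGroups[row > 0])
  }
  centralOnly <- function(set) {
    set[vapply(set, function(id) all(allOCofCell(id) %in% centralGroups),
               logical(1))]
  }
  list(tertiary = tertiary, secondary = secondary,
       tertiary_central = centralOnly(tertiary),
       secondary_central = centralOnly(secondary),
       oc_neighbor_count = nOCnb, central_groups = centralGroups)
}

#' Classify a tertiary pigment cell
#'
#' A living IPC is a tertiary (3°) when it contacts exactly three distinct
#' ommatidial cores; the two halves of a compartment-split core count as one
#' core.
#'
#' @param field a [CellField-class].
#' @param registry a [CellRegistry-class].
#' @param params an [EngineParameters-class].
#' @param cellId identifier of a living IPC (anything else is a
#'   classification error).
#' @return logical flag.
#' @export
classifyTertiary <- function(field, registry, params = engineParameters(),
                             cellId) {
  df <- registry@cells
  i <- match(cellId, df$cell_id)
  if (is.na(i) || df$type[i] != "IPC")
    stop("classification error: cell ", cellId, " is not a living IPC")
  M <- .scoringContactMatrix(field, registry)
  sc <- .scoreContacts(M, registry)
  cellId %in% sc$tertiary
}

#' Classify a secondary pigment cell
#'
#' A living IPC is a secondary (2°) when it contacts exactly two distinct
#' ommatidial cores and exactly two cells of the given tertiary set.
#'
#' @inheritParams classifyTertiary
#' @param tertiarySet integer ids of the snapshot's tertiary cells (computed
#'   first, e.g. via [classifyTertiary()]).
#' @return logical flag.
#' @export
classifySecondary <- function(field, registry, params = engineParameters(),
                              cellId, tertiarySet) {
  df <- registry@cells
  i <- match(cellId, df$cell_id)
  if (is.na(i) || df$type[i] != "IPC")
    stop("classification error: cell ", cellId, " is not a living IPC")
  M <- .scoringContactMatrix(field, registry)
  M <- M * (M >= .MIN_SCORE_CONTACT)
  isOCType <- df$type %in% c("OC", "OC_compartment")
  ocIds <- df$cell_id[isOCType]
  ocGroups <- df$group_id[isOCType]
  row <- M[cellId + 1L, ]
  nOC <- length(unique(ocGroups[row[ocIds + 1L] > 0]))
  nbs <- which(row > 0) - 1L
  nOC == 2 && sum(nbs %in% tertiarySet) == 2
}

#' Score one snapshot
#'
#' Counts living cells, secondary and tertiary pigment cells (whole-field
#' and restricted to central ommatidia) and per-type mean area and
#' perimeter.
#'
#' @inheritParams classifyTertiary
#' @return one-row data.frame with columns `mcs`, `n_cells`, `n_oc`,
#'   `n_ipc`, `n_secondary`, `n_tertiary`, `n_secondary_central`,
#'   `n_tertiary_central`, `mean_area_OC`, `mean_area_IPC`,
#'   `mean_perim_OC`, `mean_perim_IPC`.
#' @export
scoreField <- function(field, registry, params = engineParameters()) {
  M <- .scoringContactMatrix(field, registry)
  sc <- .scoreContacts(M, registry)
  df <- registry@cells
  isOC <- df$type %in% c("OC", "OC_compartment")
  isIPC <- df$type == "IPC"
  data.frame(
    mcs = field@mcs,
    n_cells = nrow(df),
    n_oc = length(unique(df$group_id[isOC])),
    n_ipc = sum(isIPC),
    n_secondary = length(sc$secondary),
    n_tertiary = length(sc$tertiary),
    n_secondary_central = length(sc$secondary_central),
    n_tertiary_central = length(sc$tertiary_central),
    mean_area_OC = if (any(isOC)) mean(df$area[isOC]) else NA_real_,
    mean_area_IPC = if (any(isIPC)) mean(df$area[isIPC]) else NA_real_,
    mean_perim_OC = if (any(isOC)) mean(df$perimeter[isOC]) else NA_real_,
    mean_perim_IPC = if (any(isIPC)) mean(df$perimeter[isIPC]) else NA_real_)
}

#' Count IPCs within a hexagonal outline
#'
#' Reproduces the in-vivo scoring protocol: the centers of the six
#' ommatidia surrounding a focal ommatidium are connected into a hexagonal
#' outline, every IPC wholly inside counts 1, every IPC traversing the
#' outline counts 0.5, and IPCs wholly outside count 0.
#'
#' @inheritParams classifyTertiary
#' @param region numeric 6 x 2 matrix of core centers (columns x, y, 0-based
#'   lattice coordinates) forming a simple polygon.
#' @return half-integer IPC count.
#' @export
hexagonIPCCount <- function(field, registry, region,
                            params = engineParameters()) {
  region <- as.matrix(region)
  if (nrow(region) != 6 || ncol(region) != 2)
    stop("geometry error: region must be a 6 x 2 matrix of core centers")
  if (anyDuplicated(region))
    stop("geometry error: hexagon vertices must be distinct")
  bnd <- rbind(region, region[1, , drop = FALSE])
  df <- registry@cells
  ipcIds <- df$cell_id[df$type == "IPC"]
  ow <- field@owner
  total <- 0
  for (id in ipcIds) {
    w <- which(ow == id, arr.ind = TRUE) - 1  # 0-based site coords
    inside <- mgcv::in.out(bnd, w)
    total <- total + if (all(inside)) 1 else if (any(inside)) 0.5 else 0
  }
  total
}

#' Convert Monte Carlo Steps to developmental hours
#'
#' One MCS represents about 2 seconds of pupal development, so 10,000 MCS
#' correspond to approximately 5.5 hours after puparium formation.
#'
#' @param mcs non-negative MCS count.
#' @param secondsPerMCS seconds represented by one MCS (default 2).
#' @return hours of developmental time.
#' @examples
#' mcsToHours(10000)
#' @export
mcsToHours <- function(mcs, secondsPerMCS = 2) {
  if (any(mcs < 0)) stop("mcs must be >= 0")
  mcs * secondsPerMCS / 3600
}
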