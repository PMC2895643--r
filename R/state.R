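## Internal mutable run state.
##
## The C++ kernel works on flat vectors indexed by cell identifier (position
## id + 1; position 1 is Medium). The functions here convert between the
## functional S4 containers and an environment holding those vectors, which
## the kernel mutates in place during a run.

## 4x4 boundary-energy matrix indexed by type code (Medium, OC, IPC,
## OC_compartment). Missing OC_compartment entries are derived from OC, with
## the compartment-compartment energy 0 so that the two halves of a split
## core adhere as one body.
.buildJ <- function(energies) {
  J <- energies@J
  full <- matrix(0, 4, 4, dimnames = list(.CELL_TYPES, .CELL_TYPES))
  for (a in rownames(J)) for (b in colnames(J)) full[a, b] <- J[a, b]
  if (!"OC_compartment" %in% rownames(J)) {
    for (t in c("Medium", "OC", "IPC"))
      full["OC_compartment", t] <- full[t, "OC_compartment"] <- full["OC", t]
    full["OC_compartment", "OC_compartment"] <- 0
  }
  unname(full)
}

.stateFromObjects <- function(field, registry, energies, params) {
  validObject(field); validObject(registry); validObject(energies)
  validObject(params)
  df <- registry@cells
  owner <- field@owner
  present <- setdiff(unique(as.vector(owner)), 0L)
  unknown <- setdiff(present, df$cell_id)
  if (length(unknown))
    stop("site owners not present in registry: ",
         paste(sort(unknown), collapse = ", "))
  n <- max(c(df$cell_id, 0L))
  st <- new.env(parent = emptyenv())
  st$owner <- owner + 0L  # force a copy; the kernel mutates in place
  st$W <- nrow(owner); st$H <- ncol(owner)
  st$ncells <- as.integer(n)
  st$mcs <- field@mcs
  st$params <- params
  st$J <- .buildJ(energies)
  idx <- df$cell_id + 1L
  st$typeOf <- integer(n + 1L)
  st$typeOf[idx] <- .typeCode(df$type)
  st$AT <- numeric(n + 1L); st$AT[idx] <- df$target_area
  st$PT <- numeric(n + 1L); st$PT[idx] <- df$target_perimeter
  st$lamA <- numeric(n + 1L); st$lamA[idx] <- df$lambda_area
  st$lamP <- numeric(n + 1L); st$lamP[idx] <- df$lambda_perimeter
  st$A0 <- numeric(n + 1L); st$A0[idx] <- df$initial_target_area
  st$P0 <- numeric(n + 1L); st$P0[idx] <- df$initial_target_perimeter
  st$registered <- logical(n + 1L); st$registered[idx] <- TRUE
  st$alive <- st$registered
  st$alive[1L] <- TRUE  # Medium
  st$exempt <- logical(n + 1L); st$exempt[idx] <- df$death_exempt
  st$expEnabled <- logical(n + 1L); st$expEnabled[idx] <- df$expansion_enabled
  st$dying <- logical(n + 1L); st$dying[idx] <- df$dying
  st$group <- integer(n + 1L); st$group[idx] <- df$group_id
  st$centralOC <- rep(NA, n + 1L)
  if (!is.null(df$central_oc)) st$centralOC[idx] <- df$central_oc
  geo <- cpp_geometry(st$owner, st$ncells, st$typeOf, .isOCCode,
                      params@boundaryOrder)
  st$area <- geo$area
  st$perim <- geo$perimeter
  st$ocContact <- geo$oc_contact
  st$alive <- st$alive & c(TRUE, st$area[-1L] > 0)
  st
}

.registryFromState <- function(st) {
  ids <- which(st$registered & st$alive) - 1L
  ids <- ids[ids > 0L & st$area[ids + 1L] > 0]
  idx <- ids + 1L
  cellRegistry(data.frame(
    cell_id = as.integer(ids),
    type = .CELL_TYPES[st$typeOf[idx] + 1L],
    area = st$area[idx],
    perimeter = st$perim[idx],
    target_area = st$AT[idx],
    target_perimeter = st$PT[idx],
    lambda_area = st$lamA[idx],
    lambda_perimeter = st$lamP[idx],
    initial_target_area = st$A0[idx],
    initial_target_perimeter = st$P0[idx],
    death_exempt = st$exempt[idx],
    expansion_enabled = st$expEnabled[idx],
    dying = st$dying[idx],
    group_id = st$group[idx],
    central_oc = st$centralOC[idx],
    stringsAsFactors = FALSE))
}

.fieldFromState <- function(st) cellField(st$owner + 0L, st$mcs)

## Compare cached registry statistics against a full recomputation.
## Used as the integrity precondition of totalEnergy().
.checkConsistency <- function(field, registry, params) {
  df <- registry@cells
  if (nrow(df) == 0) return(invisible(TRUE))
  n <- max(df$cell_id)
  typeOf <- integer(n + 1L)
  typeOf[df$cell_id + 1L] <- .typeCode(df$type)
  geo <- cpp_geometry(field@owner, n, typeOf, .isOCCode,
                      params@boundaryOrder)
  aRef <- geo$area[df$cell_id + 1L]
  pRef <- geo$perimeter[df$cell_id + 1L]
  badA <- which(abs(df$area - aRef) > 1e-9)
  if (length(badA))
    stop(sprintf("registry integrity error: cell %d has area %g but field says %g",
                 df$cell_id[badA[1]], df$area[badA[1]], aRef[badA[1]]))
  badP <- which(abs(df$perimeter - pRef) > 1e-9)
  if (length(badP))
    stop(sprintf("registry integrity error: cell %d has perimeter %g but field says %g",
                 df$cell_id[badP[1]], df$perimeter[badP[1]], pRef[badP[1]]))
  invisible(TRUE)
}
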