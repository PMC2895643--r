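#' Contact-gated death probability
#'
#' Per-MCS probability that an IPC dies, as a function of its contact length
#' with ommatidial cores: `pMax * (1 - cs/L)^lambdaDeath` for `cs < L` and
#' exactly 0 at and above the survival threshold `L`. The maximum `pMax` is
#' attained at zero contact; the function is continuous and monotone
#' non-increasing on `[0, L]`.
#'
#' @param csOC numeric vector of core-contact lengths (boundary links),
#'   `>= 0`.
#' @param rule a [DeathRule-class].
#' @return numeric vector of probabilities per MCS.
#' @examples
#' deathProbability(c(0, 8, 16, 32), deathRule())
#' @export
deathProbability <- function(csOC, rule = deathRule()) {
  if (any(csOC < 0)) stop("contact lengths must be >= 0")
  L <- rule@thresholdLength
  p <- ifelse(csOC >= L, 0,
              rule@pMax * (1 - csOC / L)^rule@lambdaDeath)
  as.numeric(p)
}

## state-level death hook used inside the run loop
.deathHook <- function(st, rule) {
  if (!rule@enabled || st$mcs < rule@onsetMCS) return(integer(0))
  ipc <- .typeCode("IPC")
  idx <- which(st$registered & st$alive & st$typeOf == ipc &
               !st$exempt & !st$dying)
  if (!length(idx)) return(integer(0))
  p <- deathProbability(pmax(st$ocContact[idx], 0), rule)
  hit <- idx[runif(length(idx)) < p]
  if (length(hit)) {
    st$AT[hit] <- 0
    st$PT[hit] <- 0
    st$dying[hit] <- TRUE
    st$expEnabled[hit] <- FALSE
  }
  as.integer(hit - 1L)
}

#' Evaluate programmed cell death for one MCS
#'
#' Called once per MCS (after the lattice sweep). Does nothing before the
#' onset MCS or when the rule is disabled. Otherwise every living,
#' non-exempt, non-dying IPC draws one Bernoulli variate against
#' [deathProbability()] of its current core contact; cells that die get
#' target area and target perimeter 0, are flagged `dying` and are excluded
#' from future expansion and death draws. Cores and Medium are never
#' evaluated.
#'
#' @param field a [CellField-class].
#' @param registry a [CellRegistry-class].
#' @param rule a [DeathRule-class].
#' @param mcs current MCS (defaults to the field's counter).
#' @param params an [EngineParameters-class].
#' @return list with the updated `registry` and `dying`, the integer ids of
#'   newly dying cells.
#' @export
pcdSweep <- function(field, registry, rule = deathRule(),
                     mcs = mcsCount(field), params = engineParameters()) {
  st <- .stateFromObjects(field, registry, contactEnergyTable(), params)
  st$mcs <- as.integer(mcs)
  dying <- .deathHook(st, rule)
  list(registry = .registryFromState(st), dying = dying)
}

#' Flag margin IPCs as exempt from death
#'
#' IPCs at the edge of the eye do not die in the young pupa; every IPC with
#' at least one boundary link to Medium at initialization is flagged
#' `death_exempt`, permanently for the run.
#'
#' @inheritParams pcdSweep
#' @return the updated [CellRegistry-class].
#' @export
markBorderExempt <- function(field, registry, params = engineParameters()) {
  df <- registry@cells
  if (!nrow(df)) return(registry)
  M <- .contactMatrix(field, registry, params)
  touchesMedium <- M[1L, df$cell_id + 1L] > 0
  df$death_exempt <- df$death_exempt | (df$type == "IPC" & touchesMedium)
  ## fix the central-ommatidium set now, from the initial contacts: a core
  ## is central when none of its contacting IPCs lies on the exempt margin
  ## or touches it (one-cell buffer, since the generated margin ring is one
  ## cell removed from the boundary cores)
  exemptIds <- df$cell_id[df$death_exempt]
  nearExempt <- vapply(df$cell_id, function(id) {
    nbs <- which(M[id + 1L, ] > 0) - 1L
    id %in% exemptIds || any(nbs %in% exemptIds)
  }, logical(1))
  marginIds <- df$cell_id[df$type == "IPC" & nearExempt]
  isOC <- df$type %in% c("OC", "OC_compartment")
  central <- vapply(df$cell_id[isOC], function(id) {
    nbs <- which(M[id + 1L, ] > 0) - 1L
    !any(nbs %in% marginIds)
  }, logical(1))
  ## a split core is central only if both compartments are
  grpCentral <- tapply(central, df$group_id[isOC], all)
  df$central_oc <- NA
  df$central_oc[isOC] <- unname(grpCentral[as.character(df$group_id[isOC])])
  new("CellRegistry", cells = df)
}

## state-level expansion hook: recompute targets from the linear schedule.
## Targets move only at multiples of the entry's interval; at completion the
## target area equals exactly max_multiplier * initial target area.
.expansionHook <- function(st, schedule) {
  if (!schedule@enabled) return(invisible(NULL))
  en <- schedule@entries
  for (i in seq_len(nrow(en))) {
    if (st$mcs %% en$interval_mcs[i] != 0) next
    code <- .typeCode(en$type[i])
    idx <- which(st$registered & st$alive & st$typeOf == code &
                 st$expEnabled & !st$dying)
    if (!length(idx)) next
    frac <- min(st$mcs, en$completion_mcs[i]) / en$completion_mcs[i]
    st$AT[idx] <- st$A0[idx] * (1 + (en$max_multiplier[i] - 1) * frac)
    st$PT[idx] <- st$P0[idx] * (1 + (en$perim_multiplier[i] - 1) * frac)
  }
  invisible(NULL)
}

#' Apply one expansion increment
#'
#' Called once per MCS; targets change only at multiples of the schedule
#' interval. For each expansion-enabled, non-dying cell of a scheduled type,
#' the target area and target perimeter are set on the linear ramp from
#' their initial values to `max_multiplier` times those values at
#' `completion_mcs`, clamped thereafter.
#'
#' @param registry a [CellRegistry-class].
#' @param schedule an [ExpansionSchedule-class].
#' @param mcs current MCS.
#' @return the updated [CellRegistry-class].
#' @export
expansionStep <- function(registry, schedule = expansionSchedule(), mcs) {
  df <- registry@cells
  en <- schedule@entries
  if (!schedule@enabled || !nrow(df)) return(registry)
  for (i in seq_len(nrow(en))) {
    if (mcs %% en$interval_mcs[i] != 0) next
    sel <- df$type == en$type[i] & df$expansion_enabled & !df$dying
    if (!any(sel)) next
    frac <- min(mcs, en$completion_mcs[i]) / en$completion_mcs[i]
    df$target_area[sel] <- df$initial_target_area[sel] *
      (1 + (en$max_multiplier[i] - 1) * frac)
    df$target_perimeter[sel] <- df$initial_target_perimeter[sel] *
      (1 + (en$perim_multiplier[i] - 1) * frac)
  }
  new("CellRegistry", cells = df)
}

#' Derive a run configuration from a variant
#'
#' Starting from a base preset (normally the wild type), returns a new
#' [ExperimentPreset-class] with only the variant's parameters changed:
#' the adhesion mode rewrites the `J` table (`flat` sets
#' `J_OC,IPC = J_IPC,IPC`; `anti_preferential` swaps the two), `deathL`
#' overrides the survival threshold, `deathEnabled` switches death off, and
#' the expansion fields select which cells expand. Cell-level effects
#' (disabling expansion of one core, compartment-splitting half a core,
#' enabling IPC growth) are applied to the field when the experiment is
#' built.
#'
#' @param base an [ExperimentPreset-class].
#' @param variant a [VariantSpec-class].
#' @return a new [ExperimentPreset-class].
#' @export
applyVariant <- function(base, variant) {
  validObject(variant)
  if (!variant@deathEnabled && !is.na(variant@deathL))
    stop("conflicting overrides: deathL set while death is disabled")
  p <- base
  p@variant <- variant
  J <- p@energies@J
  if (variant@adhesionMode == "flat") {
    J["OC", "IPC"] <- J["IPC", "OC"] <- J["IPC", "IPC"]
  } else if (variant@adhesionMode == "anti_preferential") {
    oi <- J["OC", "IPC"]; ii <- J["IPC", "IPC"]
    J["OC", "IPC"] <- J["IPC", "OC"] <- max(oi, ii)
    J["IPC", "IPC"] <- min(oi, ii)
  }
  p@energies <- new("ContactEnergyTable", J = J)
  d <- p@death
  if (!is.na(variant@deathL)) d@thresholdLength <- variant@deathL
  d@enabled <- variant@deathEnabled
  p@death <- d
  if (variant@ipcGrowth) {
    en <- p@expansion@entries
    if (!"IPC" %in% en$type) {
      en <- rbind(en, data.frame(type = "IPC", interval_mcs = 100L,
                                 completion_mcs = p@params@totalMCS,
                                 max_multiplier = 2,
                                 perim_multiplier = sqrt(2)))
      p@expansion <- new("ExpansionSchedule", entries = en,
                         enabled = p@expansion@enabled)
    }
  }
  p
}

## Apply the cell-level part of a variant to a freshly built eye field:
## expansion flags and the compartment split of the central core.
.applyVariantToField <- function(eye, variant, params) {
  df <- eye@registry@cells
  if (variant@ipcGrowth)
    df$expansion_enabled[df$type == "IPC"] <- TRUE
  mode <- variant@ocExpansion
  if (mode == "none") {
    df$expansion_enabled[df$type %in% c("OC", "OC_compartment")] <- FALSE
  } else if (mode %in% c("all_but_one", "half_of_one")) {
    target <- .centralOC(eye)
    if (mode == "all_but_one") {
      df$expansion_enabled[df$cell_id == target] <- FALSE
    } else {
      return(.splitOC(eye, target, params, registryOverride = df))
    }
  }
  new("EyeField", field = eye@field,
      registry = new("CellRegistry", cells = df), centers = eye@centers)
}

## the core whose site centroid is closest to the lattice center
.centralOC <- function(eye) {
  df <- eye@registry@cells
  ocs <- df$cell_id[df$type == "OC"]
  ow <- eye@field@owner
  mid <- dim(ow) / 2
  d <- vapply(ocs, function(id) {
    w <- which(ow == id, arr.ind = TRUE)
    sum((colMeans(w) - mid)^2)
  }, numeric(1))
  ocs[which.min(d)]
}

## Split one core into two equal compartments that adhere as one body
## (mutual J = 0 via the OC_compartment type); the new compartment does not
## expand. Combined area, targets and group identity are preserved.
.splitOC <- function(eye, target, params, registryOverride = NULL) {
  df <- if (is.null(registryOverride)) eye@registry@cells else registryOverride
  ow <- eye@field@owner
  sites <- which(ow == target, arr.ind = TRUE)
  sites <- sites[order(sites[, 1], sites[, 2]), , drop = FALSE]
  nHalf <- ceiling(nrow(sites) / 2)
  newId <- max(df$cell_id) + 1L
  half <- sites[seq_len(nHalf), , drop = FALSE]
  ow[cbind(half[, 1], half[, 2])] <- newId
  row <- df[df$cell_id == target, ]
  fracNew <- nHalf / nrow(sites)
  newRow <- row
  newRow$cell_id <- newId
  newRow$expansion_enabled <- FALSE
  df <- rbind(df, newRow)
  sel <- df$cell_id %in% c(target, newId)
  df$type[sel] <- "OC_compartment"
  df$group_id[sel] <- row$group_id
  fr <- ifelse(df$cell_id[sel] == newId, fracNew, 1 - fracNew)
  df$target_area[sel] <- row$target_area * fr
  df$initial_target_area[sel] <- row$initial_target_area * fr
  ## perimeter targets: each half keeps a near-complete share of the round
  ## outline plus the internal split is free (J = 0), so scale mildly
  df$target_perimeter[sel] <- row$target_perimeter * 0.65
  df$initial_target_perimeter[sel] <- row$initial_target_perimeter * 0.65
  field <- cellField(ow, eye@field@mcs)
  reg <- cellRegistry(df)
  cdf <- reg@cells
  geo <- cpp_geometry(ow, max(cdf$cell_id),
                      `[<-`(integer(max(cdf$cell_id) + 1L),
                            cdf$cell_id + 1L, .typeCode(cdf$type)),
                      .isOCCode, params@boundaryOrder)
  cdf$area <- geo$area[cdf$cell_id + 1L]
  cdf$perimeter <- geo$perimeter[cdf$cell_id + 1L]
  new("EyeField", field = field, registry = new("CellRegistry", cells = cdf),
      centers = eye@centers)
}
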