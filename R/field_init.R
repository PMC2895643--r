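#' Generate a synthetic initial eye field
#'
#' Builds an initial condition emulating a traced pupal eye at the stage
#' when every interommatidial precursor already touches at least two
#' ommatidial cores: a hexagonally offset `rows x cols` grid of disc-shaped
#' cores, the interstitial space partitioned into IPCs seeded along each
#' inter-core corridor (one to two cells deep), a bounding ring of IPCs,
#' and Medium outside. Initial target area and perimeter are set to each
#' cell's current area and perimeter. The construction is deterministic for
#' a given seed.
#'
#' @param spec a [SyntheticFieldSpec-class].
#' @param params an [EngineParameters-class] (used for the boundary
#'   neighborhood when measuring geometry).
#' @return An [EyeField-class]; its `centers` slot holds the core centers.
#' @examples
#' eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2,
#'                                                  seed = 1))
#' nCells(eye@registry)
#' @export
generateSyntheticField <- function(spec = syntheticFieldSpec(),
                                   params = engineParameters()) {
  validObject(spec)
  if (!is.na(spec@seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed)
  }
  s <- spec@spacing; r <- spec@ocRadius; m <- spec@mediumMargin
  rows <- spec@rows; cols <- spec@cols
  h <- s * sqrt(3) / 2
  grid <- expand.grid(i = seq_len(rows) - 1L, j = seq_len(cols) - 1L)
  cx <- m + r + s * grid$j + ifelse(grid$i %% 2 == 1, s / 2, 0)
  cy <- m + r + h * grid$i
  centers <- cbind(x = cx, y = cy)
  W <- as.integer(ceiling(max(cx) + r + m))
  H <- as.integer(ceiling(max(cy) + r + m))
  X <- matrix(seq_len(W) - 1L, W, H)
  Y <- matrix(rep(seq_len(H) - 1L, each = W), W, H)

  nOC <- nrow(centers)
  d2min <- matrix(Inf, W, H)
  nearest <- matrix(0L, W, H)
  for (k in seq_len(nOC)) {
    d2 <- (X - cx[k])^2 + (Y - cy[k])^2
    upd <- d2 < d2min
    d2min[upd] <- d2[upd]
    nearest[upd] <- k
  }
  owner <- matrix(0L, W, H)
  for (k in seq_len(nOC))
    owner[(X - cx[k])^2 + (Y - cy[k])^2 <= r^2] <- k

  coverR <- 0.62 * s      # covers the three-core interstitial vertices
  ringDepth <- 6          # width of the bounding IPC ring
  interior <- d2min <= coverR^2 & owner == 0L
  ring <- d2min > coverR^2 & d2min <= (coverR + ringDepth)^2

  ## IPC seeds: ipcBandCells per inter-core corridor, spread along the
  ## corridor so each resulting cell spans the gap and touches both cores
  pairs <- which(as.matrix(dist(centers)) < 1.35 * s &
                 upper.tri(matrix(0, nOC, nOC)), arr.ind = TRUE)
  nb <- spec@ipcBandCells
  seeds <- NULL
  for (p in seq_len(nrow(pairs))) {
    a <- centers[pairs[p, 1], ]; b <- centers[pairs[p, 2], ]
    mid <- (a + b) / 2
    u <- (b - a) / sqrt(sum((b - a)^2))
    v <- c(-u[2], u[1])
    offs <- if (nb == 1) 0 else seq(-0.22, 0.22, length.out = nb) * s
    for (o in offs)
      seeds <- rbind(seeds, mid + v * o + runif(2, -0.8, 0.8))
  }
  intIdx <- which(interior)
  sx <- X[intIdx]; sy <- Y[intIdx]
  best <- rep.int(1L, length(intIdx)); bestd <- rep(Inf, length(intIdx))
  for (k in seq_len(nrow(seeds))) {
    d2 <- (sx - seeds[k, 1])^2 + (sy - seeds[k, 2])^2
    upd <- d2 < bestd
    bestd[upd] <- d2[upd]
    best[upd] <- k
  }
  ipcStart <- nOC
  owner[intIdx] <- ipcStart + best

  ## bounding ring: contiguous angular sectors around the field centroid
  ringIdx <- which(ring)
  cxm <- mean(cx); cym <- mean(cy)
  ang <- atan2(Y[ringIdx] - cym, X[ringIdx] - cxm)
  nRing <- max(8L, round(length(ringIdx) / 110))
  sector <- 1L + (floor((ang + pi) / (2 * pi) * nRing)) %% nRing
  ringStart <- ipcStart + nrow(seeds)
  owner[ringIdx] <- ringStart + as.integer(sector)

  ## repair pass: an interior IPC whose seed landed badly can touch < 2
  ## cores; merge it into the neighboring IPC it shares the most boundary
  ## with until every interior IPC spans its corridor
  for (pass in 1:10) {
    ids <- sort(setdiff(unique(as.vector(owner)), 0L))
    M <- cpp_contact_matrix(owner, max(ids), params@boundaryOrder)
    ipcIds <- setdiff(ids, seq_len(nOC))
    bad <- integer(0)
    for (id in ipcIds) {
      row <- M[id + 1L, ]
      if (row[1L] > 0) next                       # margin cell
      if (sum(row[seq_len(nOC) + 1L] > 0) < 2) bad <- c(bad, id)
    }
    if (!length(bad)) break
    for (id in bad) {
      row <- M[id + 1L, ]
      row[c(1L, seq_len(nOC) + 1L)] <- 0          # only IPC neighbors
      row[id + 1L] <- 0
      tgt <- which.max(row) - 1L
      if (row[tgt + 1L] > 0) owner[owner == id] <- tgt
    }
  }

  ## drop empty labels, relabel contiguously
  used <- sort(setdiff(unique(as.vector(owner)), 0L))
  remap <- integer(max(used) + 1L)
  remap[used + 1L] <- seq_along(used)
  owner <- matrix(remap[owner + 1L], W, H)
  typeOfUsed <- ifelse(used <= nOC, "OC", "IPC")

  n <- length(used)
  typeOf <- integer(n + 1L)
  typeOf[seq_len(n) + 1L] <- .typeCode(typeOfUsed)
  geo <- cpp_geometry(owner, n, typeOf, .isOCCode, params@boundaryOrder)
  df <- data.frame(cell_id = seq_len(n), type = typeOfUsed,
                   area = geo$area[-1L], perimeter = geo$perimeter[-1L],
                   stringsAsFactors = FALSE)
  registry <- cellRegistry(df)
  field <- cellField(owner)
  eye <- new("EyeField", field = field, registry = registry,
             centers = centers)
  .checkGeneratedField(eye, params)
  eye
}

## generated-field postconditions: no core-core contact, and every interior
## IPC (no Medium contact) touches at least two cores
.checkGeneratedField <- function(eye, params) {
  df <- eye@registry@cells
  M <- .contactMatrix(eye@field, eye@registry, params)
  ocIds <- df$cell_id[df$type == "OC"]
  sub <- M[ocIds + 1L, ocIds + 1L, drop = FALSE]
  diag(sub) <- 0
  if (any(sub > 0))
    stop("generation error: ommatidial cores touch; increase spacing")
  ipcIds <- df$cell_id[df$type == "IPC"]
  for (id in ipcIds) {
    row <- M[id + 1L, ]
    if (row[1L] > 0) next  # margin IPC touching Medium
    nOCtouch <- sum(row[ocIds + 1L] > 0)
    if (nOCtouch < 2)
      stop(sprintf(
        "generation error: interior IPC %d touches %d core(s) (< 2); adjust spacing/ocRadius/ipcBandCells",
        id, nOCtouch))
  }
  invisible(TRUE)
}

#' Import a segmented tracing as an initial condition
#'
#' Reads an integer label image (grayscale PNG or TIFF) in which each label
#' value marks one traced cell, plus a type map assigning every label a cell
#' type. Labels sharing a value but disconnected on the lattice become
#' distinct cells (reported via a message). Areas and perimeters are
#' measured from the lattice; targets are initialized to the current values.
#'
#' @param image path to a grayscale integer PNG/TIFF, or an integer matrix
#'   of labels indexed `[x, y]`.
#' @param typeMap named character vector or data.frame (`label`, `type`)
#'   mapping every label value occurring in the image to one of `Medium`,
#'   `OC`, `IPC`; exactly one label (conventionally 0) must map to Medium.
#' @param params an [EngineParameters-class].
#' @return An [EyeField-class] (centers inferred as core centroids).
#' @export
importTracing <- function(image, typeMap, params = engineParameters()) {
  labels <- if (is.matrix(image)) {
    storage.mode(image) <- "integer"
    image
  } else .readLabelImage(image)
  if (is.data.frame(typeMap))
    typeMap <- setNames(as.character(typeMap$type), typeMap$label)
  vals <- sort(unique(as.vector(labels)))
  unmapped <- setdiff(as.character(vals), names(typeMap))
  if (length(unmapped))
    stop("unmapped labels in image: ", paste(unmapped, collapse = ", "))
  if (!all(typeMap %in% c("Medium", "OC", "IPC")))
    stop("typeMap types must be Medium, OC or IPC")
  mediumLabels <- names(typeMap)[typeMap == "Medium"]
  if (sum(as.character(vals) %in% mediumLabels) != 1)
    stop("exactly one label present in the image must map to Medium")
  mediumVal <- as.integer(vals[as.character(vals) %in% mediumLabels])
  comp <- cpp_label_components(labels, mediumVal)
  owner <- comp$labels
  orig <- comp$original
  nSplit <- sum(duplicated(orig))
  if (nSplit > 0)
    message(nSplit, " disconnected label region(s) became distinct cells")
  types <- unname(typeMap[as.character(orig)])
  n <- length(orig)
  typeOf <- integer(n + 1L)
  typeOf[seq_len(n) + 1L] <- .typeCode(types)
  geo <- cpp_geometry(owner, n, typeOf, .isOCCode, params@boundaryOrder)
  registry <- if (n) {
    cellRegistry(data.frame(cell_id = seq_len(n), type = types,
                            area = geo$area[-1L],
                            perimeter = geo$perimeter[-1L],
                            stringsAsFactors = FALSE))
  } else {
    cellRegistry(data.frame(cell_id = integer(0), type = character(0),
                            area = numeric(0), perimeter = numeric(0)))
  }
  centers <- .ocCentroids(owner, registry)
  new("EyeField", field = cellField(owner), registry = registry,
      centers = centers)
}

.ocCentroids <- function(owner, registry) {
  df <- registry@cells
  ocs <- df$cell_id[df$type %in% c("OC", "OC_compartment")]
  if (!length(ocs)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("x", "y"))))
  out <- t(vapply(ocs, function(id) {
    w <- which(owner == id, arr.ind = TRUE)
    colMeans(w) - 1  # 0-based coordinates
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

.readLabelImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF label images")
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    img <- round(img * (2^depth - 1))
  } else {
    stop("unsupported label image format: .", ext,
         " (PNG or TIFF expected)")
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1)
      stop("format error: label image must be single-channel grayscale")
    img <- img[, , 1]
  }
  if (any(img != round(img)))
    stop("format error: label image must contain integer labels")
  labels <- t(img)  # image rows are y; lattice is indexed [x, y]
  storage.mode(labels) <- "integer"
  labels
}

#' Export a field as a label image plus a cell table
#'
#' Writes the site-ownership lattice as a grayscale integer label image
#' whose pixel values are cell identifiers (Medium exported as 0, by
#' convention) and the registry as a CSV sidecar. Up to 255 cells fit an
#' 8-bit PNG; larger registries need a 16-bit TIFF path (`.tif`/`.tiff`).
#'
#' @param field a [CellField-class] (or an [EyeField-class], in which case
#'   `registry` is taken from it).
#' @param registry a [CellRegistry-class].
#' @param imagePath output PNG (<= 255 cells) or TIFF path.
#' @param tablePath output CSV path (default: `imagePath` with `.csv`).
#' @return invisibly, a list of the two paths.
#' @export
exportField <- function(field, registry = NULL,
                        imagePath,
                        tablePath = sub("\\.(png|tiff?)$", ".csv",
                                        imagePath)) {
  if (is(field, "EyeField")) {
    registry <- field@registry
    field <- field@field
  }
  ow <- field@owner
  ext <- tolower(tools::file_ext(imagePath))
  tryCatch({
    if (ext == "png") {
      if (max(ow) > 255)
        stop("more than 255 cell identifiers; export as 16-bit TIFF instead")
      png::writePNG(t(ow) / 255, imagePath)
    } else if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required for TIFF export")
      if (max(ow) > 65535)
        stop("more than 65535 cell identifiers")
      tiff::writeTIFF(t(ow) / 65535, imagePath, bits.per.sample = 16L)
    } else {
      stop("unsupported export format: .", ext)
    }
    write.csv(registry@cells, tablePath, row.names = FALSE)
  }, error = function(e)
    stop("export failed for ", imagePath, ": ", conditionMessage(e)))
  invisible(list(image = imagePath, table = tablePath))
}
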