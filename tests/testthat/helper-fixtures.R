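## Test fixtures and an independent reference implementation of the
## effective energy, written in plain R loops so that kernel results can be
## checked against code that shares nothing with the C++ path.

## reference boundary/area/perimeter energy; owner is [x, y], 0 = Medium
refEnergy <- function(owner, cells, J, order = 2) {
  W <- nrow(owner); H <- ncol(owner)
  offs <- list(c(1, 0), c(0, 1))
  if (order >= 2) offs <- c(offs, list(c(1, 1), c(1, -1)))
  typeOf <- function(id) {
    if (id == 0) return("Medium")
    cells$type[match(id, cells$cell_id)]
  }
  eb <- 0
  perim <- setNames(numeric(nrow(cells)), cells$cell_id)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    a <- owner[x, y]
    for (o in offs) {
      xn <- (x - 1 + o[1]) %% W + 1
      yn <- (y - 1 + o[2]) %% H + 1
      b <- owner[xn, yn]
      if (a != b) {
        eb <- eb + J[typeOf(a), typeOf(b)]
        if (a != 0) perim[as.character(a)] <- perim[as.character(a)] + 1
        if (b != 0) perim[as.character(b)] <- perim[as.character(b)] + 1
      }
    }
  }
  counts <- table(factor(owner, levels = cells$cell_id))
  area <- as.numeric(counts[as.character(cells$cell_id)])
  ea <- sum(cells$lambda_area * (area - cells$target_area)^2)
  ep <- sum(cells$lambda_perimeter * (perim - cells$target_perimeter)^2)
  list(boundary = eb, area = ea, perimeter = ep, total = eb + ea + ep,
       cellArea = area, cellPerim = unname(perim))
}

## registry whose cached area/perimeter are recounted in R from the field
refRegistry <- function(owner, ids, types, targetArea = NULL,
                        targetPerim = NULL, lamA = 2, lamP = 0.2,
                        order = 2) {
  skeleton <- data.frame(cell_id = ids, type = types,
                         area = 0, perimeter = 0,
                         lambda_area = lamA, lambda_perimeter = lamP)
  geo <- refEnergy(owner, transform(skeleton, target_area = 0,
                                    target_perimeter = 0),
                   matrix(0, 4, 4, dimnames = list(eyeCPM:::.CELL_TYPES,
                                                   eyeCPM:::.CELL_TYPES)),
                   order)
  skeleton$area <- geo$cellArea
  skeleton$perimeter <- geo$cellPerim
  skeleton$target_area <- if (is.null(targetArea)) skeleton$area else targetArea
  skeleton$target_perimeter <-
    if (is.null(targetPerim)) skeleton$perimeter else targetPerim
  cellRegistry(skeleton)
}

## random multi-cell field: patchy labels from seeded nearest-point growth
randomField <- function(W = 16, H = 16, k = 5) {
  sx <- runif(k, 1, W); sy <- runif(k, 1, H)
  owner <- matrix(0L, W, H)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    d <- (x - sx)^2 + (y - sy)^2
    if (min(d) < (0.45 * min(W, H))^2) owner[x, y] <- which.min(d)
  }
  owner
}

## a 6 x 6 field holding one 2 x 2 IPC in Medium (the worked example)
blockField <- function() {
  ow <- matrix(0L, 6, 6)
  ow[3:4, 3:4] <- 1L
  ow
}

## three discs around a central wedge: cell 4 touches all three cores
wedgeField <- function() {
  W <- 40; H <- 40
  ow <- matrix(0L, W, H)
  centers <- list(c(12, 12), c(28, 12), c(20, 28))
  for (i in 1:3) {
    cc <- centers[[i]]
    for (x in seq_len(W)) for (y in seq_len(H))
      if ((x - cc[1])^2 + (y - cc[2])^2 <= 64) ow[x, y] <- i
  }
  ## wedge occupies the triangle between the cores
  for (x in 14:26) for (y in 14:22) if (ow[x, y] == 0) ow[x, y] <- 4L
  ow
}
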