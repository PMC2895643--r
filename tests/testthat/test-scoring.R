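## constructed scoring fixture: three discs and a central wedge cell
.wedgeFixture <- function() {
  ow <- wedgeField()
  ids <- sort(setdiff(unique(as.vector(ow)), 0L))
  types <- c("OC", "OC", "OC", "IPC")[ids]
  reg <- refRegistry(ow, ids, types, lamP = 0)
  list(field = cellField(ow), registry = reg)
}

test_that("tertiary classification requires exactly three core contacts", {
  fx <- .wedgeFixture()
  expect_true(classifyTertiary(fx$field, fx$registry, cellId = 4))

  ## remove one disc: only two core contacts left
  ow2 <- siteOwner(fx$field)
  ow2[ow2 == 3L] <- 0L
  reg2 <- refRegistry(ow2, c(1, 2, 4), c("OC", "OC", "IPC"), lamP = 0)
  expect_false(classifyTertiary(cellField(ow2), reg2, cellId = 4))

  ## a fourth contacting core disqualifies ("exactly three")
  ow4 <- siteOwner(fx$field)
  ow4[17:23, 8:13][ow4[17:23, 8:13] == 0L] <- 5L
  reg4 <- refRegistry(ow4, c(1:5),
                      c("OC", "OC", "OC", "IPC", "OC"), lamP = 0)
  M <- eyeCPM:::.scoringContactMatrix(cellField(ow4), reg4)
  if (M[5, 6] >= 3)  # the added core really touches the wedge
    expect_false(classifyTertiary(cellField(ow4), reg4, cellId = 4))

  expect_error(classifyTertiary(fx$field, fx$registry, cellId = 1),
               "classification error")
})

test_that("secondary classification needs two cores and two tertiaries", {
  ## geometry: two core columns with a central IPC column between them,
  ## split into two flanking tertiary-like cells and one middle cell
  W <- 30; H <- 44
  ow <- matrix(0L, W, H)
  ow[4:12, 4:40] <- 1L    # left core
  ow[18:26, 4:40] <- 2L   # right core
  ow[13:17, 4:12] <- 3L   # upper flank
  ow[13:17, 13:31] <- 4L  # middle cell: touches both cores
  ow[13:17, 32:40] <- 5L  # lower flank
  reg <- refRegistry(ow, 1:5, c("OC", "OC", "IPC", "IPC", "IPC"), lamP = 0)
  f <- cellField(ow)
  ## with both flanks declared tertiary, the middle cell is a secondary
  expect_true(classifySecondary(f, reg, cellId = 4, tertiarySet = c(3, 5)))
  ## with only one flank tertiary it is not
  expect_false(classifySecondary(f, reg, cellId = 4, tertiarySet = 3))

  ## end-to-end pair in one niche: each touches one tertiary and the
  ## other IPC, so neither scores as a correct single secondary
  ow2 <- ow
  ow2[13:17, 13:22] <- 4L
  ow2[13:17, 23:31] <- 6L
  reg2 <- refRegistry(ow2, 1:6,
                      c("OC", "OC", "IPC", "IPC", "IPC", "IPC"), lamP = 0)
  f2 <- cellField(ow2)
  expect_false(classifySecondary(f2, reg2, cellId = 4, tertiarySet = c(3, 5)))
  expect_false(classifySecondary(f2, reg2, cellId = 6, tertiarySet = c(3, 5)))
})

test_that("a cell is never both secondary and tertiary in one snapshot", {
  set.seed(12)
  eye <- generateSyntheticField(syntheticFieldSpec(rows = 3, cols = 3))
  out <- runMCS(eye@field, markBorderExempt(eye@field, eye@registry),
                contactEnergyTable(), n = 20)
  M <- eyeCPM:::.scoringContactMatrix(out$field, out$registry)
  sc <- eyeCPM:::.scoreContacts(M, out$registry)
  expect_length(intersect(sc$secondary, sc$tertiary), 0)
})

test_that("tertiary counts are invariant under relabeling", {
  set.seed(13)
  eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2))
  base <- scoreField(eye@field, eye@registry)

  ## relabel by reversing cell ids
  df <- cellTable(eye)
  old <- df$cell_id
  new <- rev(old)
  map <- integer(max(old) + 1)
  map[old + 1] <- new
  ow <- siteOwner(eye)
  owR <- matrix(ifelse(ow == 0, 0L, map[ow + 1]), nrow(ow), ncol(ow))
  dfR <- df
  dfR$cell_id <- new
  dfR$group_id <- new
  dfR <- dfR[order(dfR$cell_id), ]
  relabeled <- scoreField(cellField(owR), cellRegistry(dfR))
  expect_identical(relabeled$n_tertiary, base$n_tertiary)
  expect_identical(relabeled$n_secondary, base$n_secondary)
})

test_that("time series records appear on the reporting grid", {
  p <- eyePreset("wild_type", fieldSpec = syntheticFieldSpec(rows = 2, cols = 2),
                 totalMCS = 1500L)
  res <- runExperiment(p, seed = 2)
  ts <- timeSeries(res)
  expect_identical(ts$mcs, c(0L, 500L, 1000L, 1500L))
  expect_identical(nrow(ts), 1500L %/% 500L + 1L)

  ## per-type means follow their definition
  df <- cellTable(res@registry)
  expect_equal(ts$mean_area_OC[nrow(ts)], mean(df$area[df$type == "OC"]))
  expect_equal(ts$n_cells[nrow(ts)], nrow(df))
})

test_that("hexagon counting applies the half-cell rule", {
  ## nine 2x2 IPCs inside a hexagon, plus cores ignored by the count
  W <- 40; H <- 40
  ow <- matrix(0L, W, H)
  id <- 0
  for (i in 0:2) for (j in 0:2) {
    id <- id + 1
    ow[14 + 4 * i + (0:1), 14 + 4 * j + (0:1)] <- id
  }
  reg <- refRegistry(ow, 1:9, rep("IPC", 9), lamP = 0)
  hexa <- cbind(x = c(20, 30, 30, 20, 8, 8), y = c(5, 14, 26, 35, 26, 14))
  expect_equal(hexagonIPCCount(cellField(ow), reg, hexa), 9)

  ## two straddling cells count half each
  ow2 <- ow
  ow2[6:10, 18:19] <- 10L   # crosses the left edge
  ow2[28:32, 18:19] <- 11L  # crosses the right edge
  reg2 <- refRegistry(ow2, 1:11, rep("IPC", 11), lamP = 0)
  expect_equal(hexagonIPCCount(cellField(ow2), reg2, hexa), 10)

  ## empty region
  empty <- cbind(x = c(2, 4, 5, 4, 2, 1), y = c(1, 1, 2, 4, 4, 2))
  expect_equal(hexagonIPCCount(cellField(ow), reg, empty), 0)

  expect_error(hexagonIPCCount(cellField(ow), reg, hexa[1:5, ]),
               "geometry error")
  expect_error(hexagonIPCCount(cellField(ow), reg, hexa[c(1, 1:5), ]),
               "geometry error")
})

test_that("MCS convert to developmental hours at 2 s per step", {
  expect_equal(mcsToHours(10000), 5.5556, tolerance = 1e-4)
  expect_identical(mcsToHours(0), 0)
  expect_equal(mcsToHours(1800), 1)
  expect_error(mcsToHours(-5), ">= 0")
})
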