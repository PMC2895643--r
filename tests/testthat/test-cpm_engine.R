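test_that("total energy matches hand-enumerated configurations", {
  ## one cell owning everything: no inter-cell links anywhere
  ow <- matrix(1L, 5, 5)
  reg <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 25,
                                 perimeter = 0, lambda_perimeter = 0))
  e <- totalEnergy(cellField(ow), reg, contactEnergyTable())
  expect_equal(e@boundary, 0)

  ## 2x2 IPC block in Medium, order-1: 8 links x J = 80, shape terms at target
  reg2 <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 4,
                                  perimeter = 8, lambda_area = 2,
                                  lambda_perimeter = 0))
  e2 <- totalEnergy(cellField(blockField()), reg2,
                    contactEnergyTable(ipc_medium = 10),
                    engineParameters(boundaryOrder = 1))
  expect_equal(e2@boundary, 80)
  expect_equal(e2@area, 0)
  expect_equal(e2@perimeter, 0)
  expect_equal(e2@total, 80)
})

test_that("total energy agrees with the independent R reference", {
  set.seed(11)
  for (i in 1:5) {
    ow <- randomField()
    ids <- sort(setdiff(unique(as.vector(ow)), 0L))
    J <- contactEnergyTable(oc_ipc = 7, ipc_ipc = 11, oc_medium = 3,
                            ipc_medium = 5, oc_oc = 13)
    for (ord in 1:2) {
      reg <- refRegistry(ow, ids, rep(c("OC", "IPC"), length.out = length(ids)),
                         targetArea = sample(10:40, length(ids), TRUE),
                         targetPerim = sample(10:40, length(ids), TRUE),
                         order = ord)
      e <- totalEnergy(cellField(ow), reg, J, engineParameters(boundaryOrder = ord))
      ref <- refEnergy(ow, cellTable(reg), J@J, ord)
      expect_equal(e@boundary, ref$boundary)
      expect_equal(e@area, ref$area)
      expect_equal(e@perimeter, ref$perimeter)
      expect_equal(e@total, ref$total)
    }
  }
})

test_that("inconsistent registry raises an integrity error naming the cell", {
  reg <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 99,
                                 perimeter = 8))
  expect_error(
    totalEnergy(cellField(blockField()), reg, contactEnergyTable()),
    "integrity error: cell 1")
})

test_that("deltaH matches the full-recompute oracle on random proposals", {
  set.seed(42)
  J <- contactEnergyTable(oc_ipc = 7, ipc_ipc = 11, oc_medium = 3,
                          ipc_medium = 5, oc_oc = 13)
  params <- engineParameters(boundaryOrder = 2)
  checked <- 0
  while (checked < 100) {
    ow <- randomField()
    ids <- sort(setdiff(unique(as.vector(ow)), 0L))
    if (length(ids) < 2) next
    reg <- refRegistry(ow, ids, rep(c("OC", "IPC"), length.out = length(ids)),
                       targetArea = sample(10:40, length(ids), TRUE),
                       targetPerim = sample(10:40, length(ids), TRUE))
    for (rep in 1:10) {
      x <- sample(16, 1); y <- sample(16, 1)
      o <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
      xs <- (x - 1 + o[1]) %% 16 + 1; ys <- (y - 1 + o[2]) %% 16 + 1
      if (ow[xs, ys] == ow[x, y]) next
      dh <- deltaH(cellField(ow), reg, J, params,
                   source = c(xs, ys), target = c(x, y))
      ow2 <- ow
      ow2[x, y] <- ow[xs, ys]
      before <- refEnergy(ow, cellTable(reg), J@J, 2)
      after <- refEnergy(ow2, cellTable(reg), J@J, 2)
      expect_lt(abs(dh - (after$total - before$total)), 1e-9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 100)
})

test_that("deltaH of a same-owner proposal is zero and a 1-site cell removal is -38", {
  ow <- blockField()
  reg <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 4,
                                 perimeter = 8, lambda_perimeter = 0))
  J <- contactEnergyTable(ipc_medium = 10)
  p1 <- engineParameters(boundaryOrder = 1)
  expect_identical(deltaH(cellField(ow), reg, J, p1,
                          source = c(3, 3), target = c(3, 4)), 0)

  ## Medium copying over the last site of a 1-site IPC: -4 links * 10 plus
  ## the area penalty moving from 0 to lambda * (0 - 1)^2 * 2
  ow2 <- matrix(0L, 6, 6); ow2[3, 3] <- 1L
  reg2 <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 1,
                                  perimeter = 4, lambda_area = 2,
                                  lambda_perimeter = 0))
  expect_equal(deltaH(cellField(ow2), reg2, J, p1,
                      source = c(2, 3), target = c(3, 3)), -38)
})

test_that("Metropolis acceptance is 1 for dH <= 0 and converges to exp(-dH/T)", {
  ## no variate is drawn for dH <= 0: the RNG stream must be untouched
  set.seed(1); before <- .Random.seed
  expect_true(metropolisAccept(-5, 60))
  expect_true(metropolisAccept(0, 60))
  expect_identical(.Random.seed, before)

  set.seed(2)
  n <- 1e5
  hits <- sum(vapply(seq_len(n), function(i) metropolisAccept(60, 60),
                     logical(1)))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("a pure-Medium field is invariant and MCS bookkeeping advances", {
  ow <- matrix(0L, 8, 8)
  reg <- cellRegistry(data.frame(cell_id = integer(0), type = character(0),
                                 area = numeric(0), perimeter = numeric(0)))
  set.seed(3)
  out <- runMCS(cellField(ow), reg, contactEnergyTable(), n = 3)
  expect_identical(siteOwner(out$field), ow)
  expect_identical(mcsCount(out$field), 3L)
})

test_that("areas are conserved and caches stay consistent across MCS", {
  set.seed(7)
  eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2))
  params <- engineParameters()
  st <- eyeCPM:::.stateFromObjects(eye@field, eye@registry,
                                   contactEnergyTable(), params)
  h0 <- sum(eyeCPM:::cpp_total_energy(st$owner, st$ncells, st$typeOf, st$J,
                                      st$AT, st$PT, st$lamA, st$lamP, 2L))
  sumDH <- 0
  for (i in 1:15) {
    blk <- eyeCPM:::.stepState(st)
    sumDH <- sumDH + blk$delta_H
    ## area conservation including Medium
    expect_equal(sum(st$area), prod(dim(eye@field)))
    ## cached area/perimeter/contact equal full recomputation
    geo <- eyeCPM:::cpp_geometry(st$owner, st$ncells, st$typeOf,
                                 eyeCPM:::.isOCCode, 2L)
    expect_equal(st$area, geo$area)
    expect_equal(st$perim, geo$perimeter)
    expect_equal(st$ocContact, geo$oc_contact)
  }
  ## running energy difference equals endpoint difference
  h1 <- sum(eyeCPM:::cpp_total_energy(st$owner, st$ncells, st$typeOf, st$J,
                                      st$AT, st$PT, st$lamA, st$lamP, 2L))
  expect_lt(abs((h0 + sumDH) - h1), 1e-6)
})

test_that("identical seeds give identical trajectories", {
  run <- function() {
    set.seed(99)
    eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2))
    out <- runMCS(eye@field, eye@registry, contactEnergyTable(), n = 5)
    siteOwner(out$field)
  }
  expect_identical(run(), run())
})

test_that("contact lengths are symmetric and match direct enumeration", {
  ## two 1-site cells side by side: one mutual order-1 link
  ow <- matrix(0L, 6, 6)
  ow[3, 3] <- 1L; ow[4, 3] <- 2L
  reg <- cellRegistry(data.frame(cell_id = 1:2, type = "IPC",
                                 area = c(1, 1), perimeter = c(4, 4),
                                 lambda_perimeter = 0))
  p1 <- engineParameters(boundaryOrder = 1)
  c1 <- contactLengths(cellField(ow), reg, p1, 1)
  c2 <- contactLengths(cellField(ow), reg, p1, 2)
  expect_equal(unname(c1$cells["2"]), 1)
  expect_equal(unname(c2$cells["1"]), 1)

  ## 2x2 IPC sharing one full edge with a large OC: 2 order-1 links
  ow2 <- matrix(0L, 8, 8)
  ow2[2:5, 2:5] <- 2L      # large OC
  ow2[6:7, 3:4] <- 1L      # 2x2 IPC against its right edge
  reg2 <- cellRegistry(data.frame(cell_id = 1:2, type = c("IPC", "OC"),
                                  area = c(4, 16), perimeter = c(8, 16),
                                  lambda_perimeter = 0))
  cc <- contactLengths(cellField(ow2), reg2, p1, 1)
  expect_equal(unname(cc$types["OC_total"]), 2)

  ## isolated cell in Medium: zero OC contact
  cc0 <- contactLengths(cellField(blockField()),
                        cellRegistry(data.frame(cell_id = 1, type = "IPC",
                                                area = 4, perimeter = 8,
                                                lambda_perimeter = 0)),
                        p1, 1)
  expect_equal(unname(cc0$types["OC_total"]), 0)
  expect_error(contactLengths(cellField(ow2), reg2, p1, 99), "unknown cell")
})

test_that("contact energy tables enforce symmetry", {
  J <- matrix(c(0, 1, 2, 1, 0, 3, 9, 3, 0), 3, 3,
              dimnames = list(c("Medium", "OC", "IPC"),
                              c("Medium", "OC", "IPC")))
  expect_error(new("ContactEnergyTable", J = J), "symmetric")
  expect_silent(validObject(contactEnergyTable()))
  J2 <- contactEnergyTable()
  expect_identical(J2@J, t(J2@J))
})
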