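test_that("death probability honors its boundary and default form", {
  rule <- deathRule()
  expect_identical(deathProbability(0, rule), 0.01)
  expect_identical(deathProbability(20, rule), 0)
  for (L in c(10, 12, 16)) {
    r <- deathRule(thresholdLength = L)
    expect_identical(deathProbability(L, r), 0)
    expect_identical(deathProbability(c(L + 1, 2 * L, 10 * L), r),
                     c(0, 0, 0))
    expect_identical(deathProbability(0, r), r@pMax)
  }
  ## declared closed form at half threshold
  expect_equal(deathProbability(8, deathRule(thresholdLength = 16)),
               0.01 * 0.5^1.2, tolerance = 1e-12)
  ## monotone non-increasing, continuous at L
  cs <- seq(0, 20, by = 0.25)
  p <- deathProbability(cs, rule)
  expect_true(all(diff(p) <= 0))
  expect_lt(deathProbability(15.999, rule), 1e-5)
  expect_error(deathProbability(-1, rule), ">= 0")
})

test_that("the death sweep respects onset, threshold and exemptions", {
  ## fully tiled field of 1-site IPCs, no Medium and no core contact
  W <- 40; H <- 25
  ow <- matrix(seq_len(W * H), W, H)
  reg <- cellRegistry(data.frame(cell_id = seq_len(W * H), type = "IPC",
                                 area = 1, perimeter = 8,
                                 lambda_perimeter = 0))
  f <- cellField(ow)

  ## before onset nothing happens
  set.seed(5)
  out <- pcdSweep(f, reg, deathRule(), mcs = 9999)
  expect_length(out$dying, 0)
  expect_false(any(cellTable(out$registry)$dying))

  ## at cs = 0 each cell draws Bernoulli(P_MAX): mean over repeated sweeps
  ## within 3 standard errors of 10 per 1,000 cells
  set.seed(6)
  nSweep <- 30
  flagged <- vapply(seq_len(nSweep), function(i)
    length(pcdSweep(f, reg, deathRule(), mcs = 10000)$dying), numeric(1))
  se <- sqrt(1000 * 0.01 * 0.99 / nSweep)
  expect_lt(abs(mean(flagged) - 10), 3 * se)

  ## newly dying cells have zeroed targets and keep their flags
  set.seed(7)
  out2 <- pcdSweep(f, reg, deathRule(), mcs = 10000)
  df <- cellTable(out2$registry)
  dy <- df[df$dying, ]
  expect_gt(nrow(dy), 0)
  expect_true(all(dy$target_area == 0 & dy$target_perimeter == 0))
  expect_true(all(!dy$expansion_enabled))

  ## an IPC at or above threshold never dies: 20 shared lattice edges > L
  ow3 <- matrix(0L, 24, 24)
  ow3[2:11, 2:21] <- 1L   # OC
  ow3[12:14, 2:21] <- 2L  # IPC along its whole right edge
  reg3 <- cellRegistry(data.frame(cell_id = 1:2, type = c("OC", "IPC"),
                                  area = c(200, 60), perimeter = c(0, 0),
                                  lambda_perimeter = 0))
  geo3 <- eyeCPM:::cpp_geometry(ow3, 2L, c(0L, 1L, 2L),
                                eyeCPM:::.isOCCode, 2L)
  reg3@cells$area <- geo3$area[2:3]
  reg3@cells$perimeter <- geo3$perimeter[2:3]
  expect_gte(geo3$oc_contact[3], 16)
  set.seed(8)
  for (i in 1:50) {
    out3 <- pcdSweep(cellField(ow3), reg3, deathRule(), mcs = 20000)
    expect_length(out3$dying, 0)
  }

  ## exempt cells are skipped even at zero contact
  regE <- reg
  regE@cells$death_exempt <- TRUE
  set.seed(9)
  outE <- pcdSweep(f, regE, deathRule(), mcs = 10000)
  expect_length(outE$dying, 0)
})

test_that("border exemption marks exactly the Medium-touching IPCs", {
  ## block IPC in Medium: exempt
  reg <- cellRegistry(data.frame(cell_id = 1, type = "IPC", area = 4,
                                 perimeter = 8, lambda_perimeter = 0))
  out <- markBorderExempt(cellField(blockField()), reg)
  expect_true(cellTable(out)$death_exempt)

  ## fully tiled field: no Medium, zero exemptions
  ow <- matrix(rep(1:2, each = 18), 6, 6)
  reg2 <- cellRegistry(data.frame(cell_id = 1:2, type = "IPC",
                                  area = c(18, 18), perimeter = NA,
                                  lambda_perimeter = 0))
  geo <- eyeCPM:::cpp_geometry(ow, 2L, c(0L, 2L, 2L), eyeCPM:::.isOCCode, 2L)
  reg2@cells$perimeter <- geo$perimeter[2:3]
  out2 <- markBorderExempt(cellField(ow), reg2)
  expect_false(any(cellTable(out2)$death_exempt))

  ## interior IPC surrounded by cells only: not exempt
  set.seed(21)
  eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2))
  reg3 <- markBorderExempt(eye@field, eye@registry)
  df <- cellTable(reg3)
  M <- eyeCPM:::.contactMatrix(eye@field, reg3, engineParameters())
  touchesMedium <- M[1, df$cell_id + 1] > 0
  expect_identical(df$death_exempt, df$type == "IPC" & touchesMedium)
})

test_that("expansion ramps targets linearly to exact doubling", {
  reg <- cellRegistry(data.frame(cell_id = 1:3,
                                 type = c("OC", "OC", "IPC"),
                                 area = c(200, 300, 80),
                                 perimeter = c(120, 150, 40)))
  sch <- expansionSchedule()   # doubles area by completion
  comp <- sch@entries$completion_mcs[1]

  r0 <- expansionStep(reg, sch, mcs = 0)
  expect_identical(cellTable(r0)$target_area, c(200, 300, 80))

  rHalf <- expansionStep(reg, sch, mcs = comp / 2)
  expect_equal(cellTable(rHalf)$target_area[1:2], 1.5 * c(200, 300))

  rEnd <- expansionStep(reg, sch, mcs = comp)
  expect_identical(cellTable(rEnd)$target_area[1:2], 2 * c(200, 300))
  rLate <- expansionStep(reg, sch, mcs = comp * 2)
  expect_identical(cellTable(rLate)$target_area[1:2], 2 * c(200, 300))

  ## IPCs are not scheduled by default; dying cells are skipped
  expect_identical(cellTable(rEnd)$target_area[3], 80)
  regD <- reg
  regD@cells$dying[1] <- TRUE
  regD@cells$target_area[1] <- 0
  rD <- expansionStep(regD, sch, mcs = comp)
  expect_identical(cellTable(rD)$target_area[1], 0)

  ## off the increment grid the targets are unchanged
  rOff <- expansionStep(reg, sch, mcs = 51)
  expect_identical(cellTable(rOff)$target_area, c(200, 300, 80))
})

test_that("variants change exactly the parameters they name", {
  base <- eyePreset("wild_type")
  expect_equal(contactEnergy(base@energies, "OC", "IPC"), 35)
  expect_equal(contactEnergy(base@energies, "IPC", "IPC"), 55)
  expect_equal(base@death@thresholdLength, 16)
  expect_identical(base@death@onsetMCS, 10000L)
  expect_identical(base@params@totalMCS, 50000L)
  expect_equal(base@params@temperature, 60)

  ## wild-type variant leaves the configuration untouched
  again <- applyVariant(base, variantSpec())
  expect_identical(again@energies@J, base@energies@J)
  expect_identical(again@death@thresholdLength, base@death@thresholdLength)

  flat <- eyePreset("adhesion_flat")
  expect_equal(contactEnergy(flat@energies, "OC", "IPC"),
               contactEnergy(flat@energies, "IPC", "IPC"))
  anti <- eyePreset("adhesion_anti")
  expect_lt(contactEnergy(anti@energies, "IPC", "IPC"),
            contactEnergy(anti@energies, "OC", "IPC"))
  expect_equal(eyePreset("reduced_death_L12")@death@thresholdLength, 12)
  expect_equal(eyePreset("reduced_death_L10")@death@thresholdLength, 10)
  expect_false(eyePreset("no_death")@death@enabled)

  expect_error(applyVariant(base, variantSpec(deathEnabled = FALSE,
                                              deathL = 12)),
               "conflicting")
})

test_that("the half-core split preserves area and disables one compartment", {
  set.seed(31)
  eye <- generateSyntheticField(syntheticFieldSpec(rows = 2, cols = 2))
  target <- eyeCPM:::.centralOC(eye)
  areaBefore <- cellTable(eye)$area[cellTable(eye)$cell_id == target]
  split <- eyeCPM:::.splitOC(eye, target, engineParameters())
  df <- cellTable(split)
  halves <- df[df$type == "OC_compartment", ]
  expect_identical(nrow(halves), 2L)
  expect_equal(sum(halves$area), areaBefore)
  expect_identical(length(unique(halves$group_id)), 1L)
  expect_identical(sum(halves$expansion_enabled), 1L)
  ## compartments adhere as one body: mutual boundary energy is zero
  Jfull <- eyeCPM:::.buildJ(contactEnergyTable())
  expect_identical(Jfull[4, 4], 0)
})
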