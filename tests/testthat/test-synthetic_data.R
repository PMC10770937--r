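test_that("the generator is seed-deterministic down to the written CSV", {
  cfg <- small_config(seed = 77, n_patients = 3)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort$cells, s2$cohort$cells)
  expect_identical(s1$cohort$clinical, s2$cohort$clinical)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  c1 <- withr::local_tempfile(fileext = ".csv")
  c2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(s1$cohort, p1, c1)
  write_cohort(s2$cohort, p2, c2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(c1), readLines(c2))
  s3 <- generate_cohort(small_config(seed = 78, n_patients = 3))
  expect_false(identical(s1$cohort$cells$x, s3$cohort$cells$x))
})

test_that("realized marker frequencies sit near their configured values", {
  cfg <- synthetic_config(n_patients = 12, cells_per_region_mean = 800,
                          cells_per_region_size = 50,
                          latent_strength = 0, seed = 13)
  sim <- generate_cohort(cfg)
  cells <- sim$cohort$cells
  n <- nrow(cells)
  # cancer fraction within 3 binomial SEs
  p_hat <- mean(cells$CK)
  se <- sqrt(cfg$cancer_frac * (1 - cfg$cancer_frac) / n)
  expect_lt(abs(p_hat - cfg$cancer_frac), 3 * se)
  # CD8 fraction of non-cancer cells
  nc <- !cells$CK
  p8 <- mean(cells$CD8[nc])
  se8 <- sqrt(cfg$p_cd8 * (1 - cfg$p_cd8) / sum(nc))
  expect_lt(abs(p8 - cfg$p_cd8), 3 * se8)
  # region-specific TRM fraction of CD8 cells
  for (reg in c("TC", "IM")) {
    sel <- cells$CD8 & nc & cells$region == reg
    p_trm <- mean(cells$CD103[sel])
    p0 <- cfg$p_cd103_cd8[[reg]]
    expect_lt(abs(p_trm - p0), 3 * sqrt(p0 * (1 - p0) / sum(sel)))
  }
  # generator output passes the package's own validation round-trip
  pc <- withr::local_tempfile(fileext = ".csv")
  cl <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, pc, cl)
  expect_silent(cohort2 <- assemble_cohort(read_cell_table(pc, "panel1"),
                                           read_clinical_table(cl)))
  expect_equal(nrow(cohort2$clinical), 12L)
})

test_that("subset-specific attraction orders mNND and vanishes at zero", {
  cfg0 <- synthetic_config(
    n_patients = 30, cells_per_region_mean = 400,
    cells_per_region_size = 50, seed = 21,
    attraction_prob = c(TRM1 = 0, TRM2 = 0, TRM3 = 0, TRM4 = 0,
                        TnonRM = 0, other = 0),
    epi_affinity = c(TRM1 = 0.3, TRM2 = 0.3, TRM3 = 0.3, TRM4 = 0.3,
                     TnonRM = 0.3, other = 0.25))
  f0 <- generate_cohort(cfg0)$features
  # no attraction, equal affinity: TRM1 and TRM4 mNNDs are exchangeable
  ks <- suppressWarnings(
    stats::ks.test(f0[["mNND.TRM1.TC"]], f0[["mNND.TRM4.TC"]]))
  expect_gt(ks$p.value, 0.01)

  cfg1 <- synthetic_config(n_patients = 30, cells_per_region_mean = 400,
                           cells_per_region_size = 50, seed = 21)
  f1 <- generate_cohort(cfg1)$features
  expect_lt(mean(f1[["mNND.TRM4.TC"]], na.rm = TRUE),
            mean(f1[["mNND.TRM1.TC"]], na.rm = TRUE))
  expect_lt(mean(f1[["mNND.TRM4.IM"]], na.rm = TRUE),
            mean(f1[["mNND.TRM1.IM"]], na.rm = TRUE))
})

test_that("the planted survival model controls the event fraction", {
  fracs <- vapply(1:5, function(i) {
    cfg <- small_config(seed = 100 + i, n_patients = 60,
                        cells_per_region_mean = 150)
    mean(generate_cohort(cfg)$cohort$clinical$dfs_event)
  }, numeric(1L))
  expect_lt(abs(mean(fracs) - 0.394), 0.05)
  # truth table is consistent with the emitted outcome
  sim <- generate_cohort(small_config(seed = 1, n_patients = 10,
                                      cells_per_region_mean = 150))
  with_truth <- merge(sim$cohort$clinical, sim$truth, by = "patient_id")
  expect_equal(with_truth$dfs_event,
               as.integer(with_truth$t_true <= with_truth$c_time))
  expect_equal(with_truth$dfs_months,
               round(pmin(with_truth$t_true, with_truth$c_time), 2))
})

test_that("panel 2 couples microvessels to TRM abundance but not hypoxia", {
  cfg <- synthetic_config(n_patients = 120, cells_per_region_mean = 600,
                          cells_per_region_size = 50, seed = 31,
                          cmv_coupling = -0.5)
  cohort <- generate_panel2(cfg)
  expect_identical(cohort$panel, "panel2")
  tab <- microvessel_correlates(cohort)
  trm_cd31 <- tab[tab$marker == "CD31" & tab$feature == "Dens.TRM", ]
  expect_true(all(trm_cd31$rho < -0.15))
  hif <- tab[tab$marker == "HIF1A" & tab$feature == "Dens.TRM", ]
  expect_true(all(abs(hif$rho) < 0.25))

  # zero coupling removes the association
  cfg0 <- synthetic_config(n_patients = 120, cells_per_region_mean = 600,
                           cells_per_region_size = 50, seed = 31,
                           cmv_coupling = 0)
  tab0 <- microvessel_correlates(generate_panel2(cfg0))
  trm0 <- tab0[tab0$marker == "CD31" & tab0$feature == "Dens.TRM", ]
  expect_true(all(abs(trm0$rho) < 0.25))
})

test_that("config serialization round-trips through YAML", {
  cfg <- synthetic_config(n_patients = 7, seed = 3,
                          cmv_coupling = -0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_patients, 7)
  expect_equal(cfg2$cmv_coupling, -0.25)
  expect_equal(cfg2$subset_probs, cfg$subset_probs)
  expect_equal(cfg2$planted_effects, cfg$planted_effects)
  # identical configs generate identical cohorts
  expect_identical(generate_cohort(cfg2)$cohort$cells,
                   generate_cohort(cfg)$cohort$cells)
})

test_that("infeasible geometry is rejected", {
  expect_error(synthetic_config(window = 100, nest_radius_mean = 90),
               "nest")
  expect_error(synthetic_config(cmv_coupling = -1.5), "cmv_coupling")
  expect_error(synthetic_config(cancer_frac = 1.2))
})
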