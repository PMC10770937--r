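test_that("the four feature formulas reproduce hand-computed fixtures", {
  expect_equal(cell_density(5, 1000), 5)
  expect_equal(cell_density(0, 400), 0)
  expect_equal(cell_density(200, 200), 1000)  # upper bound
  expect_true(is.na(cell_density(0, 0)))

  expect_equal(infiltration_score(10, 5), 2)
  expect_equal(infiltration_score(0, 7), 0)
  expect_true(is.na(infiltration_score(3, 0)))
  expect_true(is_infinite_ins(3, 0))
  expect_false(is_infinite_ins(0, 0))

  # 3-4-5 triangle: nearest cancer cell of (0,0) is (3,4)
  expect_equal(mean_nnd(0, 0, c(3, 10), c(4, 0)), 5)
  expect_equal(mean_nnd(1, 1, 1, 1), 0)  # coincident cells contribute 0
  expect_true(is.na(mean_nnd(numeric(0), numeric(0), 1, 1)))

  # two cancer cells with 3 and 1 A cells within r
  expect_equal(
    cancer_proximity_score(c(1, 2, 3, 101), c(0, 0, 0, 0),
                           c(0, 100), c(0, 0), r = 5), 2)
  expect_equal(cancer_proximity_score(numeric(0), numeric(0), 0, 0, r = 5), 0)
  expect_true(is.na(cancer_proximity_score(1, 1, numeric(0), numeric(0),
                                           r = 5)))
})

test_that("mNND and CCPS match the O(n^2) brute force on random patterns", {
  set.seed(101)
  for (i in 1:25) {
    nA <- sample(1:60, 1L)
    nC <- sample(1:60, 1L)
    ax <- runif(nA, 0, 300); ay <- runif(nA, 0, 300)
    cx <- runif(nC, 0, 300); cy <- runif(nC, 0, 300)
    r <- runif(1L, 5, 50)
    expect_equal(mean_nnd(ax, ay, cx, cy), brute_mnnd(ax, ay, cx, cy),
                 tolerance = 1e-12)
    expect_equal(cancer_proximity_score(ax, ay, cx, cy, r),
                 brute_ccps(ax, ay, cx, cy, r), tolerance = 1e-12)
  }
})

test_that("mNND and CCPS are invariant under rigid motions", {
  set.seed(7)
  ax <- runif(40, 0, 200); ay <- runif(40, 0, 200)
  cx <- runif(30, 0, 200); cy <- runif(30, 0, 200)
  theta <- 0.83; dx <- 42; dy <- -17
  rot <- function(x, y) list(x = cos(theta) * x - sin(theta) * y + dx,
                             y = sin(theta) * x + cos(theta) * y + dy)
  a2 <- rot(ax, ay); c2 <- rot(cx, cy)
  expect_equal(mean_nnd(a2$x, a2$y, c2$x, c2$y),
               mean_nnd(ax, ay, cx, cy), tolerance = 1e-9)
  expect_equal(cancer_proximity_score(a2$x, a2$y, c2$x, c2$y, r = 25),
               cancer_proximity_score(ax, ay, cx, cy, r = 25),
               tolerance = 1e-9)
})

test_that("CCPS is monotone in r and in added cells; density is additive", {
  set.seed(8)
  ax <- runif(50, 0, 100); ay <- runif(50, 0, 100)
  cx <- runif(20, 0, 100); cy <- runif(20, 0, 100)
  radii <- c(5, 10, 20, 40, 80)
  vals <- vapply(radii, function(r) {
    cancer_proximity_score(ax, ay, cx, cy, r)
  }, numeric(1L))
  expect_true(all(diff(vals) >= 0))
  # adding an A cell never decreases CCPS
  expect_gte(cancer_proximity_score(c(ax, 50), c(ay, 50), cx, cy, 20),
             cancer_proximity_score(ax, ay, cx, cy, 20))
  # nor does it increase the total nearest-neighbour distance mass
  base_sum <- brute_mnnd(ax, ay, cx, cy) * length(ax)
  more_sum <- brute_mnnd(c(ax, 50), c(ay, 50), cx, cy) * (length(ax) + 1)
  expect_gte(more_sum, base_sum)

  # densities of the disjoint TRM1-4 sum to the TRM density, and a
  # region's phenotype-exhaustive densities sum to 1000
  cfg <- small_config(seed = 3, n_patients = 2)
  sim <- generate_cohort(cfg)
  f <- sim$features
  expect_equal(rowSums(f[, paste0("Dens.TRM", 1:4, ".TC")]),
               f[["Dens.TRM.TC"]], tolerance = 1e-12)
  cells1 <- sim$cohort$cells[sim$cohort$cells$patient_id == "P0001" &
                               sim$cohort$cells$region == "TC", ]
  m <- phenotype_matrix(cells1, "panel1")
  n_tot <- nrow(cells1)
  covering <- cell_density(sum(m[, "Cancer"]), n_tot) +
    cell_density(sum(m[, "CD8"]), n_tot) +
    cell_density(sum(!m[, "Cancer"] & !m[, "CD8"]), n_tot)
  expect_equal(covering, 1000, tolerance = 1e-12)
})

test_that("feature vectors carry all keys and propagate missingness", {
  cfg <- small_config(seed = 11, n_patients = 2)
  sim <- generate_cohort(cfg)
  f <- sim$features
  expect_identical(setdiff(names(f), "patient_id"), feature_names())

  # independently recompute one patient-region with naive loops
  cells <- sim$cohort$cells
  p1 <- cells[cells$patient_id == "P0002" & cells$region == "IM", ]
  m <- phenotype_matrix(p1, "panel1")
  in_trm <- m[, "TRM"]; in_cancer <- m[, "Cancer"]
  expect_equal(f[["Dens.TRM.IM"]][2L], sum(in_trm) / nrow(p1) * 1000)
  expect_equal(f[["mNND.TRM.IM"]][2L],
               brute_mnnd(p1$x[in_trm], p1$y[in_trm],
                          p1$x[in_cancer], p1$y[in_cancer]),
               tolerance = 1e-9)
  expect_equal(f[["CCPS.TRM.IM"]][2L],
               brute_ccps(p1$x[in_trm], p1$y[in_trm],
                          p1$x[in_cancer], p1$y[in_cancer], r = 20),
               tolerance = 1e-9)
  epi <- p1$compartment == "epithelium"
  expect_equal(f[["InS.TRM.IM"]][2L],
               sum(in_trm & epi) / sum(in_trm & !epi))

  # a patient lacking the IM region gets NA for every IM feature
  cohort <- sim$cohort
  cohort$cells <- cohort$cells[!(cohort$cells$patient_id == "P0001" &
                                   cohort$cells$region == "IM"), ]
  f2 <- compute_feature_vectors(cohort)
  im_cols <- grep("\\.IM$", names(f2), value = TRUE)
  expect_true(all(is.na(f2[1L, im_cols])))
  expect_false(anyNA(f2[1L, grep("Dens.*\\.TC$", names(f2))]))
})

test_that("microvessel correlations recover monotone and degenerate cases", {
  # perfect rank anti-correlation when CD31 density decreases in TRM density
  n <- 12
  ids <- sprintf("P%02d", 1:n)
  cells <- do.call(rbind, lapply(1:n, function(i) {
    n_trm <- 2 * i
    n_cd31 <- 2 * (n - i) + 1
    n_bulk <- 30
    df <- data.frame(
      patient_id = ids[i], region = "TC",
      compartment = "stroma",
      x = seq_len(n_trm + n_cd31 + n_bulk) * 3,
      y = 5,
      CD8 = rep(c(TRUE, FALSE, FALSE), c(n_trm, n_cd31, n_bulk)),
      CD103 = rep(c(TRUE, FALSE, FALSE), c(n_trm, n_cd31, n_bulk)),
      CK = FALSE,
      CD31 = rep(c(FALSE, TRUE, FALSE), c(n_trm, n_cd31, n_bulk)),
      HIF1A = FALSE, stringsAsFactors = FALSE)
    df
  }))
  cells$region <- factor(cells$region, levels = c("TC", "IM"))
  cells$compartment <- factor(cells$compartment,
                              levels = c("epithelium", "stroma"))
  attr(cells, "panel") <- "panel2"
  cohort <- structure(list(cells = cells,
                           clinical = make_clinical(ids),
                           panel = "panel2"), class = "trm_cohort")
  tab <- microvessel_correlates(cohort)
  row <- tab[tab$marker == "CD31" & tab$feature == "Dens.TRM" &
               tab$region == "TC", ]
  expect_equal(row$rho, -1)
  # HIF1A density is constant: undefined ranks give missing rho
  hif <- tab[tab$marker == "HIF1A" & tab$feature == "Dens.TRM" &
               tab$region == "TC", ]
  expect_true(is.na(hif$rho))
  # absent IM region: too few pairs
  im <- tab[tab$marker == "CD31" & tab$feature == "Dens.TRM" &
              tab$region == "IM", ]
  expect_true(is.na(im$rho))
})
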