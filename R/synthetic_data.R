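# Synthetic mIF cohort generator.
#
# Emulates the structure the analysis assumes: per-patient TC and IM
# point patterns with disk-shaped epithelial nests, cancer cells
# confined to the epithelium, immune cells placed by a mixture of
# compartment-uniform and cancer-attracted kernels with
# subset-specific attraction, a patient-level latent factor inducing
# positive CD103-PD-1/Tim-3/GZMB correlation, and disease-free
# survival drawn from a proportional-hazards model on the spatial
# features computed from the realized pattern (so recovery targets are
# exactly what the pipeline measures).

.logit  <- function(p) log(p / (1 - p))
.expit  <- function(x) 1 / (1 + exp(-x))

#' Configuration of the synthetic cohort generator
#'
#' All generator knobs with defaults emulating an operable-NSCLC mIF
#' cohort: 274 patients, two 600 um square regions (TC/IM) per
#' patient with about 1500 cells each, about 35% cancer cells inside
#' epithelial nests, region-specific TRM fractions of CD8+ cells
#' (higher in TC), checkpoint-defined subset mixes, graded epithelium
#' affinity and cancer attraction from TRM1 to TRM4, and an event
#' fraction near 39%.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; the generator is fully deterministic
#'   given the config.
#' @param window Side of the square region window, um.
#' @param n_nests,nest_radius_mean,nest_radius_sd Number and radius
#'   (um) of the disk-shaped epithelial nests per region; the
#'   epithelium compartment is the union of the disks.
#' @param cells_per_region_mean,cells_per_region_size Negative-binomial
#'   mean and size of the per-region cell count.
#' @param cancer_frac Fraction of cells that are cancer (CK+) cells.
#' @param p_cd8 P(CD8+) among non-cancer cells.
#' @param p_cd103_cd8 Named vector `c(TC=, IM=)`: P(CD103+ | CD8+),
#'   i.e. the TRM fraction of cytotoxic T cells per region.
#' @param p_cd103_noncd8 P(CD103+) among non-cancer, non-CD8 cells.
#' @param subset_probs List with `TC` and `IM` probability vectors
#'   over `TRM1`-`TRM4` (PD-1/Tim-3 co-expression mix of TRM).
#' @param p_pd1_tnonrm,p_tim3_tnonrm Checkpoint rates on TnonRM cells.
#' @param p_gzmb Named GZMB+ rates per subset (`TRM1`-`TRM4`,
#'   `TnonRM`); highest for TRM2, lowest TRM subset is TRM4.
#' @param latent_strength Scale of the patient-level latent factor
#'   that tilts (on the logit scale) the CD103, PD-1, Tim-3 and GZMB
#'   rates jointly, inducing their positive patient-level correlation.
#' @param epi_affinity Named probabilities that an immune cell of each
#'   class is placed in the epithelium (TRM3/TRM4 higher than
#'   TRM1/TRM2, mirroring their better infiltration).
#' @param attraction_prob Named probabilities that a cell of each
#'   class is placed near a random cancer cell rather than uniformly;
#'   graded upward from TRM1 to TRM4 so that mNND decreases and CCPS
#'   increases along the subsets.
#' @param attraction_sd Gaussian displacement (um) of attracted cells
#'   around their anchor cancer cell.
#' @param radius CCPS radius (um) used when computing the features on
#'   which survival is planted.
#' @param planted_effects `data.frame` with columns `feature` (a
#'   [feature_names()] entry), `form` (`"linear"` = per-SD effect on
#'   the standardized feature, `"indicator"` = effect of exceeding the
#'   cohort median) and `ln_hr`. Defaults plant a protective CD103
#'   density effect in TC and a harmful TRM4 infiltration effect in
#'   IM.
#' @param stage_probs,stage_ln_hr Tumor-stage distribution and planted
#'   stage log hazard ratios (reference stage I).
#' @param baseline_hazard Reference exponential baseline hazard per
#'   month; rescaled at generation time so the realized event fraction
#'   under the follow-up window hits `target_event_frac`.
#' @param follow_up Censoring window `c(min, max)` in months:
#'   censoring times are uniform over it (median 60 months by
#'   default, emulating a mature surgical cohort followed for about
#'   five years).
#' @param target_event_frac Event fraction the baseline hazard is
#'   calibrated to.
#' @param cmv_coupling Panel 2 only: Gaussian-copula correlation
#'   between the patient-level TRM-abundance factor and the CD31+
#'   (microvessel) rate; negative values reproduce the angiogenesis
#'   finding. Hif-1alpha rates are drawn independently of TRM.
#' @param p_cd31,p_hif1a Panel 2 baseline marker rates among eligible
#'   cells.
#' @return A validated list of class `trm_sim_config`.
#' @export
synthetic_config <- function(
    n_patients = 274,
    seed = 1,
    window = 600,
    n_nests = 6,
    nest_radius_mean = 90,
    nest_radius_sd = 15,
    cells_per_region_mean = 1500,
    cells_per_region_size = 20,
    cancer_frac = 0.35,
    p_cd8 = 0.25,
    p_cd103_cd8 = c(TC = 0.60, IM = 0.37),
    p_cd103_noncd8 = 0.13,
    subset_probs = list(
      TC = c(TRM1 = 0.40, TRM2 = 0.10, TRM3 = 0.25, TRM4 = 0.25),
      IM = c(TRM1 = 0.51, TRM2 = 0.10, TRM3 = 0.235, TRM4 = 0.155)),
    p_pd1_tnonrm = 0.20,
    p_tim3_tnonrm = 0.15,
    p_gzmb = c(TRM1 = 0.50, TRM2 = 0.65, TRM3 = 0.45, TRM4 = 0.30,
               TnonRM = 0.20),
    latent_strength = 0.6,
    epi_affinity = c(TRM1 = 0.30, TRM2 = 0.30, TRM3 = 0.50, TRM4 = 0.55,
                     TnonRM = 0.25, other = 0.25),
    attraction_prob = c(TRM1 = 0.10, TRM2 = 0.15, TRM3 = 0.35, TRM4 = 0.50,
                        TnonRM = 0.05, other = 0),
    attraction_sd = 15,
    radius = 20,
    planted_effects = data.frame(
      feature = c("Dens.CD103.TC", "InS.TRM4.IM"),
      form = c("linear", "linear"),
      ln_hr = c(log(0.41), log(2.04)),
      stringsAsFactors = FALSE),
    stage_probs = c(I = 0.553, II = 0.21, III = 0.237),
    stage_ln_hr = c(II = log(1.85), III = log(3.10)),
    baseline_hazard = log(2) / 60,
    follow_up = c(24, 96),
    target_event_frac = 0.394,
    cmv_coupling = -0.4,
    p_cd31 = 0.06,
    p_hif1a = 0.10) {
  cfg <- as.list(environment())
  probs <- c(cfg$cancer_frac, cfg$p_cd8, cfg$p_cd103_cd8,
             cfg$p_cd103_noncd8, unlist(cfg$subset_probs),
             cfg$p_pd1_tnonrm, cfg$p_tim3_tnonrm, cfg$p_gzmb,
             cfg$epi_affinity, cfg$attraction_prob, cfg$stage_probs,
             cfg$p_cd31, cfg$p_hif1a, cfg$target_event_frac)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(abs(vapply(cfg$subset_probs, sum, numeric(1L)) - 1) < 1e-8),
            abs(sum(cfg$stage_probs) - 1) < 1e-8,
            cfg$n_patients >= 1, cfg$window > 0, cfg$radius > 0,
            cfg$baseline_hazard > 0,
            length(cfg$follow_up) == 2L, cfg$follow_up[1L] >= 0,
            cfg$follow_up[1L] < cfg$follow_up[2L],
            all(is.finite(cfg$planted_effects$ln_hr)),
            all(cfg$planted_effects$form %in% c("linear", "indicator")),
            all(cfg$planted_effects$feature %in% feature_names()),
            abs(cfg$cmv_coupling) <= 1)
  if (cfg$nest_radius_mean + 3 * cfg$nest_radius_sd > cfg$window) {
    stop("epithelial nests larger than the region window", call. = FALSE)
  }
  structure(cfg, class = "trm_sim_config")
}

#' Read or write a generator configuration
#'
#' YAML serialization of a [synthetic_config()]; only scalar and named
#' vector/list fields are stored, so configs are human-editable.
#'
#' @param config A `trm_sim_config`.
#' @param path YAML file path.
#' @return `read_sim_config` returns the `trm_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "trm_sim_config"))
  obj <- unclass(config)
  obj$planted_effects <- as.list(obj$planted_effects)
  # named vectors become YAML maps so names survive the round trip
  for (nm in c("p_cd103_cd8", "p_gzmb", "epi_affinity", "attraction_prob",
               "stage_probs", "stage_ln_hr")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  obj$subset_probs <- lapply(obj$subset_probs, as.list)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$planted_effects <- as.data.frame(obj$planted_effects,
                                       stringsAsFactors = FALSE)
  for (nm in c("p_cd103_cd8", "p_gzmb", "epi_affinity", "attraction_prob",
               "stage_probs", "stage_ln_hr")) {
    obj[[nm]] <- unlist(obj[[nm]])
  }
  obj$subset_probs <- lapply(obj$subset_probs, unlist)
  do.call(synthetic_config, obj)
}

# Tilt a probability on the logit scale by a latent shift.
.tilt <- function(p, shift) .expit(.logit(pmin(pmax(p, 1e-6), 1 - 1e-6)) + shift)

# Uniform points in the window, split into inside/outside the nest mask.
.sample_in_mask <- function(n, window, nests, inside) {
  if (n == 0L) return(cbind(x = numeric(0L), y = numeric(0L)))
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 50L)
    x <- runif(m, 0, window); y <- runif(m, 0, window)
    in_nest <- .in_nests(x, y, nests)
    keep <- if (inside) in_nest else !in_nest
    take <- min(sum(keep), n - got)
    if (take > 0L) {
      idx <- which(keep)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(x[idx], y[idx])
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

.in_nests <- function(x, y, nests) {
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(nests))) {
    inside <- inside |
      ((x - nests[k, "cx"])^2 + (y - nests[k, "cy"])^2 <= nests[k, "r"]^2)
  }
  inside
}

# One region's cells for one patient. `tilts` carries the patient's
# latent logit shifts; draws come from the current RNG stream.
.generate_region <- function(config, region, tilts, panel) {
  n_cells <- max(50L, rnbinom(1L, size = config$cells_per_region_size,
                              mu = config$cells_per_region_mean))
  nests <- cbind(
    cx = runif(config$n_nests, 0, config$window),
    cy = runif(config$n_nests, 0, config$window),
    r = pmax(10, rnorm(config$n_nests, config$nest_radius_mean,
                       config$nest_radius_sd)))
  n_cancer <- rbinom(1L, n_cells, config$cancer_frac)
  n_other <- n_cells - n_cancer
  cancer_xy <- .sample_in_mask(n_cancer, config$window, nests, inside = TRUE)

  # Immune-class assignment for non-cancer cells.
  is_cd8 <- runif(n_other) < .tilt(config$p_cd8, 0)
  p_trm <- .tilt(config$p_cd103_cd8[[region]], tilts$cd103)
  is_cd103 <- ifelse(is_cd8,
                     runif(n_other) < p_trm,
                     runif(n_other) < config$p_cd103_noncd8)
  cls <- rep("other", n_other)
  cls[is_cd8 & !is_cd103] <- "TnonRM"
  trm_idx <- which(is_cd8 & is_cd103)
  if (length(trm_idx) > 0L) {
    base <- config$subset_probs[[region]]
    # Tilt the PD-1+ and Tim-3+ subset odds by the latent factor, then
    # renormalize; keeps the four subsets a proper partition.
    w <- base * exp(c(0, tilts$pd1, tilts$tim3, tilts$pd1 + tilts$tim3))
    cls[trm_idx] <- sample(names(base), length(trm_idx), replace = TRUE,
                           prob = w / sum(w))
  }

  # Placement: attracted cells land near a random cancer cell, the
  # rest uniformly in the compartment chosen by epithelium affinity.
  xy <- matrix(NA_real_, n_other, 2L)
  attract_p <- config$attraction_prob[ifelse(cls %in% names(config$attraction_prob),
                                             cls, "other")]
  attracted <- runif(n_other) < attract_p & n_cancer > 0L
  n_att <- sum(attracted)
  if (n_att > 0L) {
    anchor <- sample.int(n_cancer, n_att, replace = TRUE)
    xy[attracted, ] <- cbind(
      pmin(pmax(cancer_xy[anchor, "x"] + rnorm(n_att, 0, config$attraction_sd),
                0), config$window),
      pmin(pmax(cancer_xy[anchor, "y"] + rnorm(n_att, 0, config$attraction_sd),
                0), config$window))
  }
  free <- which(!attracted)
  if (length(free) > 0L) {
    aff <- config$epi_affinity[ifelse(cls[free] %in% names(config$epi_affinity),
                                      cls[free], "other")]
    in_epi <- runif(length(free)) < aff
    xy[free[in_epi], ] <- .sample_in_mask(sum(in_epi), config$window, nests,
                                          inside = TRUE)
    xy[free[!in_epi], ] <- .sample_in_mask(sum(!in_epi), config$window, nests,
                                           inside = FALSE)
  }

  x <- round(c(cancer_xy[, "x"], xy[, 1L]), 2L)
  y <- round(c(cancer_xy[, "y"], xy[, 2L]), 2L)
  compartment <- ifelse(.in_nests(x, y, nests), "epithelium", "stroma")
  cls_all <- c(rep("cancer", n_cancer), cls)
  cd8 <- c(rep(FALSE, n_cancer), is_cd8)
  cd103 <- c(rep(FALSE, n_cancer), is_cd103)

  cells <- data.frame(
    region = region, compartment = compartment, x = x, y = y,
    stringsAsFactors = FALSE)
  cells$CK <- cls_all == "cancer"
  cells$CD8 <- cd8
  cells$CD103 <- cd103
  if (panel == "panel1") {
    pd1 <- tim3 <- rep(FALSE, nrow(cells))
    pd1[cls_all %in% c("TRM2", "TRM4")] <- TRUE
    tim3[cls_all %in% c("TRM3", "TRM4")] <- TRUE
    tn <- cls_all == "TnonRM"
    pd1[tn] <- runif(sum(tn)) < .tilt(config$p_pd1_tnonrm, tilts$pd1)
    tim3[tn] <- runif(sum(tn)) < .tilt(config$p_tim3_tnonrm, tilts$tim3)
    oth <- cls_all == "other"
    pd1[oth] <- runif(sum(oth)) < 0.03
    tim3[oth] <- runif(sum(oth)) < 0.03
    gz_rate <- rep(0.02, nrow(cells))
    gz_rate[cls_all == "cancer"] <- 0.01
    for (s in names(config$p_gzmb)) {
      gz_rate[cls_all == s] <- .tilt(config$p_gzmb[[s]], tilts$gzmb)
    }
    cells$PD1 <- pd1
    cells$TIM3 <- tim3
    cells$GZMB <- runif(nrow(cells)) < gz_rate
  } else {
    cd31 <- rep(FALSE, nrow(cells))
    cd31[cls_all == "other"] <- runif(sum(cls_all == "other")) <
      .tilt(config$p_cd31, tilts$cmv)
    cells$CD31 <- cd31
    cells$HIF1A <- runif(nrow(cells)) < .tilt(config$p_hif1a, tilts$hif)
  }
  cells
}

# Latent patient-level tilts. `z` is the shared factor behind the
# CD103 / PD-1 / Tim-3 / GZMB coupling; panel-2 rates get their own
# (anti-)coupled draws.
.draw_tilts <- function(config) {
  z <- rnorm(1L)
  s <- config$latent_strength
  rho <- config$cmv_coupling
  list(cd103 = s * z,
       pd1 = s * (0.8 * z + 0.6 * rnorm(1L)),
       tim3 = s * (0.8 * z + 0.6 * rnorm(1L)),
       gzmb = s * (0.8 * z + 0.6 * rnorm(1L)),
       cmv = 0.8 * (rho * z + sqrt(1 - rho^2) * rnorm(1L)),
       hif = 0.8 * rnorm(1L))
}

#' Generate one synthetic patient
#'
#' Draws the TC and IM point patterns of a single patient from the
#' current RNG stream. Mostly useful for inspecting the generator; use
#' [generate_cohort()] for a full cohort.
#'
#' @param config A [synthetic_config()].
#' @param patient_id Patient identifier.
#' @param panel `"panel1"` or `"panel2"`.
#' @return A cell `data.frame` in the layout of [read_cell_table()].
#' @export
generate_patient <- function(config, patient_id = "P001",
                             panel = c("panel1", "panel2")) {
  stopifnot(inherits(config, "trm_sim_config"))
  panel <- match.arg(panel)
  tilts <- .draw_tilts(config)
  cells <- do.call(rbind, lapply(.regions, function(reg) {
    .generate_region(config, reg, tilts, panel)
  }))
  cells <- cbind(patient_id = patient_id, cells, stringsAsFactors = FALSE)
  cells$region <- factor(cells$region, levels = .regions)
  cells$compartment <- factor(cells$compartment, levels = .compartments)
  cells <- cells[, c("patient_id", "region", "compartment", "x", "y",
                     panel_markers(panel))]
  attr(cells, "panel") <- panel
  cells
}

#' Generate a synthetic cohort with planted survival effects
#'
#' Generates the full panel-1 cohort: per-patient point patterns,
#' clinical covariates, and disease-free survival drawn from an
#' exponential proportional-hazards model whose linear predictor
#' combines the planted spatial-feature effects (computed from the
#' realized patterns, standardized across the cohort) and the planted
#' stage effects. Censoring is independent uniform, with its upper
#' bound calibrated so the realized event fraction matches
#' `target_event_frac`.
#'
#' @param config A [synthetic_config()].
#' @return List of class `trm_sim`: `cohort` (a `trm_cohort`),
#'   `features` (the [compute_feature_vectors()] table used to plant
#'   survival), `truth` (`data.frame` with the true linear predictor
#'   `lp`, uncensored event time `t_true` and censoring time
#'   `c_time`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "trm_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  cells <- do.call(rbind, lapply(ids, function(id) {
    generate_patient(config, id, panel = "panel1")
  }))
  attr(cells, "panel") <- "panel1"
  n <- config$n_patients
  clinical <- data.frame(
    patient_id = ids,
    age_group = factor(ifelse(runif(n) < 0.5, "<=60", ">60"),
                       levels = .clinical_levels$age_group),
    gender = factor(ifelse(runif(n) < 0.35, "female", "male"),
                    levels = .clinical_levels$gender),
    smoking = factor(ifelse(runif(n) < 0.45, "heavy", "non_light"),
                     levels = .clinical_levels$smoking),
    histology = factor(ifelse(runif(n) < 0.347, "LUSC", "LUAD"),
                       levels = .clinical_levels$histology),
    stage = factor(sample(names(config$stage_probs), n, replace = TRUE,
                          prob = config$stage_probs),
                   levels = .clinical_levels$stage),
    dfs_months = 0, dfs_event = 0L,
    stringsAsFactors = FALSE)
  cohort <- structure(list(cells = cells, clinical = clinical,
                           panel = "panel1"), class = "trm_cohort")
  features <- compute_feature_vectors(cohort, r = config$radius)

  lp <- rep(0, n)
  pe <- config$planted_effects
  for (i in seq_len(nrow(pe))) {
    v <- features[[pe$feature[i]]]
    v[is.na(v)] <- median(v, na.rm = TRUE)
    v[is.na(v)] <- 0  # feature missing for every patient
    x <- if (pe$form[i] == "linear") {
      s <- sd(v); if (!is.finite(s) || s == 0) s <- 1
      (v - mean(v)) / s
    } else {
      as.numeric(v > median(v))
    }
    lp <- lp + pe$ln_hr[i] * x
  }
  stage_eff <- c(I = 0, config$stage_ln_hr)
  lp <- lp + stage_eff[as.character(clinical$stage)]

  # Censoring is uniform over the follow-up window; the baseline
  # hazard is rescaled so the realized event fraction hits its target.
  t_base <- rexp(n) / (config$baseline_hazard * exp(lp))
  c_time <- runif(n, config$follow_up[1L], config$follow_up[2L])
  f <- function(m) mean(t_base / m < c_time) - config$target_event_frac
  m <- if (f(1e6) < 0) 1e6 else if (f(1e-6) > 0) 1e-6 else
    uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-9)$root
  t_true <- t_base / m
  clinical$dfs_months <- round(pmin(t_true, c_time), 2L)
  clinical$dfs_event <- as.integer(t_true <= c_time)
  cohort$clinical <- clinical

  truth <- data.frame(patient_id = ids, lp = unname(lp),
                      t_true = t_true, c_time = c_time,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pe))) truth[[pe$feature[i]]] <- features[[pe$feature[i]]]
  structure(list(cohort = cohort, features = features, truth = truth,
                 config = config), class = "trm_sim")
}

#' Generate a synthetic panel-2 cohort
#'
#' Generates the microvessel/hypoxia panel: per-patient CD31+
#' (endothelium) rates are drawn from a Gaussian copula with
#' correlation `cmv_coupling` against the latent TRM-abundance factor
#' (negative values make microvessel density anti-correlated with TRM
#' infiltration), while Hif-1alpha rates are independent of TRM.
#' Survival is not planted; the clinical table carries covariates
#' only.
#'
#' @param config A [synthetic_config()].
#' @return A `trm_cohort` with `panel = "panel2"`.
#' @export
generate_panel2 <- function(config) {
  stopifnot(inherits(config, "trm_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  cells <- do.call(rbind, lapply(ids, function(id) {
    generate_patient(config, id, panel = "panel2")
  }))
  attr(cells, "panel") <- "panel2"
  n <- config$n_patients
  clinical <- data.frame(
    patient_id = ids,
    age_group = factor("<=60", levels = .clinical_levels$age_group),
    gender = factor("male", levels = .clinical_levels$gender),
    smoking = factor("non_light", levels = .clinical_levels$smoking),
    histology = factor("LUAD", levels = .clinical_levels$histology),
    stage = factor("I", levels = .clinical_levels$stage),
    dfs_months = 0, dfs_event = 0L, stringsAsFactors = FALSE)
  structure(list(cells = cells, clinical = clinical, panel = "panel2"),
            class = "trm_cohort")
}
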