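# Per-patient spatial immune features: Dens, InS, mNND, CCPS.
#
# All distances are planar Euclidean in micrometres, computed within a
# tumor region across both tissue compartments; no edge correction is
# applied at core boundaries.

#' Cell density per 1000 cells
#'
#' Density of a phenotype in one patient-region, normalized to the
#' total segmented cell count of that region (both compartments):
#' `Dens(A) = n(A) / n(total) * 1000`.
#'
#' @param n_pheno Phenotype cell count `n(A)`.
#' @param n_total Total segmented cells of the patient-region.
#' @return Cells per 1000 cells, in `[0, 1000]`; `NA` for an empty
#'   region.
#' @examples
#' cell_density(5, 1000)  # 5.0
#' @export
cell_density <- function(n_pheno, n_total) {
  ifelse(n_total > 0, n_pheno / n_total * 1000, NA_real_)
}

#' Infiltration score
#'
#' Ratio of a phenotype's epithelial to stromal cell count in one
#' patient-region: `InS(A) = n(A)^epi / n(A)^stro`. Reflects how far
#' the phenotype penetrates the epithelial (cancer-nest) compartment.
#'
#' @param n_epi,n_stro Phenotype counts in the epithelium and stroma
#'   compartments.
#' @return Non-negative ratio. A zero stromal count makes the ratio
#'   undefined: `NA` is returned both for `0/0` and for the
#'   "undefined-infinite" case `n_epi > 0, n_stro = 0` (the latter is
#'   distinguishable by [is_infinite_ins()]).
#' @export
infiltration_score <- function(n_epi, n_stro) {
  ifelse(n_stro > 0, n_epi / n_stro, NA_real_)
}

#' @rdname infiltration_score
#' @export
is_infinite_ins <- function(n_epi, n_stro) {
  n_stro == 0 & n_epi > 0
}

#' Mean nearest-neighbour distance to cancer cells
#'
#' For each cell of phenotype A, the Euclidean distance to its nearest
#' cancer cell; mNND is the mean of these minima over all A cells.
#' Larger values mean weaker spatial interaction with the tumor.
#'
#' The pairwise distance computation is blocked over A cells to bound
#' memory, and agrees with a naive double loop to within floating-point
#' rounding.
#'
#' @param ax,ay Coordinates (um) of the A cells.
#' @param cx,cy Coordinates (um) of the cancer cells.
#' @return Mean distance in um; `NA` if either set is empty.
#' @examples
#' mean_nnd(0, 0, c(3, 10), c(4, 0))  # 5: nearest cancer cell is at (3,4)
#' @export
mean_nnd <- function(ax, ay, cx, cy) {
  if (length(ax) == 0L || length(cx) == 0L) return(NA_real_)
  mean(nearest_cancer_distance(ax, ay, cx, cy))
}

# Distance from each (ax, ay) to its nearest (cx, cy), blocked so the
# working distance matrix stays under ~8 MB.
nearest_cancer_distance <- function(ax, ay, cx, cy) {
  n <- length(ax)
  block <- max(1L, floor(1e6 / length(cx)))
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(ax[idx], cx, "-")^2 + outer(ay[idx], cy, "-")^2
    j <- max.col(-d2, ties.method = "first")
    out[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
  }
  out
}

#' Cancer-cell proximity score
#'
#' For each cancer cell, the number of phenotype-A cells within radius
#' `r`; CCPS is the mean of these counts over all cancer cells. Higher
#' values mean more A cells in direct interaction range of the tumor.
#'
#' @inheritParams mean_nnd
#' @param r Proximity radius in um (cells at distance exactly `r`
#'   count). The radius is a fixed analysis parameter, reported with
#'   all outputs; the package default is 20 um, a cell-contact-scale
#'   neighbourhood.
#' @return Mean count (non-negative real); `NA` if there are no cancer
#'   cells. No A cells gives 0.
#' @examples
#' # two cancer cells with 3 and 1 A cells within r: CCPS = 2
#' cancer_proximity_score(c(1, 2, 3, 101), c(0, 0, 0, 0),
#'                        c(0, 100), c(0, 0), r = 5)
#' @export
cancer_proximity_score <- function(ax, ay, cx, cy, r = 20) {
  stopifnot(r > 0)
  if (length(cx) == 0L) return(NA_real_)
  if (length(ax) == 0L) return(0)
  n <- length(cx)
  block <- max(1L, floor(1e6 / length(ax)))
  counts <- numeric(n)
  r2 <- r * r
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(cx[idx], ax, "-")^2 + outer(cy[idx], ay, "-")^2
    counts[idx] <- rowSums(d2 <= r2)
  }
  mean(counts)
}

# Feature grid of the panel-1 analysis: which phenotypes get which
# feature kinds, in each of the two regions.
.dens_phenotypes    <- c("CD103", "CD8", "TRM", "TnonRM",
                         "TRM1", "TRM2", "TRM3", "TRM4",
                         "PD1_CD8", "TIM3_CD8", "GZMB_CD8")
.spatial_phenotypes <- c("TRM", "TnonRM", "TRM1", "TRM2", "TRM3", "TRM4")

#' Names of the candidate feature set
#'
#' Column names produced by [compute_feature_vectors()]:
#' `<kind>.<phenotype>.<region>`, e.g. `"InS.TRM4.IM"`.
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c(paste0("Dens.", rep(.dens_phenotypes, each = 2L), ".", .regions),
    paste0("InS.",  rep(.spatial_phenotypes, each = 2L), ".", .regions),
    paste0("mNND.", rep(.spatial_phenotypes, each = 2L), ".", .regions),
    paste0("CCPS.", rep(.spatial_phenotypes, each = 2L), ".", .regions))
}

# Feature vector for the cells of one patient-region.
region_features <- function(cells, pheno, region, r) {
  out <- setNames(
    rep(NA_real_, length(feature_names()) / 2L),
    grep(paste0("\\.", region, "$"), feature_names(), value = TRUE)
  )
  n_total <- nrow(cells)
  if (n_total == 0L) return(out)
  cancer <- pheno[, "Cancer"]
  cx <- cells$x[cancer]; cy <- cells$y[cancer]
  epi <- cells$compartment == "epithelium"
  for (p in .dens_phenotypes) {
    out[paste0("Dens.", p, ".", region)] <-
      cell_density(sum(pheno[, p]), n_total)
  }
  for (p in .spatial_phenotypes) {
    in_p <- pheno[, p]
    out[paste0("InS.", p, ".", region)] <-
      infiltration_score(sum(in_p & epi), sum(in_p & !epi))
    out[paste0("mNND.", p, ".", region)] <-
      mean_nnd(cells$x[in_p], cells$y[in_p], cx, cy)
    out[paste0("CCPS.", p, ".", region)] <-
      cancer_proximity_score(cells$x[in_p], cells$y[in_p], cx, cy, r = r)
  }
  out
}

#' Compute per-patient spatial feature vectors
#'
#' Computes the full candidate feature set for every patient of a
#' panel-1 cohort: density (per 1000 cells) for CD103+, CD8+, TRM,
#' TnonRM, TRM1-TRM4, PD-1+CD8+, Tim-3+CD8+ and GZMB+CD8+ cells;
#' infiltration score, mean nearest-neighbour distance to cancer cells
#' and cancer-cell proximity score for TRM, TnonRM and TRM1-TRM4 —
#' each in the tumor center (TC) and invasive margin (IM).
#'
#' Features of a region the patient lacks, and ratios with an empty
#' denominator, are `NA`; missingness is carried through to the
#' modelling stage, which imputes training-set medians.
#'
#' @param cohort A panel-1 `trm_cohort`.
#' @param r Proximity radius for CCPS, um.
#' @return A `data.frame` with `patient_id` plus one numeric column per
#'   feature (see [feature_names()]), and attribute `"radius"`.
#' @export
compute_feature_vectors <- function(cohort, r = 20) {
  stopifnot(inherits(cohort, "trm_cohort"), cohort$panel == "panel1")
  ids <- cohort$clinical$patient_id
  pheno_all <- phenotype_matrix(cohort$cells, "panel1")
  rows <- lapply(ids, function(id) {
    in_pat <- cohort$cells$patient_id == id
    vals <- unlist(lapply(.regions, function(reg) {
      in_reg <- in_pat & cohort$cells$region == reg
      region_features(cohort$cells[in_reg, , drop = FALSE],
                      pheno_all[in_reg, , drop = FALSE], reg, r = r)
    }))
    vals[feature_names()]
  })
  out <- data.frame(patient_id = ids,
                    do.call(rbind, rows),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "radius") <- r
  out
}

#' Microvessel and hypoxia correlates of TRM spatial features
#'
#' For a panel-2 cohort, correlates the per-patient density of CD31+
#' endothelium (cancer microvessels) and of Hif-1alpha+ (hypoxic)
#' cells with the spatial features of TRM and TnonRM cells, per
#' region, using Spearman rank correlation.
#'
#' @param cohort A panel-2 `trm_cohort` with at least 3 patients.
#' @param r Proximity radius for CCPS, um.
#' @return A `data.frame` with columns `marker` (`CD31`/`HIF1A`),
#'   `feature`, `region`, `rho`, `p_value`, `n` (non-missing pairs).
#'   `rho` is `NA` when fewer than 3 complete pairs exist or a
#'   variable is constant (undefined ranks).
#' @export
microvessel_correlates <- function(cohort, r = 20) {
  stopifnot(inherits(cohort, "trm_cohort"), cohort$panel == "panel2")
  ids <- cohort$clinical$patient_id
  stopifnot(length(ids) >= 3L)
  pheno_all <- phenotype_matrix(cohort$cells, "panel2")
  feats <- c("Dens.TRM", "InS.TRM", "mNND.TRM", "CCPS.TRM",
             "Dens.TnonRM", "InS.TnonRM", "mNND.TnonRM", "CCPS.TnonRM")
  per_patient <- lapply(ids, function(id) {
    in_pat <- cohort$cells$patient_id == id
    unlist(lapply(.regions, function(reg) {
      in_reg <- in_pat & cohort$cells$region == reg
      cells <- cohort$cells[in_reg, , drop = FALSE]
      ph <- pheno_all[in_reg, , drop = FALSE]
      vals <- setNames(rep(NA_real_, length(feats) + 2L),
                       paste0(c(feats, "Dens.CD31", "Dens.HIF1A"), ".", reg))
      if (nrow(cells) == 0L) return(vals)
      cancer <- ph[, "Cancer"]
      epi <- cells$compartment == "epithelium"
      for (p in c("TRM", "TnonRM")) {
        in_p <- ph[, p]
        vals[paste0("Dens.", p, ".", reg)] <-
          cell_density(sum(in_p), nrow(cells))
        vals[paste0("InS.", p, ".", reg)] <-
          infiltration_score(sum(in_p & epi), sum(in_p & !epi))
        vals[paste0("mNND.", p, ".", reg)] <-
          mean_nnd(cells$x[in_p], cells$y[in_p],
                   cells$x[cancer], cells$y[cancer])
        vals[paste0("CCPS.", p, ".", reg)] <-
          cancer_proximity_score(cells$x[in_p], cells$y[in_p],
                                 cells$x[cancer], cells$y[cancer], r = r)
      }
      vals[paste0("Dens.CD31.", reg)]  <- cell_density(sum(ph[, "CD31"]),
                                                       nrow(cells))
      vals[paste0("Dens.HIF1A.", reg)] <- cell_density(sum(ph[, "HIF1A"]),
                                                       nrow(cells))
      vals
    }))
  })
  mat <- do.call(rbind, per_patient)
  grid <- expand.grid(marker = c("CD31", "HIF1A"), feature = feats,
                      region = .regions, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    x <- mat[, paste0("Dens.", g$marker, ".", g$region)]
    y <- mat[, paste0(g$feature, ".", g$region)]
    ok <- is.finite(x) & is.finite(y)
    rho <- p <- NA_real_
    if (sum(ok) >= 3L && var(x[ok]) > 0 && var(y[ok]) > 0) {
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(marker = g$marker, feature = g$feature, region = g$region,
               rho = rho, p_value = p, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "radius") <- r
  out
}
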