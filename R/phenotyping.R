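# Composite cell phenotypes from binary marker calls.
#
# CK+ cells are cancer cells regardless of other markers (cells
# co-expressing CK and CD8 are treated as segmentation artifacts and
# kept out of the T-cell phenotypes), so the cancer-cell set is
# disjoint from every immune set used in the distance metrics.

# Phenotype predicates for panel 1, evaluated on the logical marker
# columns of a cell table. GZMB never enters a subset definition: the
# TRM1-4 taxonomy is by PD-1/Tim-3 co-expression only, and GZMB
# positivity is the cytotoxicity readout layered on top.
.panel1_phenotypes <- list(
  Cancer  = function(m) m$CK,
  CD8     = function(m) m$CD8 & !m$CK,
  CD103   = function(m) m$CD103 & !m$CK,
  TRM     = function(m) m$CD8 & m$CD103 & !m$CK,
  TnonRM  = function(m) m$CD8 & !m$CD103 & !m$CK,
  TRM1    = function(m) m$CD8 & m$CD103 & !m$CK & !m$PD1 & !m$TIM3,
  TRM2    = function(m) m$CD8 & m$CD103 & !m$CK &  m$PD1 & !m$TIM3,
  TRM3    = function(m) m$CD8 & m$CD103 & !m$CK & !m$PD1 &  m$TIM3,
  TRM4    = function(m) m$CD8 & m$CD103 & !m$CK &  m$PD1 &  m$TIM3,
  PD1_CD8  = function(m) m$CD8 & !m$CK & m$PD1,
  TIM3_CD8 = function(m) m$CD8 & !m$CK & m$TIM3
)

.panel2_phenotypes <- list(
  Cancer = function(m) m$CK,
  CD8    = function(m) m$CD8 & !m$CK,
  TRM    = function(m) m$CD8 & m$CD103 & !m$CK,
  TnonRM = function(m) m$CD8 & !m$CD103 & !m$CK,
  CD31   = function(m) m$CD31 & !m$CK,
  HIF1A  = function(m) m$HIF1A
)

#' Phenotype scheme
#'
#' The named list of phenotype predicates for a panel. Each predicate
#' is a pure function of one cell's marker calls. For panel 1 the
#' scheme includes the four TRM functional subsets defined by
#' immune-checkpoint co-expression: TRM1 = PD-1-Tim-3- TRM, TRM2 =
#' PD-1+Tim-3- TRM, TRM3 = PD-1-Tim-3+ TRM, TRM4 = PD-1+Tim-3+ TRM.
#' GZMB+ variants (e.g. `GZMB_TRM2`) mark the cytotoxic fraction of
#' each CD8-derived phenotype.
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return Named list of predicate functions.
#' @export
phenotype_scheme <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  base <- if (panel == "panel1") .panel1_phenotypes else .panel2_phenotypes
  if (panel == "panel1") {
    gz_parents <- c("CD8", "TRM", "TnonRM", "TRM1", "TRM2", "TRM3", "TRM4")
    for (p in gz_parents) {
      base[[paste0("GZMB_", p)]] <- local({
        parent <- base[[p]]
        function(m) parent(m) & m$GZMB
      })
    }
  }
  base
}

#' Phenotype membership matrix
#'
#' Evaluates every phenotype predicate of a panel on a cell table.
#'
#' @param cells A validated cell `data.frame` (see [read_cell_table()]).
#' @param panel Marker panel; defaults to the panel recorded on `cells`.
#' @return Logical matrix, one row per cell, one column per phenotype.
#' @examples
#' cells <- data.frame(CD8 = c(TRUE, TRUE, FALSE), CD103 = c(TRUE, FALSE, FALSE),
#'                     PD1 = c(TRUE, FALSE, FALSE), TIM3 = c(FALSE, FALSE, FALSE),
#'                     GZMB = c(TRUE, FALSE, FALSE), CK = c(FALSE, FALSE, TRUE))
#' phenotype_matrix(cells, "panel1")[, c("TRM", "TRM2", "TnonRM", "Cancer")]
#' @export
phenotype_matrix <- function(cells, panel = attr(cells, "panel")) {
  if (is.null(panel)) panel <- "panel1"
  scheme <- phenotype_scheme(panel)
  out <- vapply(scheme, function(f) f(cells), logical(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(scheme)))
  out
}

#' Classify a single cell
#'
#' @param cell A one-row cell `data.frame` with the panel's marker
#'   columns.
#' @inheritParams phenotype_matrix
#' @return Character vector of all phenotype labels that apply.
#' @examples
#' classify_cell(data.frame(CD8 = TRUE, CD103 = TRUE, PD1 = TRUE,
#'                          TIM3 = FALSE, GZMB = TRUE, CK = FALSE))
#' @export
classify_cell <- function(cell, panel = "panel1") {
  stopifnot(nrow(cell) == 1L)
  m <- phenotype_matrix(cell, panel)
  colnames(m)[m[1L, ]]
}

#' GZMB-positive fraction of a phenotype
#'
#' The proportion of cells of a CD8-derived phenotype that are GZMB+,
#' used as the cytotoxicity readout when comparing CD8+ T-cell subsets.
#'
#' @param cells A panel-1 cell `data.frame`.
#' @param subset Phenotype name (e.g. `"TRM2"`).
#' @return Proportion in `[0, 1]`; `NA` if the subset is empty (an
#'   empty denominator is missing, not zero).
#' @export
gzmb_positive_fraction <- function(cells, subset) {
  m <- phenotype_matrix(cells, "panel1")
  stopifnot(subset %in% colnames(m))
  in_subset <- m[, subset]
  if (!any(in_subset)) return(NA_real_)
  sum(cells$GZMB[in_subset]) / sum(in_subset)
}

#' Nested phenotype composition
#'
#' The fraction of `denominator`-phenotype cells that also carry the
#' `numerator` phenotype, e.g. the proportion of CD103+ cells that are
#' TRM, or the composition of TRM over its four subsets.
#'
#' @param cells A cell `data.frame`.
#' @param numerator,denominator Phenotype names; `numerator` may be a
#'   vector, in which case one fraction per element is returned.
#' @param panel Marker panel.
#' @return Named numeric vector of proportions; `NA` when the
#'   denominator count is zero. Fractions of a partition (TRM1-TRM4
#'   over TRM) sum to 1.
#' @export
composition_fractions <- function(cells, numerator, denominator,
                                  panel = "panel1") {
  m <- phenotype_matrix(cells, panel)
  stopifnot(all(c(numerator, denominator) %in% colnames(m)))
  n_den <- sum(m[, denominator])
  out <- vapply(numerator, function(p) {
    if (n_den == 0L) NA_real_ else sum(m[, p] & m[, denominator]) / n_den
  }, numeric(1L))
  setNames(out, numerator)
}
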