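# Domain model and CSV input/output for per-cell mIF tables and
# clinical outcome tables.

#' Marker panels
#'
#' Marker sets for the two multiplex immunofluorescence panels. Panel 1
#' profiles cytotoxic T cells and TRM subsets (CD8, CD103, PD-1, Tim-3,
#' GZMB) against cancer cells (CK). Panel 2 profiles TRM against cancer
#' microvessels (CD31) and cellular hypoxia (Hif-1alpha).
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return Character vector of marker column names.
#' @examples
#' panel_markers("panel1")
#' @export
panel_markers <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  switch(panel,
    panel1 = c("CD8", "CD103", "PD1", "TIM3", "GZMB", "CK"),
    panel2 = c("CD8", "CD103", "CK", "CD31", "HIF1A")
  )
}

.regions      <- c("TC", "IM")
.compartments <- c("epithelium", "stroma")

.clinical_levels <- list(
  age_group = c("<=60", ">60"),
  gender    = c("male", "female"),
  smoking   = c("non_light", "heavy"),
  histology = c("LUAD", "LUSC"),
  stage     = c("I", "II", "III")
)

#' Read a per-cell table
#'
#' Reads a CSV of segmented cells (one row per cell) as exported from
#' mIF image analysis, with columns `patient_id`, `region` (`TC` tumor
#' center / `IM` invasive margin), `compartment`
#' (`epithelium`/`stroma`), `x_um`, `y_um` and one 0/1 column per panel
#' marker. Coordinates are planar Euclidean in micrometres; marker
#' thresholding is assumed done upstream.
#'
#' @param path CSV file path.
#' @param panel Which marker panel the table carries (see
#'   [panel_markers()]).
#' @return A `data.frame` of validated cells: `patient_id` (character),
#'   `region` and `compartment` (factors), `x`, `y` (numeric, um) and
#'   one logical column per marker. Unknown columns are dropped with a
#'   warning.
#' @seealso [read_clinical_table()], [assemble_cohort()]
#' @export
read_cell_table <- function(path, panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  markers <- panel_markers(panel)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "region", "compartment", "x_um", "y_um", markers)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  validate_cells(raw[required], panel = panel, source = path)
}

# Validates and coerces a raw cell data.frame; `source` only labels errors.
# Line numbers reported count the CSV header as line 1.
validate_cells <- function(raw, panel, source = "cell table") {
  markers <- panel_markers(panel)
  bad_xy <- !is.finite(raw$x_um) | !is.finite(raw$y_um)
  if (any(bad_xy)) {
    stop(source, ": non-finite coordinates on line(s) ",
         paste(head(which(bad_xy), 5L) + 1L, collapse = ", "), call. = FALSE)
  }
  bad_region <- !(raw$region %in% .regions)
  if (any(bad_region)) {
    stop(source, ": region must be one of ",
         paste(.regions, collapse = "/"), "; offending line(s) ",
         paste(head(which(bad_region), 5L) + 1L, collapse = ", "),
         call. = FALSE)
  }
  bad_comp <- !(raw$compartment %in% .compartments)
  if (any(bad_comp)) {
    stop(source, ": compartment must be one of ",
         paste(.compartments, collapse = "/"), "; offending line(s) ",
         paste(head(which(bad_comp), 5L) + 1L, collapse = ", "),
         call. = FALSE)
  }
  cells <- data.frame(
    patient_id  = as.character(raw$patient_id),
    region      = factor(raw$region, levels = .regions),
    compartment = factor(raw$compartment, levels = .compartments),
    x = as.numeric(raw$x_um),
    y = as.numeric(raw$y_um),
    stringsAsFactors = FALSE
  )
  for (m in markers) {
    v <- raw[[m]]
    ok <- (is.logical(v) & !is.na(v)) | (v %in% c(0, 1, "0", "1"))
    if (!all(ok)) {
      stop(source, ": marker '", m, "' must be 0/1; offending line(s) ",
           paste(head(which(!ok), 5L) + 1L, collapse = ", "), call. = FALSE)
    }
    cells[[m]] <- as.logical(as.integer(as.character(v)) |
                               (is.logical(v) & v))
  }
  attr(cells, "panel") <- panel
  cells
}

#' Read a clinical outcome table
#'
#' Reads the per-patient clinical table: `patient_id`, `age_group`
#' (`<=60`/`>60`), `gender` (`male`/`female`), `smoking`
#' (`non_light`/`heavy`), `histology` (`LUAD`/`LUSC`), `stage`
#' (`I`/`II`/`III`; the cohort design is restricted to operable stage
#' I-III disease), `dfs_months` (disease-free survival, months from
#' radical surgery to progression or last follow-up) and `dfs_event`
#' (0/1, 1 = progression observed).
#'
#' @param path CSV file path.
#' @return A validated `data.frame`, one row per patient, enum columns
#'   as factors with the declared levels.
#' @export
read_clinical_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", names(.clinical_levels), "dfs_months", "dfs_event")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_clinical(raw[required], source = path)
}

validate_clinical <- function(raw, source = "clinical table") {
  ids <- as.character(raw$patient_id)
  if (anyDuplicated(ids)) {
    stop(source, ": duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (col in names(.clinical_levels)) {
    lev <- .clinical_levels[[col]]
    bad <- !(raw[[col]] %in% lev)
    if (any(bad)) {
      stop(source, ": '", col, "' has value(s) outside {",
           paste(lev, collapse = ", "), "}: ",
           paste(unique(raw[[col]][bad]), collapse = ", "), call. = FALSE)
    }
    out[[col]] <- factor(raw[[col]], levels = lev)
  }
  t <- as.numeric(raw$dfs_months)
  if (any(!is.finite(t) | t < 0)) {
    stop(source, ": dfs_months must be finite and non-negative", call. = FALSE)
  }
  ev <- raw$dfs_event
  if (!all(ev %in% c(0, 1, TRUE, FALSE))) {
    stop(source, ": dfs_event must be 0/1", call. = FALSE)
  }
  out$dfs_months <- t
  out$dfs_event  <- as.integer(ev)
  out
}

#' Assemble a cohort from cell and clinical tables
#'
#' Inner-joins the per-cell table and the clinical table on
#' `patient_id`. Patients present in only one of the two tables are
#' dropped with a message reporting the counts; an empty intersection
#' is an error.
#'
#' @param cells A validated cell `data.frame` from [read_cell_table()].
#' @param clinical A validated clinical `data.frame` from
#'   [read_clinical_table()].
#' @param panel Marker panel of `cells`; defaults to the panel recorded
#'   on the cell table.
#' @return A `trm_cohort` object: a list with elements `cells`,
#'   `clinical` and `panel`. Patients whose cells lack one of the two
#'   tumor regions are kept; their region-level features are later
#'   reported as missing.
#' @export
assemble_cohort <- function(cells, clinical, panel = attr(cells, "panel")) {
  if (is.null(panel)) panel <- "panel1"
  keep <- intersect(unique(cells$patient_id), clinical$patient_id)
  if (length(keep) == 0L) {
    stop("no patient_id is shared between the cell and clinical tables",
         call. = FALSE)
  }
  n_cell_only <- length(setdiff(unique(cells$patient_id), keep))
  n_clin_only <- length(setdiff(clinical$patient_id, keep))
  if (n_cell_only + n_clin_only > 0L) {
    message("assemble_cohort: dropped ", n_cell_only,
            " patient(s) with cells but no clinical record and ",
            n_clin_only, " with clinical record but no cells")
  }
  cells    <- cells[cells$patient_id %in% keep, , drop = FALSE]
  clinical <- clinical[match(sort(keep), clinical$patient_id), , drop = FALSE]
  cells    <- cells[order(cells$patient_id), , drop = FALSE]
  rownames(cells) <- rownames(clinical) <- NULL
  structure(list(cells = cells, clinical = clinical, panel = panel),
            class = "trm_cohort")
}

#' @export
print.trm_cohort <- function(x, ...) {
  cat("<trm_cohort> ", nrow(x$clinical), " patients, ",
      nrow(x$cells), " cells (", x$panel, ")\n", sep = "")
  tab <- table(x$cells$region)
  cat("  cells per region: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write cohort tables
#'
#' Writes a cohort back to the two-CSV on-disk form read by
#' [read_cell_table()] and [read_clinical_table()]. Coordinates are
#' written at 0.01 um precision, which round-trips exactly for
#' coordinates stored at that precision.
#'
#' @param cohort A `trm_cohort`.
#' @param cells_path,clinical_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, cells_path, clinical_path) {
  stopifnot(inherits(cohort, "trm_cohort"))
  cells <- cohort$cells
  out <- data.frame(
    patient_id  = cells$patient_id,
    region      = as.character(cells$region),
    compartment = as.character(cells$compartment),
    x_um = sprintf("%.2f", cells$x),
    y_um = sprintf("%.2f", cells$y),
    stringsAsFactors = FALSE
  )
  for (m in panel_markers(cohort$panel)) out[[m]] <- as.integer(cells[[m]])
  write.csv(out, cells_path, row.names = FALSE, quote = FALSE)
  clin <- cohort$clinical
  clin_out <- data.frame(lapply(clin, as.character),
                         stringsAsFactors = FALSE)
  clin_out$dfs_months <- sprintf("%.4f", clin$dfs_months)
  write.csv(clin_out, clinical_path, row.names = FALSE, quote = FALSE)
  invisible(c(cells = cells_path, clinical = clinical_path))
}
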