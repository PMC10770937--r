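# Shared fixtures: tiny cell tables built in code, naive reference
# implementations of the spatial metrics, and scaled-down generator
# configs for unit tests.

make_cells <- function(patient_id = "P1", region = "TC",
                       compartment = "stroma", x = 0, y = 0,
                       CD8 = FALSE, CD103 = FALSE, PD1 = FALSE,
                       TIM3 = FALSE, GZMB = FALSE, CK = FALSE) {
  df <- data.frame(patient_id = patient_id, region = region,
                   compartment = compartment, x = x, y = y,
                   CD8 = CD8, CD103 = CD103, PD1 = PD1, TIM3 = TIM3,
                   GZMB = GZMB, CK = CK, stringsAsFactors = FALSE)
  df$region <- factor(df$region, levels = c("TC", "IM"))
  df$compartment <- factor(df$compartment,
                           levels = c("epithelium", "stroma"))
  attr(df, "panel") <- "panel1"
  df
}

write_cells_csv <- function(df, path) {
  out <- df
  names(out)[names(out) == "x"] <- "x_um"
  names(out)[names(out) == "y"] <- "y_um"
  for (m in c("CD8", "CD103", "PD1", "TIM3", "GZMB", "CK")) {
    if (m %in% names(out)) out[[m]] <- as.integer(out[[m]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

make_clinical <- function(patient_id, dfs_months = 12, dfs_event = 1,
                          stage = "I") {
  n <- length(patient_id)
  data.frame(patient_id = patient_id,
             age_group = rep("<=60", n), gender = rep("male", n),
             smoking = rep("non_light", n), histology = rep("LUAD", n),
             stage = rep(stage, length.out = n),
             dfs_months = rep(dfs_months, length.out = n),
             dfs_event = rep(dfs_event, length.out = n),
             stringsAsFactors = FALSE)
}

# O(n^2) reference implementations, independent of the package's
# blocked/vectorized code paths.
brute_mnnd <- function(ax, ay, cx, cy) {
  if (length(ax) == 0L || length(cx) == 0L) return(NA_real_)
  total <- 0
  for (i in seq_along(ax)) {
    best <- Inf
    for (j in seq_along(cx)) {
      d <- sqrt((ax[i] - cx[j])^2 + (ay[i] - cy[j])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / length(ax)
}

brute_ccps <- function(ax, ay, cx, cy, r) {
  if (length(cx) == 0L) return(NA_real_)
  counts <- numeric(length(cx))
  for (i in seq_along(cx)) {
    for (j in seq_along(ax)) {
      if (sqrt((cx[i] - ax[j])^2 + (cy[i] - ay[j])^2) <= r) {
        counts[i] <- counts[i] + 1
      }
    }
  }
  mean(counts)
}

# Independent log-rank chi-square (two groups), for checking the
# cut-point scan against a from-scratch computation.
brute_logrank_chisq <- function(group, time, event) {
  tt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    if (n < 2) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  (o1 - e1)^2 / v
}

small_config <- function(n_patients = 10, cells_per_region_mean = 250, ...) {
  synthetic_config(n_patients = n_patients,
                   cells_per_region_mean = cells_per_region_mean,
                   cells_per_region_size = 50, ...)
}
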