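# Survival evaluation of the signature: Kaplan-Meier / log-rank, Cox
# models with backward elimination, time-dependent ROC with inverse
# probability of censoring weighting, and the SIS + stage combination.

#' Kaplan-Meier curves and log-rank test
#'
#' Fits per-group Kaplan-Meier estimates of disease-free survival and
#' tests the group difference with a two-sided log-rank test.
#'
#' @param group Factor or character group labels (at least 2 groups).
#' @param time,event DFS months and 0/1 event indicator.
#' @return List: `fit` (the [survival::survfit()] object), `median`
#'   (named vector of median DFS per group; `NA` when not reached,
#'   with attribute `"not_reached"`), `p_value` (log-rank; `NA` when
#'   there are no events), `chisq`.
#' @export
km_logrank <- function(group, time, event) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("km_logrank needs at least 2 groups", call. = FALSE)
  }
  y <- survival::Surv(time, event)
  fit <- survival::survfit(y ~ group)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  attr(med, "not_reached") <- is.na(med)
  if (sum(event) == 0L) {
    return(list(fit = fit, median = med, p_value = NA_real_,
                chisq = NA_real_))
  }
  sd <- survival::survdiff(y ~ group)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  list(fit = fit, median = med, p_value = p, chisq = sd$chisq)
}

# Likelihood-ratio p-value for a whole covariate in a coxph fit.
.lrt_p <- function(fit) {
  s <- summary(fit)
  unname(s$logtest["pvalue"])
}

#' Univariate and multivariate Cox models with backward elimination
#'
#' Fits a univariate Cox proportional-hazards model of DFS for every
#' covariate, then a multivariate model on the covariates with
#' univariate p < `alpha` (likelihood-ratio test per covariate),
#' iteratively removing the covariate with the largest p-value until
#' every retained covariate has p < `alpha`.
#'
#' @param data `data.frame` of covariates (factors for categorical
#'   variables; first level is the reference).
#' @param time,event DFS outcome aligned with `data` rows.
#' @param covariates Covariate names in `data` (default: all columns).
#' @param alpha Retention threshold (default 0.05, two-sided).
#' @return List with `table` (a `data.frame` in the style of a
#'   clinical Table 1: `variable`, `level`, `model`
#'   (`"univariate"`/`"multivariate"`), `hr`, `lcl`, `ucl`, `p_value`;
#'   reference levels have `hr = 1` and `NA` elsewhere), `retained`
#'   (covariates kept in the multivariate model) and `fit` (the final
#'   multivariate [survival::coxph()] fit, or `NULL` when no covariate
#'   passed screening).
#' @export
cox_models <- function(data, time, event, covariates = names(data),
                       alpha = 0.05) {
  stopifnot(nrow(data) == length(time), sum(event) >= 10L)
  y <- survival::Surv(time, event)
  rows <- list()
  uni_p <- setNames(numeric(length(covariates)), covariates)
  for (v in covariates) {
    fit <- tryCatch(
      survival::coxph(y ~ x, data = data.frame(x = data[[v]])),
      error = function(e) NULL)
    if (is.null(fit)) {
      uni_p[v] <- NA_real_
      warning("univariate Cox fit failed for '", v, "'", call. = FALSE)
      next
    }
    uni_p[v] <- .lrt_p(fit)
    rows[[v]] <- .cox_rows(fit, v, data[[v]], "univariate")
  }
  keep <- covariates[!is.na(uni_p) & uni_p < alpha]
  retained <- keep
  final_fit <- NULL
  while (length(retained) > 0L) {
    df <- data[, retained, drop = FALSE]
    final_fit <- survival::coxph(
      stats::as.formula(paste("y ~", paste(retained, collapse = " + "))),
      data = cbind(df, y = y))
    term_p <- vapply(retained, function(v) {
      reduced <- setdiff(retained, v)
      f0 <- if (length(reduced) == 0L) survival::coxph(y ~ 1) else
        survival::coxph(
          stats::as.formula(paste("y ~", paste(reduced, collapse = " + "))),
          data = cbind(data[, reduced, drop = FALSE], y = y))
      lrt <- 2 * (final_fit$loglik[2L] - f0$loglik[length(f0$loglik)])
      df_v <- length(coef(final_fit)) -
        (if (length(reduced) == 0L) 0L else length(coef(f0)))
      pchisq(lrt, df = df_v, lower.tail = FALSE)
    }, numeric(1L))
    if (all(term_p < alpha)) break
    retained <- setdiff(retained, retained[which.max(term_p)])
    final_fit <- NULL
  }
  if (length(retained) > 0L && is.null(final_fit)) {
    final_fit <- survival::coxph(
      stats::as.formula(paste("y ~", paste(retained, collapse = " + "))),
      data = cbind(data[, retained, drop = FALSE], y = y))
  }
  if (!is.null(final_fit)) {
    for (v in retained) {
      rows[[paste0(v, ".multi")]] <-
        .cox_multi_rows(final_fit, v, data[[v]])
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, retained = retained, fit = final_fit)
}

# Table rows (HR, CI, p per level) for one univariate fit.
.cox_rows <- function(fit, variable, values, model) {
  s <- summary(fit)
  if (is.factor(values)) {
    lev <- levels(values)
    ref <- data.frame(variable = variable, level = lev[1L], model = model,
                      hr = 1, lcl = NA_real_, ucl = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    est <- data.frame(variable = variable, level = lev[-1L], model = model,
                      hr = unname(s$conf.int[, "exp(coef)"]),
                      lcl = unname(s$conf.int[, "lower .95"]),
                      ucl = unname(s$conf.int[, "upper .95"]),
                      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
    rbind(ref, est)
  } else {
    data.frame(variable = variable, level = "", model = model,
               hr = unname(s$conf.int[1L, "exp(coef)"]),
               lcl = unname(s$conf.int[1L, "lower .95"]),
               ucl = unname(s$conf.int[1L, "upper .95"]),
               p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }
}

# Rows for one covariate inside the final multivariate fit.
.cox_multi_rows <- function(fit, variable, values) {
  s <- summary(fit)
  cn <- rownames(s$coefficients)
  if (is.factor(values)) {
    lev <- levels(values)
    pick <- paste0(variable, lev[-1L])
    ref <- data.frame(variable = variable, level = lev[1L],
                      model = "multivariate", hr = 1, lcl = NA_real_,
                      ucl = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    est <- data.frame(variable = variable, level = lev[-1L],
                      model = "multivariate",
                      hr = unname(s$conf.int[match(pick, cn), "exp(coef)"]),
                      lcl = unname(s$conf.int[match(pick, cn), "lower .95"]),
                      ucl = unname(s$conf.int[match(pick, cn), "upper .95"]),
                      p_value = unname(
                        s$coefficients[match(pick, cn), "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
    rbind(ref, est)
  } else {
    data.frame(variable = variable, level = "", model = "multivariate",
               hr = unname(s$conf.int[match(variable, cn), "exp(coef)"]),
               lcl = unname(s$conf.int[match(variable, cn), "lower .95"]),
               ucl = unname(s$conf.int[match(variable, cn), "upper .95"]),
               p_value = unname(
                 s$coefficients[match(variable, cn), "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }
}

#' Time-dependent ROC AUC with censoring weighting
#'
#' Cumulative-case / dynamic-control AUC of a risk score at fixed
#' horizons, with inverse-probability-of-censoring weighting (IPCW):
#' cases are patients with an observed event by the horizon, controls
#' are patients still event-free at the horizon; case weights are
#' `1/G(T_i-)` and control weights `1/G(t)`, where `G` is the
#' Kaplan-Meier estimate of the censoring distribution. With no
#' censoring this reduces to the empirical AUC.
#'
#' @param score Numeric risk score (higher = higher risk).
#' @param time,event DFS outcome.
#' @param horizons Evaluation times in months (default 12, 36, 60).
#' @return `data.frame`: `horizon`, `auc`, `n_cases`, `n_controls`.
#'   `auc` is `NA` when a horizon has no cases or no controls, or lies
#'   beyond follow-up.
#' @export
time_dependent_auc <- function(score, time, event,
                               horizons = c(12, 36, 60)) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  ok <- is.finite(score) & is.finite(time)
  score <- score[ok]; time <- time[ok]; event <- event[ok]
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  # G evaluated just before t: left-continuous version of the KM step.
  G_minus <- function(t) {
    vapply(t, function(ti) {
      prior <- cens_fit$time < ti
      if (!any(prior)) 1 else cens_fit$surv[max(which(prior))]
    }, numeric(1L))
  }
  out <- lapply(horizons, function(h) {
    is_case <- time <= h & event == 1
    is_ctrl <- time > h
    n_cases <- sum(is_case); n_ctrl <- sum(is_ctrl)
    if (n_cases == 0L || n_ctrl == 0L) {
      return(data.frame(horizon = h, auc = NA_real_,
                        n_cases = n_cases, n_controls = n_ctrl))
    }
    w_case <- 1 / pmax(G_minus(time[is_case]), .Machine$double.eps)
    g_h <- max(G(h), .Machine$double.eps)
    w_ctrl <- rep(1 / g_h, n_ctrl)
    sc <- score[is_case]; st <- score[is_ctrl]
    # weighted P(case score > control score) + 0.5 * ties
    cmp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
    wmat <- outer(w_case, w_ctrl)
    data.frame(horizon = h, auc = sum(cmp * wmat) / sum(wmat),
               n_cases = n_cases, n_controls = n_ctrl)
  })
  do.call(rbind, out)
}

#' Combined signature + stage prognostic model
#'
#' Fits a Cox model of DFS on the SIS risk group and tumor stage
#' jointly, uses its linear predictor as a combined risk score, and
#' reports time-dependent AUCs for the combined score alongside the
#' stage-only and SIS-only scores.
#'
#' @param sis_group Factor/character `"low"`/`"high"` SIS group (or a
#'   numeric SIS score).
#' @param stage Factor of tumor stage (reference = first level).
#' @param time,event DFS outcome.
#' @param horizons Evaluation horizons in months.
#' @return List: `fit` (the joint [survival::coxph()]), `auc`
#'   (`data.frame` with `model` in
#'   `"combined"`/`"stage_only"`/`"sis_only"`, `horizon`, `auc`).
#' @export
combined_model <- function(sis_group, stage, time, event,
                           horizons = c(12, 36, 60)) {
  if (!is.numeric(sis_group)) {
    sis_group <- factor(sis_group, levels = c("low", "high"))
  }
  stage <- droplevels(factor(stage))
  y <- survival::Surv(time, event)
  df <- data.frame(sis = sis_group, stage = stage)
  fit <- survival::coxph(y ~ sis + stage, data = df)
  lp_combined <- predict(fit, type = "lp")
  lp_stage <- predict(survival::coxph(y ~ stage, data = df), type = "lp")
  lp_sis <- predict(survival::coxph(y ~ sis, data = df), type = "lp")
  scores <- list(combined = lp_combined, stage_only = lp_stage,
                 sis_only = lp_sis)
  auc <- do.call(rbind, lapply(names(scores), function(nm) {
    a <- time_dependent_auc(scores[[nm]], time, event, horizons)
    cbind(model = nm, a, stringsAsFactors = FALSE)
  }))
  list(fit = fit, auc = auc)
}
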