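# Construction of the TRM-based spatial immune signature (TRM-SIS):
# train/test split, triple machine-learning importance ranking, top-10
# intersection, maximally selected log-rank cut-points, univariate-Cox
# weighting and patient scoring.
#
# Everything the model needs to score a new patient (imputation
# medians, standardization, cut-offs, weights, SIS threshold) is
# derived from the training set only.

#' Split a cohort into training and testing sets
#'
#' Random 7:3 split of patients, reproducible given `seed`. Reports
#' events per candidate variable (EPV) in the training set and warns
#' when the 10-EPV heuristic is not met.
#'
#' @param patient_ids Character vector of patient ids.
#' @param dfs_event 0/1 event indicator aligned with `patient_ids`.
#' @param seed Integer seed for the random assignment.
#' @param ratio Training fraction (default 0.7).
#' @param n_variables Number of candidate variables used in the EPV
#'   check (default: number of signature features eventually fitted is
#'   unknown here, so the check uses this argument when supplied).
#' @return A `data.frame` with columns `patient_id` and `set`
#'   (`"train"`/`"test"`); attribute `"epv"` carries the training
#'   events-per-variable when `n_variables` is given.
#' @examples
#' s <- split_cohort(sprintf("P%03d", 1:274), rbinom(274, 1, 0.4), seed = 1)
#' table(s$set)  # 192 train / 82 test
#' @export
split_cohort <- function(patient_ids, dfs_event, seed, ratio = 0.7,
                         n_variables = NULL) {
  stopifnot(length(patient_ids) == length(dfs_event),
            !anyDuplicated(patient_ids), length(patient_ids) >= 20L)
  n <- length(patient_ids)
  n_train <- as.integer(floor(n * ratio + 0.5))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_idx <- sample.int(n, n_train)
  set_lab <- rep("test", n)
  set_lab[train_idx] <- "train"
  out <- data.frame(patient_id = patient_ids, set = set_lab,
                    stringsAsFactors = FALSE)
  if (!is.null(n_variables)) {
    epv <- sum(dfs_event[train_idx]) / n_variables
    if (epv < 10) {
      warning(sprintf(
        "training set has %.1f events per variable (< 10 EPV)", epv),
        call. = FALSE)
    }
    attr(out, "epv") <- epv
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Training-set preprocessing: median imputation then standardization.
# Returns the transformed matrix plus the statistics needed to apply
# the identical transform to new data (no test-set leakage).
fit_preprocessor <- function(x) {
  x <- as.matrix(x)
  med <- apply(x, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0  # all-missing column
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(medians = med, center = ctr, scale = scl,
       x = sweep(sweep(x, 2L, ctr), 2L, scl, "/"))
}

apply_preprocessor <- function(prep, x) {
  x <- as.matrix(x)[, names(prep$medians), drop = FALSE]
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- prep$medians[j]
  sweep(sweep(x, 2L, prep$center), 2L, prep$scale, "/")
}

#' Rank feature importance for disease-free survival
#'
#' Ranks candidate features by one of three machine-learning methods,
#' all fitted on the survival outcome (DFS time + event):
#'
#' * `"lasso"` — penalized Cox regression ([glmnet::cv.glmnet()]),
#'   penalty chosen by tenfold cross-validation; importance is the
#'   absolute coefficient at the selected penalty.
#' * `"boosting"` — gradient boosting with the Cox partial-likelihood
#'   objective ([xgboost::xgb.train()]), refitted on `n_boot`
#'   bootstrap resamples; importance is the mean gain over resamples.
#' * `"random_forest"` — random survival forest ([ranger::ranger()])
#'   permutation importance.
#'
#' Ties are broken by lexicographic feature name, so rankings are
#' stable and fully reproducible given `seed`.
#'
#' @param x Numeric feature matrix (patients x features), already
#'   imputed and standardized on the training set.
#' @param time,event DFS months and 0/1 event indicator.
#' @param method One of `"lasso"`, `"boosting"`, `"random_forest"`.
#' @param seed Integer seed.
#' @param n_boot Bootstrap refits for `"boosting"` (default 1000).
#' @param top_k Length of the reported head of the ranking.
#' @return A list of class `trm_ranking`: `method`, `scores` (named,
#'   full), `top10` (character, the `top_k` best).
#' @export
rank_importance <- function(x, time, event,
                            method = c("lasso", "boosting", "random_forest"),
                            seed = 1, n_boot = 1000, top_k = 10) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event),
            !is.null(colnames(x)), !any(is.na(x)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  constant <- apply(x, 2L, function(v) var(v) == 0)
  if (any(constant)) {
    message("rank_importance: ", sum(constant),
            " constant feature(s) assigned importance 0")
  }
  xa <- x[, !constant, drop = FALSE]
  scores_active <- switch(method,
    lasso = {
      y <- survival::Surv(time, event)
      cv <- glmnet::cv.glmnet(xa, y, family = "cox", nfolds = 10,
                              standardize = FALSE)
      b <- as.numeric(coef(cv, s = "lambda.min"))
      setNames(abs(b), colnames(xa))
    },
    boosting = {
      lab <- ifelse(event == 1, time, -time)
      acc <- setNames(numeric(ncol(xa)), colnames(xa))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(xa), replace = TRUE)
        if (sum(event[idx]) == 0L) next
        dm <- xgboost::xgb.DMatrix(xa[idx, , drop = FALSE],
                                   label = lab[idx], nthread = 1)
        bst <- xgboost::xgb.train(
          params = list(objective = "survival:cox", eta = 0.3,
                        max_depth = 3, nthread = 1),
          data = dm, nrounds = 30, verbose = 0)
        imp <- xgboost::xgb.importance(model = bst)
        if (!is.null(imp) && nrow(imp) > 0L) {
          acc[imp$Feature] <- acc[imp$Feature] + imp$Gain
        }
      }
      acc / n_boot
    },
    random_forest = {
      rf <- ranger::ranger(
        x = as.data.frame(xa), y = survival::Surv(time, event),
        importance = "permutation", num.trees = 500,
        num.threads = 1, seed = seed)
      rf$variable.importance[colnames(xa)]
    })
  scores <- setNames(numeric(ncol(x)), colnames(x))
  scores[names(scores_active)] <- scores_active
  ord <- order(-scores, names(scores))
  structure(list(method = method, scores = scores,
                 top10 = names(scores)[ord][seq_len(min(top_k, ncol(x)))]),
            class = "trm_ranking")
}

#' Intersect top-10 feature lists
#'
#' The features common to the top-10 lists of all three ranking
#' methods, ordered by mean rank across methods (best first).
#'
#' @param rankings List of exactly 3 `trm_ranking` objects.
#' @return Character vector of selected features.
#' @export
intersect_top10 <- function(rankings) {
  stopifnot(length(rankings) == 3L,
            all(vapply(rankings, inherits, logical(1L), "trm_ranking")))
  tops <- lapply(rankings, `[[`, "top10")
  sel <- Reduce(intersect, tops)
  if (length(sel) == 0L) {
    stop("the three top-10 lists share no feature; consider a larger ",
         "top-k or more data", call. = FALSE)
  }
  mean_rank <- vapply(sel, function(f) {
    mean(vapply(tops, function(t) match(f, t), numeric(1L)))
  }, numeric(1L))
  sel[order(mean_rank, sel)]
}

#' Maximally selected log-rank cut-point
#'
#' Finds the threshold that best separates survival when a continuous
#' feature is dichotomized: every observed feature value that leaves at
#' least `min_frac` of patients on each side is tried as a cut-point
#' (group = value > threshold), and the one maximizing the two-group
#' log-rank chi-square is returned (the smallest such threshold on
#' ties). This is the cut-point-search operation of the X-tile
#' procedure; no multiplicity correction is applied, so downstream
#' p-values at the chosen cut are optimistic.
#'
#' @param values Numeric feature values (no missing).
#' @param time,event Survival outcome.
#' @param min_frac Minimum fraction of patients on each side of the cut
#'   (default 0.10).
#' @return The threshold, with attributes `"statistic"` (log-rank
#'   chi-square) and `"n_candidates"`.
#' @export
find_cutoff <- function(values, time, event, min_frac = 0.10) {
  stopifnot(length(values) == length(time), !any(is.na(values)))
  n <- length(values)
  cand <- sort(unique(values))
  floor_n <- ceiling(min_frac * n)
  ok <- vapply(cand, function(t) {
    hi <- sum(values > t)
    hi >= floor_n && (n - hi) >= floor_n
  }, logical(1L))
  cand <- cand[ok]
  if (length(cand) == 0L) {
    stop("no cut-point leaves at least ", sprintf("%.0f%%", 100 * min_frac),
         " of patients on each side", call. = FALSE)
  }
  stat <- vapply(cand, function(t) {
    g <- factor(values > t, levels = c(FALSE, TRUE))
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sd$chisq
  }, numeric(1L))
  best <- which(stat == max(stat))[1L]  # cand is sorted: smallest wins ties
  structure(cand[best], statistic = stat[best], n_candidates = length(cand))
}

#' Fit the TRM spatial immune signature
#'
#' Builds the TRM-SIS on training data: each selected feature is
#' median-imputed, dichotomized at its maximally selected log-rank
#' cut-point, and weighted by the log hazard ratio `ln(HR)` of a
#' univariate Cox fit of DFS on the resulting indicator; the patient
#' score is `SIS = sum_i ln(HR_i) * X_i`, and the high/low SIS
#' threshold is found by applying the same cut-point search to the
#' training SIS values.
#'
#' Features whose univariate fit does not converge (e.g. no events on
#' one side of the cut) are dropped with a warning.
#'
#' @param features Training feature `data.frame` from
#'   [compute_feature_vectors()] (raw scale; imputation is internal).
#' @param time,event Training DFS outcome, aligned with `features`
#'   rows.
#' @param selected_features Feature names entering the signature
#'   (typically from [intersect_top10()]).
#' @param min_frac Group-size floor for cut-point searches.
#' @return An object of class `trm_sis`: `features` (retained names),
#'   `medians`, `cutoffs`, `weights` (ln HR), `hr` (hazard ratios),
#'   `sis_cutoff`.
#' @export
fit_signature <- function(features, time, event, selected_features,
                          min_frac = 0.10) {
  stopifnot(all(selected_features %in% names(features)),
            nrow(features) == length(time))
  medians <- vapply(selected_features, function(f) {
    median(features[[f]], na.rm = TRUE)
  }, numeric(1L))
  medians[!is.finite(medians)] <- 0
  cutoffs <- weights <- setNames(numeric(0L), character(0L))
  for (f in selected_features) {
    v <- features[[f]]
    v[is.na(v)] <- medians[[f]]
    cut <- tryCatch(find_cutoff(v, time, event, min_frac = min_frac),
                    error = function(e) NULL)
    if (is.null(cut)) {
      warning("signature: no admissible cut-point for '", f,
              "'; feature dropped", call. = FALSE)
      next
    }
    x <- as.numeric(v > cut)
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ x),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)) || abs(coef(fit)) > 10) {
      warning("signature: univariate Cox fit for '", f,
              "' did not converge; feature dropped", call. = FALSE)
      next
    }
    cutoffs[f] <- as.numeric(cut)
    weights[f] <- unname(coef(fit))
  }
  if (length(weights) == 0L) {
    stop("no selected feature yielded a convergent univariate Cox fit",
         call. = FALSE)
  }
  model <- structure(
    list(features = names(weights), medians = medians[names(weights)],
         cutoffs = cutoffs, weights = weights, hr = exp(weights),
         sis_cutoff = NA_real_, min_frac = min_frac),
    class = "trm_sis")
  sis <- score_patients(model, features)$sis
  model$sis_cutoff <- as.numeric(find_cutoff(sis, time, event,
                                             min_frac = min_frac))
  model
}

#' Score patients with a fitted signature
#'
#' Computes `SIS = sum_i ln(HR_i) * X_i`, where `X_i` indicates the
#' i-th selected feature exceeding its training cut-off; missing
#' feature values are imputed with training medians before
#' dichotomization. Patients with `SIS > sis_cutoff` form the
#' high-risk group.
#'
#' @param model A `trm_sis` from [fit_signature()].
#' @param features Feature `data.frame` for the patients to score.
#' @return A `data.frame`: `patient_id` (if present in `features`),
#'   `sis`, `risk_group` (`"high"`/`"low"`; `NA` until the model's SIS
#'   cut-off is set).
#' @export
score_patients <- function(model, features) {
  stopifnot(inherits(model, "trm_sis"))
  miss <- setdiff(model$features, names(features))
  if (length(miss) > 0L) {
    stop("features table lacks signature feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sis <- rep(0, nrow(features))
  for (f in model$features) {
    v <- features[[f]]
    v[is.na(v)] <- model$medians[[f]]
    sis <- sis + model$weights[[f]] * as.numeric(v > model$cutoffs[[f]])
  }
  out <- data.frame(sis = sis)
  if ("patient_id" %in% names(features)) {
    out <- cbind(patient_id = features$patient_id, out,
                 stringsAsFactors = FALSE)
  }
  out$risk_group <- if (is.na(model$sis_cutoff)) NA_character_ else
    ifelse(sis > model$sis_cutoff, "high", "low")
  out
}

#' @export
print.trm_sis <- function(x, ...) {
  cat("<trm_sis> ", length(x$features), " features, SIS cut-off ",
      format(x$sis_cutoff, digits = 4L), "\n", sep = "")
  print(data.frame(feature = x$features,
                   cutoff = unname(x$cutoffs),
                   HR = unname(round(x$hr, 3L)),
                   weight = unname(round(x$weights, 4L)),
                   row.names = NULL))
  invisible(x)
}

#' Save or load a fitted signature
#'
#' Serializes everything needed to re-score any cohort (selected
#' features, medians, cut-offs, ln(HR) weights, SIS cut-off and the
#' CCPS radius, if recorded) as JSON.
#'
#' @param model A `trm_sis`.
#' @param path JSON file path.
#' @param radius Optional CCPS radius (um) to record with the model.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the `trm_sis`.
#' @export
write_signature <- function(model, path, radius = NULL) {
  stopifnot(inherits(model, "trm_sis"))
  obj <- list(features = model$features,
              medians = as.list(model$medians),
              cutoffs = as.list(model$cutoffs),
              weights = as.list(model$weights),
              sis_cutoff = model$sis_cutoff,
              min_frac = model$min_frac,
              radius = radius)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(features = obj$features,
         medians = unlist(obj$medians)[obj$features],
         cutoffs = unlist(obj$cutoffs)[obj$features],
         weights = unlist(obj$weights)[obj$features],
         hr = exp(unlist(obj$weights)[obj$features]),
         sis_cutoff = obj$sis_cutoff,
         min_frac = obj$min_frac,
         radius = obj$radius),
    class = "trm_sis")
}

#' Run the full signature construction pipeline
#'
#' Convenience wrapper chaining the construction steps on a cohort's
#' feature table: 7:3 split, training-set imputation/standardization,
#' the three importance rankings, top-10 intersection, and
#' [fit_signature()] on the training set; test patients are scored
#' with the frozen model.
#'
#' @param features Feature `data.frame` from
#'   [compute_feature_vectors()].
#' @param clinical Clinical `data.frame` aligned by `patient_id`.
#' @param seed Integer seed controlling split and rankings.
#' @param n_boot Bootstrap refits for the boosting ranking.
#' @param top_k Ranking head size used for the intersection.
#' @return List: `split`, `rankings`, `selected`, `model`, `scores`
#'   (all patients, with `set` column).
#' @export
build_signature <- function(features, clinical, seed = 1, n_boot = 1000,
                            top_k = 10) {
  stopifnot(all(features$patient_id == clinical$patient_id))
  split <- split_cohort(clinical$patient_id, clinical$dfs_event, seed = seed,
                        n_variables = top_k)
  tr <- split$set == "train"
  fmat <- features[, setdiff(names(features), "patient_id"), drop = FALSE]
  prep <- fit_preprocessor(fmat[tr, , drop = FALSE])
  time_tr <- clinical$dfs_months[tr]
  ev_tr <- clinical$dfs_event[tr]
  rankings <- lapply(c("lasso", "boosting", "random_forest"), function(m) {
    rank_importance(prep$x, time_tr, ev_tr, method = m, seed = seed,
                    n_boot = n_boot, top_k = top_k)
  })
  selected <- intersect_top10(rankings)
  model <- fit_signature(features[tr, , drop = FALSE], time_tr, ev_tr,
                         selected_features = selected)
  scores <- score_patients(model, features)
  scores$set <- split$set
  list(split = split, rankings = rankings, selected = selected,
       model = model, scores = scores)
}
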