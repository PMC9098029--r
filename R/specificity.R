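#' Score labeled task-contrast maps with frozen decoders
#'
#' Standardizes each map like a training image (mean 0, SD 1 across
#' voxels) unless `standardize = FALSE`, then scores every map with every
#' frozen model via [apply_model()].
#'
#' @param models named list of `pcr_model`s from [train_final()].
#' @param task_maps list with `maps` (maps x voxels matrix over the full
#'   in-mask grid) and `info` (task, category, modality, participant_id,
#'   study_id per map), as from [simulate_specificity_maps()].
#' @param standardize per-map standardization flag (default TRUE, matching
#'   the training pipeline).
#' @return `task_score_table` data.frame: one row per map x model with
#'   `score`, `model`, task labels.
#' @export
score_task_maps <- function(models, task_maps, standardize = TRUE) {
  maps <- as.matrix(task_maps$maps)
  info <- task_maps$info
  stopifnot(nrow(maps) == nrow(info))
  if (standardize) {
    mu <- rowMeans(maps)
    sdv <- apply(maps, 1, sd)
    if (any(sdv < 1e-12)) stop("zero-variance task map cannot be standardized")
    maps <- (maps - mu) / sdv
  }
  out <- do.call(rbind, lapply(names(models), function(nm) {
    s <- apply_model(models[[nm]], maps)
    cbind(info, data.frame(model = nm, score = s, stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  class(out) <- c("task_score_table", "data.frame")
  out
}

#' Specificity contrasts on a task-score table
#'
#' Mixed model of scores with random participant and task intercepts (maps
#' from one task share its idiosyncratic evoked pattern, so the task is
#' the exchangeable unit for the category contrasts) and three planned
#' contrasts: pain minus non-pain; heat minus the mean of mechanical and
#' visceral (pain rows only); and the (distributed model minus local
#' model) x (pain minus non-pain) interaction. Also runs per-task
#' one-sample t tests with a Sidak correction across tasks.
#'
#' @param table a `task_score_table`.
#' @param distributed_models model names counted as distributed (default
#'   PATHWAYS, META, FULL; the rest are local).
#' @param alpha level for the per-task tests.
#' @return list with `contrasts` (estimate, se, t, df, p per contrast)
#'   and `per_task` test table.
#' @export
specificity_contrasts <- function(table,
                                  distributed_models = c("PATHWAYS", "META", "FULL"),
                                  alpha = 0.05) {
  d <- as.data.frame(table)
  d$c_pain <- ifelse(d$category == "pain", 0.5, -0.5)
  d$c_dist <- ifelse(d$model %in% distributed_models, 0.5, -0.5)
  d$participant <- d$participant_id
  re <- if (anyDuplicated(d$participant))
    "(1 | participant) + (1 | task)" else "(1 | task)"
  fit <- lmer_quiet(as.formula(paste("score ~ c_pain * c_dist +", re)), d)
  sm <- summary(fit)$coefficients
  pick <- function(nm) {
    if (!nm %in% rownames(sm))   # constant code (e.g. a single model class)
      return(data.frame(contrast = nm, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    tv <- sm[nm, "t value"]; df <- sm[nm, "df"]
    data.frame(contrast = nm, estimate = sm[nm, "Estimate"],
               se = sm[nm, "Std. Error"], t = tv, df = df,
               p = 2 * pt(-abs(tv), df), stringsAsFactors = FALSE)
  }
  rows <- rbind(pick("c_pain"), pick("c_pain:c_dist"))
  rows$contrast <- c("pain_vs_nonpain", "distributed_x_pain")
  pain <- d[d$category == "pain" & !is.na(d$modality), ]
  if (nrow(pain) && length(unique(pain$modality)) > 1L &&
      "heat" %in% pain$modality) {
    pain$c_heat <- ifelse(pain$modality == "heat", 2 / 3, -1 / 3)
    re_h <- if (anyDuplicated(pain$participant))
      "(1 | participant) + (1 | task)" else "(1 | task)"
    fit_h <- lmer_quiet(as.formula(paste("score ~ c_heat +", re_h)), pain)
    smh <- summary(fit_h)$coefficients
    tv <- smh["c_heat", "t value"]; df <- smh["c_heat", "df"]
    rows <- rbind(rows, data.frame(
      contrast = "heat_vs_other_pain", estimate = smh["c_heat", "Estimate"],
      se = smh["c_heat", "Std. Error"], t = tv, df = df,
      p = 2 * pt(-abs(tv), df), stringsAsFactors = FALSE))
  }
  tasks <- unique(d$task)
  thr <- sidak_alpha(alpha, length(tasks))
  per_task <- do.call(rbind, lapply(tasks, function(tk) {
    s <- d$score[d$task == tk]
    tt <- t.test(s)
    data.frame(task = tk, category = d$category[d$task == tk][1],
               mean_score = mean(s), p = tt$p.value,
               significant = tt$p.value < thr, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- rownames(per_task) <- NULL
  list(contrasts = rows, per_task = per_task, sidak_threshold = thr)
}

#' Optimal cut point balancing sensitivity and specificity
#'
#' Scans midpoints of sorted unique scores (plus outer guards) for the
#' threshold minimizing `|sensitivity - specificity|`, breaking ties by
#' maximizing `sensitivity + specificity`. Scores at or above the
#' threshold are called positive.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/TRUE = positive class).
#' @return list: `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutpoint <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (thr in cand) {
    sens <- mean(scores[labels] >= thr)
    spec <- mean(scores[!labels] < thr)
    key <- c(abs(sens - spec), -(sens + spec))
    if (is.null(best) || key[1] < best$key[1] - 1e-12 ||
        (abs(key[1] - best$key[1]) <= 1e-12 && key[2] < best$key[2] - 1e-12)) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   key = key)
    }
  }
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity,
       youden = best$sensitivity + best$specificity - 1)
}

#' Per-model pain discrimination summary
#'
#' Computes each model's optimal cut point for discriminating pain from
#' non-pain task maps and reports sensitivity and specificity there.
#'
#' @param table a `task_score_table`.
#' @return data.frame per model: threshold, sensitivity, specificity.
#' @export
pain_discrimination <- function(table) {
  d <- as.data.frame(table)
  out <- do.call(rbind, lapply(unique(d$model), function(nm) {
    s <- d[d$model == nm, ]
    cp <- optimal_cutpoint(s$score, s$category == "pain")
    data.frame(model = nm, threshold = cp$threshold,
               sensitivity = cp$sensitivity, specificity = cp$specificity,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
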