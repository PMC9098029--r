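#' Fisher z transform with boundary clipping
#'
#' @param r Pearson correlation(s); `|r|` is clipped at `1 - 1e-6` before
#'   `atanh` so four-point correlations of exactly 1 stay finite.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6))

#' Per-participant decoding performance
#'
#' Averages cross-validated predictions over the CV repeats, computes the
#' within-participant Pearson correlation between predicted and observed
#' ratings, and Fisher-z transforms it. Participants with zero-variance
#' predictions get `NA` and are logged.
#'
#' @param predset a `prediction_set` from [nested_cv_predict()].
#' @return `performance_table` data.frame: `participant`, `study`, `r`,
#'   `z`, `n_points`.
#' @export
participant_performance <- function(predset) {
  avg <- aggregate(cbind(predicted, observed) ~ row + participant + study,
                   data = predset, FUN = mean)
  out <- do.call(rbind, lapply(split(avg, avg$participant), function(d) {
    if (nrow(d) < 3L || sd(d$predicted) < 1e-12 || sd(d$observed) < 1e-12) {
      data.frame(participant = d$participant[1], study = d$study[1],
                 r = NA_real_, z = NA_real_, n_points = nrow(d),
                 stringsAsFactors = FALSE)
    } else {
      r <- cor(d$predicted, d$observed)
      data.frame(participant = d$participant[1], study = d$study[1],
                 r = r, z = fisher_z(r), n_points = nrow(d),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  if (anyNA(out$z))
    message(sprintf("participant_performance: %d participant(s) with undefined r (logged as NA)",
                    sum(is.na(out$z))))
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Sidak-adjusted per-test alpha
#' @param alpha family-wise level.
#' @param m number of tests in the family.
#' @return Per-test threshold `1 - (1 - alpha)^(1/m)`.
#' @export
sidak_alpha <- function(alpha, m) 1 - (1 - alpha)^(1 / m)

lmer_quiet <- function(formula, data, REML = TRUE) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  suppressWarnings(suppressMessages(
    lmerTest::lmer(formula, data = data, REML = REML, control = ctrl)))
}

# Fit z ~ fixed + (1|participant) + (fixed | study) stepping down a ladder
# of random-slope structures: correlated slopes (attempted only when the
# number of studies can identify the covariance), then independent
# (diagonal) slopes, then study intercept only. A diagonal fit with some
# slope variances estimated at the zero boundary is accepted: boundary
# estimates are expected with few studies and dropping the slopes entirely
# would discard real study-by-contrast heterogeneity and inflate type-I
# error.
fit_slope_ladder <- function(data, fixed_terms, REML = TRUE, slopes = TRUE) {
  rhs <- paste(fixed_terms, collapse = " + ")
  q <- length(fixed_terms) + 1L
  n_study <- length(unique(data$study))
  forms <- c(
    full = sprintf("z ~ %s + (1 | participant) + (%s | study)", rhs, rhs),
    diagonal = sprintf("z ~ %s + (1 | participant) + (%s || study)", rhs, rhs),
    intercept = sprintf("z ~ %s + (1 | participant) + (1 | study)", rhs))
  if (!slopes) {
    fit <- lmer_quiet(as.formula(forms["intercept"]), data, REML = REML)
    return(list(fit = fit, structure = "intercept", reduced = TRUE))
  }
  try_full <- n_study > q * (q + 1) / 2
  if (try_full) {
    fit <- tryCatch(lmer_quiet(as.formula(forms["full"]), data, REML = REML),
                    error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4))
      return(list(fit = fit, structure = "full", reduced = FALSE))
  }
  fit <- tryCatch(lmer_quiet(as.formula(forms["diagonal"]), data, REML = REML),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    singular <- lme4::isSingular(fit, tol = 1e-4)
    return(list(fit = fit,
                structure = if (singular) "diagonal-boundary" else "diagonal",
                reduced = TRUE))
  }
  fit <- tryCatch(lmer_quiet(as.formula(forms["intercept"]), data, REML = REML),
                  error = function(e) NULL)
  if (is.null(fit)) stop("mixed model failed to fit under every random-effect structure")
  list(fit = fit, structure = "intercept", reduced = TRUE)
}

#' Default planned orthogonal contrasts over the six model spaces
#'
#' C1: distributed (PATHWAYS, META, FULL) minus modular (REGION, FRSN,
#' CRSN); C2: REGION minus networks; C3: CRSN minus FRSN; C4: META minus
#' PATHWAYS; C5: FULL minus the two multisystem masks. The five rows are
#' pairwise orthogonal.
#'
#' @return 5 x 6 numeric matrix, rows = contrasts, columns = spaces.
#' @export
planned_contrasts <- function() {
  spaces <- c("REGION", "FRSN", "CRSN", "PATHWAYS", "META", "FULL")
  L <- rbind(
    C1 = c(-1, -1, -1, 1, 1, 1) / 3,
    C2 = c(1, -0.5, -0.5, 0, 0, 0),
    C3 = c(0, -1, 1, 0, 0, 0),
    C4 = c(0, 0, 0, -1, 1, 0),
    C5 = c(0, 0, 0, -0.5, -0.5, 1))
  colnames(L) <- spaces
  L
}

contrast_codes <- function(space, L = planned_contrasts()) {
  spaces <- colnames(L)
  m <- length(spaces)
  Lfull <- rbind(intercept = rep(1 / m, m), L)
  if (nrow(Lfull) < m) {
    # complete a partial contrast set with an orthogonal complement so the
    # fixed part spans all group differences; extra codes are unreported
    Q <- qr.Q(qr(t(Lfull)), complete = TRUE)
    extra <- t(Q[, (nrow(Lfull) + 1):m, drop = FALSE])
    rownames(extra) <- paste0(".aux", seq_len(nrow(extra)))
    Lfull <- rbind(Lfull, extra)
  }
  B <- solve(Lfull)  # column k of B codes functional k: coefficient = contrast
  codes <- B[match(space, spaces), -1, drop = FALSE]
  colnames(codes) <- rownames(Lfull)[-1]
  as.data.frame(codes)
}

#' Compare model spaces with a mixed-effects model and planned contrasts
#'
#' Fits Fisher-z performance against the planned contrast codes with a
#' random participant intercept and random study intercepts and contrast
#' slopes (stepping down to diagonal slopes, then intercepts only, if the
#' fuller structures are singular). Each contrast coefficient estimates
#' the corresponding mean difference directly; F statistics use
#' Satterthwaite denominator degrees of freedom. The planned but
#' non-orthogonal FULL minus REGION comparison is fit separately on the
#' two spaces involved.
#'
#' @param perftable `performance_table` with columns `participant`,
#'   `study`, `space`, `z` covering the six spaces (or the subset named in
#'   `contrasts`).
#' @param contrasts contrast matrix (rows = named contrasts, columns =
#'   space names); defaults to [planned_contrasts()].
#' @param full_vs_region also fit the FULL minus REGION planned comparison.
#' @param random_slopes attempt random study slopes (default). With very
#'   few studies (two or three) the slope variances are unidentifiable and
#'   their boundary estimates make the denominator degrees of freedom
#'   erratic; set `FALSE` to use random intercepts only, with
#'   participant-level degrees of freedom.
#' @return `mixed_fit_result`: data.frame of estimates, SE, F, df, p per
#'   contrast, plus the fits and the random-effect structure used.
#' @export
compare_spaces <- function(perftable, contrasts = planned_contrasts(),
                           full_vs_region = TRUE, random_slopes = TRUE) {
  d <- as.data.frame(perftable)
  d <- d[!is.na(d$z) & d$space %in% colnames(contrasts), ]
  if (!all(colnames(contrasts) %in% d$space))
    stop("performance table does not cover every space in the contrast matrix")
  codes <- contrast_codes(d$space, contrasts)
  dat <- cbind(d, codes)
  terms <- colnames(codes)
  fit <- fit_slope_ladder(dat, terms, REML = TRUE, slopes = random_slopes)
  sm <- summary(fit$fit)$coefficients
  rows <- lapply(rownames(contrasts), function(tm) {
    est <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
    df <- sm[tm, "df"]; tv <- sm[tm, "t value"]
    data.frame(contrast = tm, estimate = est, se = se,
               F = tv^2, df1 = 1, df2 = df, t = tv,
               p = 2 * pt(-abs(tv), df), stringsAsFactors = FALSE)
  })
  extra <- NULL
  if (full_vs_region && all(c("FULL", "REGION") %in% d$space)) {
    sub <- d[d$space %in% c("FULL", "REGION"), ]
    sub$FULLvsREGION <- ifelse(sub$space == "FULL", 0.5, -0.5)
    f2 <- fit_slope_ladder(sub, "FULLvsREGION", REML = TRUE, slopes = random_slopes)
    sm2 <- summary(f2$fit)$coefficients
    tv <- sm2["FULLvsREGION", "t value"]; df <- sm2["FULLvsREGION", "df"]
    rows <- c(rows, list(data.frame(
      contrast = "FULL_vs_REGION", estimate = sm2["FULLvsREGION", "Estimate"],
      se = sm2["FULLvsREGION", "Std. Error"], F = tv^2, df1 = 1, df2 = df,
      t = tv, p = 2 * pt(-abs(tv), df), stringsAsFactors = FALSE)))
    extra <- f2
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(table = res, fit = fit$fit, structure = fit$structure,
                 reduced = fit$reduced, fit_full_vs_region = extra$fit,
                 varcor = as.data.frame(lme4::VarCorr(fit$fit)),
                 data = dat, contrasts = contrasts),
            class = "mixed_fit_result")
}

#' @export
print.mixed_fit_result <- function(x, ...) {
  cat(sprintf("<mixed_fit_result> random-effect structure: %s\n", x$structure))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Screen candidate modules for significant decoding
#'
#' For every module's cross-validated prediction set, fits a mixed model
#' of observed on predicted ratings with random participant and study
#' intercepts and slopes, and flags modules significant at the
#' Sidak-adjusted level for the number of modules tested at that scale.
#'
#' @param predsets named list of `prediction_set`s, one per module.
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame per module: slope estimate, p, Sidak threshold,
#'   significance flag, mean z and SEM across participants, and a fallback
#'   flag when random slopes had to be dropped.
#' @export
screen_modules <- function(predsets, alpha = 0.05) {
  m <- length(predsets)
  thr <- sidak_alpha(alpha, m)
  out <- lapply(names(predsets) %||% as.character(seq_len(m)), function(nm) {
    ps <- predsets[[nm]]
    d <- aggregate(cbind(predicted, observed) ~ row + participant + study,
                   data = ps, FUN = mean)
    forms <- c("observed ~ predicted + (predicted | participant) + (predicted | study)",
               "observed ~ predicted + (1 | participant) + (1 | study)")
    fit <- NULL; fb <- FALSE
    for (i in seq_along(forms)) {
      fit <- tryCatch(lmer_quiet(as.formula(forms[i]), d), error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) { fb <- i > 1; break }
    }
    if (is.null(fit)) fit <- lmer_quiet(as.formula(forms[2]), d)
    sm <- summary(fit)$coefficients
    pv <- if ("predicted" %in% rownames(sm))
      2 * pt(-abs(sm["predicted", "t value"]), sm["predicted", "df"]) else NA_real_
    pf <- participant_performance(ps)
    data.frame(module = nm, estimate = sm["predicted", "Estimate"],
               p = pv, sidak_threshold = thr, significant = !is.na(pv) && pv < thr,
               mean_z = mean(pf$z, na.rm = TRUE),
               sem_z = sd(pf$z, na.rm = TRUE) / sqrt(sum(!is.na(pf$z))),
               fallback = fb, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bayes factor for the null of one contrast
#'
#' BIC-approximated Bayes factor comparing the mixed model with versus
#' without the named fixed contrast (both fit by maximum likelihood);
#' `BF01 > 10` is reported as a confirmed null.
#'
#' @param perftable performance table as in [compare_spaces()].
#' @param contrast name of the contrast (row of `contrasts`).
#' @param contrasts contrast matrix, default [planned_contrasts()].
#' @return BF01 (evidence for the null), with the two BICs as attributes.
#' @export
bayes_factor_null <- function(perftable, contrast,
                              contrasts = planned_contrasts()) {
  d <- as.data.frame(perftable)
  d <- d[!is.na(d$z) & d$space %in% colnames(contrasts), ]
  codes <- contrast_codes(d$space, contrasts)
  dat <- cbind(d, codes)
  terms <- colnames(codes)
  if (!contrast %in% terms) stop("unknown contrast: ", contrast)
  fit_full <- fit_slope_ladder(dat, terms, REML = FALSE)
  # null model: same random-effect structure, contrast removed from fixed part
  rhs_re <- switch(gsub("-(singular|boundary)", "", fit_full$structure),
    full = sprintf("(1 | participant) + (%s | study)", paste(terms, collapse = " + ")),
    diagonal = sprintf("(1 | participant) + (%s || study)", paste(terms, collapse = " + ")),
    intercept = "(1 | participant) + (1 | study)")
  rhs0 <- paste(setdiff(terms, contrast), collapse = " + ")
  if (rhs0 == "") rhs0 <- "1"
  fit_null <- lmer_quiet(as.formula(sprintf("z ~ %s + %s", rhs0, rhs_re)),
                         dat, REML = FALSE)
  b1 <- BIC(fit_full$fit); b0 <- BIC(fit_null)
  structure(exp((b1 - b0) / 2), BIC_full = b1, BIC_null = b0)
}

#' Calibration of performance estimates against holdout studies
#'
#' For each space, fits an intercept-plus-random-study-intercept model to
#' the training performance table and forms a 95 percent predictive
#' interval for the observed mean z of a new study:
#' `estimate +/- t * sqrt(SE^2 + var_study + (var_residual)/m)` with
#' `m` the holdout study's participant count (the last term covers the
#' sampling noise of the observed holdout mean; the residual variance here
#' includes participant scatter). Reports whether each holdout study mean
#' falls inside.
#'
#' @param train_perf training `performance_table` (columns participant,
#'   study, space, z).
#' @param holdout_perf holdout performance table from studies never used
#'   in fitting.
#' @param level interval level, default 0.95.
#' @return data.frame per space x holdout study: observed mean, interval,
#'   covered flag.
#' @export
calibration_check <- function(train_perf, holdout_perf, level = 0.95) {
  spaces <- intersect(unique(train_perf$space), unique(holdout_perf$space))
  out <- list(); at <- 1L
  for (sp in spaces) {
    tr <- train_perf[train_perf$space == sp & !is.na(train_perf$z), ]
    n_st <- length(unique(tr$study))
    fit <- lmer_quiet(z ~ 1 + (1 | study), tr)
    sm <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_study <- vc$vcov[vc$grp == "study"][1] %||% 0
    v_resid <- vc$vcov[vc$grp == "Residual"][1]
    if (is.na(v_study)) stop("missing study variance component")
    tq <- qt(1 - (1 - level) / 2, df = max(n_st - 1, 1))
    ho <- holdout_perf[holdout_perf$space == sp & !is.na(holdout_perf$z), ]
    for (s in unique(ho$study)) {
      zz <- ho$z[ho$study == s]
      m <- length(zz)
      half <- tq * sqrt(sm[1, "Std. Error"]^2 + v_study + v_resid / m)
      lo <- sm[1, "Estimate"] - half; hi <- sm[1, "Estimate"] + half
      out[[at]] <- data.frame(space = sp, study = s, observed = mean(zz),
                              lower = lo, upper = hi,
                              covered = mean(zz) >= lo && mean(zz) <= hi,
                              stringsAsFactors = FALSE)
      at <- at + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
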