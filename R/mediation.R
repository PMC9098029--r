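#' Within-participant mediation of experimental factors via brain scores
#'
#' Removes participant fixed effects (participant means) from every
#' variable, then fits the two least-squares path models jointly over all
#' factors: path a regresses the mediator (brain-model prediction) on all
#' factors; paths b and tau regress the outcome on the mediator plus all
#' factors. The indirect effect per factor is `a_f * b`; the total effect
#' identity `total = tau + a*b` holds exactly because both models use the
#' same rows. Confidence intervals come from a bias-corrected percentile
#' bootstrap that resamples participants (clusters) with replacement.
#'
#' Factors should be standardized by the caller if standardized path
#' coefficients are wanted; the function does not rescale inputs.
#'
#' @param factors numeric matrix or data.frame of factor values (columns
#'   named).
#' @param mediator numeric vector of brain-model scores.
#' @param outcome numeric vector of (z-scored) pain ratings.
#' @param participant_id participant labels, >= 2 rows each.
#' @param n_boot bootstrap repetitions (default 5000).
#' @param seed integer seed.
#' @param level CI level (default 0.95).
#' @return `mediation_result`: per-factor table of alpha, beta, tau,
#'   indirect, total, percent mediated, bias-corrected CIs, partial r2 for
#'   every path-b predictor, the mediator's partial r2, and an R2
#'   decomposition of the outcome model.
#' @export
mediate <- function(factors, mediator, outcome, participant_id,
                    n_boot = 5000L, seed = 1L, level = 0.95) {
  Xf <- as.matrix(factors)
  if (is.null(colnames(Xf))) colnames(Xf) <- paste0("f", seq_len(ncol(Xf)))
  n <- nrow(Xf)
  stopifnot(length(mediator) == n, length(outcome) == n,
            length(participant_id) == n)
  if (sd(mediator) < 1e-12) stop("constant mediator")
  tab <- table(participant_id)
  if (any(tab < 2L)) stop("every participant needs at least 2 rows")
  if (length(tab) < 10L)
    warning("fewer than 10 participants: bootstrap mediation tests are known to be underpowered at small sample sizes")
  demean <- function(v, g) v - stats::ave(v, g)
  paths_fn <- function(rows, ids) {
    Xd <- apply(Xf[rows, , drop = FALSE], 2, demean, g = ids)
    Md <- demean(mediator[rows], ids)
    Yd <- demean(outcome[rows], ids)
    a <- .lm.fit(cbind(1, Xd), Md)$coefficients[-1]
    fb <- .lm.fit(cbind(1, Md, Xd), Yd)$coefficients
    b <- fb[2]; tau <- fb[-(1:2)]
    c(a = a, b = b, tau = tau, ind = a * b)
  }
  est <- paths_fn(seq_len(n), participant_id)
  m <- ncol(Xf)
  idx_a <- seq_len(m); idx_b <- m + 1L; idx_tau <- m + 1L + seq_len(m)
  idx_ind <- 2L * m + 1L + seq_len(m)
  parts <- split(seq_len(n), participant_id)
  set.seed(derive_seed(seed, "mediation_boot"))
  boot <- matrix(NA_real_, n_boot, length(est))
  for (bi in seq_len(n_boot)) {
    pick <- sample.int(length(parts), length(parts), replace = TRUE)
    rows <- unlist(parts[pick], use.names = FALSE)
    ids <- rep(seq_along(pick), times = lengths(parts)[pick])
    boot[bi, ] <- tryCatch(paths_fn(rows, ids), error = function(e) rep(NA_real_, length(est)))
  }
  bc_ci <- function(th, bs) {
    bs <- bs[!is.na(bs)]
    if (!length(bs)) return(c(NA_real_, NA_real_))
    prop <- mean(bs < th) + 0.5 * mean(bs == th)
    prop <- min(max(prop, 1 / (length(bs) + 1)), length(bs) / (length(bs) + 1))
    z0 <- qnorm(prop)
    alph <- (1 - level) / 2
    lo <- pnorm(2 * z0 + qnorm(alph)); hi <- pnorm(2 * z0 + qnorm(1 - alph))
    as.numeric(quantile(bs, c(lo, hi), type = 6))
  }
  cis <- t(vapply(seq_along(est), function(j) bc_ci(est[j], boot[, j]),
                  numeric(2)))
  # partial r2 for every predictor of the outcome model (path b), on the
  # participant-demeaned data
  Xd <- apply(Xf, 2, demean, g = participant_id)
  Md <- demean(mediator, participant_id)
  Yd <- demean(outcome, participant_id)
  D <- cbind(mediator = Md, Xd)
  rss <- function(cols) {
    if (!length(cols)) sum((Yd - mean(Yd))^2) else
      sum(.lm.fit(cbind(1, D[, cols, drop = FALSE]), Yd)$residuals^2)
  }
  full_rss <- rss(seq_len(ncol(D)))
  partial_r2 <- vapply(seq_len(ncol(D)), function(j) {
    red <- rss(setdiff(seq_len(ncol(D)), j))
    (red - full_rss) / red
  }, 0)
  names(partial_r2) <- colnames(D)
  r2_model <- 1 - full_rss / sum((Yd - mean(Yd))^2)
  wedges <- r2_shapley(Yd, D)
  fac <- colnames(Xf)
  tbl <- data.frame(
    factor = fac,
    alpha = est[idx_a], alpha_lo = cis[idx_a, 1], alpha_hi = cis[idx_a, 2],
    beta = rep(est[idx_b], m),
    tau = est[idx_tau], tau_lo = cis[idx_tau, 1], tau_hi = cis[idx_tau, 2],
    indirect = est[idx_ind], indirect_lo = cis[idx_ind, 1],
    indirect_hi = cis[idx_ind, 2],
    total = est[idx_tau] + est[idx_ind],
    stringsAsFactors = FALSE)
  tbl$percent_mediated <- vapply(seq_len(m), function(j)
    percent_mediated_value(tbl$indirect[j], tbl$tau[j]), 0)
  structure(list(table = tbl, beta = est[idx_b],
                 beta_ci = cis[idx_b, ], partial_r2 = partial_r2,
                 r2_model = r2_model, r2_wedges = wedges,
                 n_boot = as.integer(n_boot),
                 n_participants = length(parts)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %d participants, %d bootstrap reps; mediator beta = %.3f [%.3f, %.3f]\n",
              x$n_participants, x$n_boot, x$beta, x$beta_ci[1], x$beta_ci[2]))
  print(format(x$table, digits = 3), row.names = FALSE)
  cat(sprintf("model R2 = %.3f\n", x$r2_model))
  invisible(x)
}

percent_mediated_value <- function(indirect, direct, tol = 1e-10) {
  total <- indirect + direct
  if (abs(total) < tol) return(NA_real_)
  round(100 * indirect / total)
}

#' Percent mediated per factor
#'
#' `100 * indirect / (indirect + direct)`, rounded to the nearest integer;
#' reported missing when the total effect is below tolerance.
#'
#' @param result a `mediation_result` from [mediate()].
#' @return Named numeric vector of percentages.
#' @export
percent_mediated <- function(result) {
  setNames(result$table$percent_mediated, result$table$factor)
}
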