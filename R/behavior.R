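# Shapley (LMG) decomposition of R2 over the columns of D for outcome y,
# optionally on top of a fixed baseline design (always-included columns).
# Shares are averages of R2 increments over all orderings, hence
# nonnegative, and sum exactly to R2(full) - R2(baseline).
r2_shapley <- function(y, D, baseline = NULL) {
  D <- as.matrix(D)
  m <- ncol(D)
  tss <- sum((y - mean(y))^2)
  r2_of <- function(cols) {
    Z <- cbind(1, baseline, D[, cols, drop = FALSE])
    1 - sum(.lm.fit(Z, y)$residuals^2) / tss
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  r2_cache <- apply(subsets, 1, function(s) r2_of(which(as.logical(s))))
  key <- function(s) sum(2^(which(s) - 1)) + 1
  shares <- numeric(m)
  for (j in seq_len(m)) {
    others <- setdiff(seq_len(m), j)
    for (sz in 0:length(others)) {
      combs <- if (sz == 0) list(integer(0)) else
        utils::combn(others, sz, simplify = FALSE)
      w <- factorial(sz) * factorial(m - sz - 1) / factorial(m)
      for (S in combs) {
        s0 <- logical(m); s0[S] <- TRUE
        s1 <- s0; s1[j] <- TRUE
        shares[j] <- shares[j] + w * (r2_cache[key(s1)] - r2_cache[key(s0)])
      }
    }
  }
  names(shares) <- colnames(D)
  shares
}

#' Backward stepwise selection of behavioral factors
#'
#' Models (quartiled, z-scored) pain report as a linear function of the
#' experimental factors with participant fixed effects always retained,
#' then iteratively drops the least significant factor with `p >= alpha`
#' and refits until every remaining factor is significant. Main effects
#' only; aliased (collinear) factors are dropped with a warning before
#' stepping.
#'
#' @param outcomes numeric outcome vector.
#' @param factors data.frame/matrix of candidate factors (may be empty).
#' @param participant_ids participant labels (fixed effects).
#' @param alpha retention threshold (default 0.05).
#' @return `stepwise_fit`: the final `lm` fit, retained/dropped factor
#'   names, and the data needed for [variance_partition()].
#' @export
stepwise_select <- function(outcomes, factors, participant_ids, alpha = 0.05) {
  Xf <- as.data.frame(factors)
  pid <- factor(participant_ids)
  keep <- names(Xf)
  dropped <- character(0)
  fit_model <- function(vars) {
    d <- data.frame(.y = outcomes, .pid = pid)
    for (v in vars) d[[v]] <- Xf[[v]]
    rhs <- paste(c(vars, ".pid"), collapse = " + ")
    if (!length(vars)) rhs <- ".pid"
    lm(as.formula(paste(".y ~", rhs)), data = d)
  }
  if (length(keep)) {
    fit <- fit_model(keep)
    aliased <- keep[keep %in% names(which(is.na(coef(fit))))]
    if (length(aliased)) {
      warning("dropping collinear factor(s) before stepping: ",
              paste(aliased, collapse = ", "))
      dropped <- c(dropped, aliased)
      keep <- setdiff(keep, aliased)
    }
  }
  repeat {
    fit <- fit_model(keep)
    if (!length(keep)) break
    sm <- summary(fit)$coefficients
    pv <- sm[keep, "Pr(>|t|)", drop = TRUE]
    worst <- which.max(pv)
    if (pv[worst] >= alpha) {
      dropped <- c(dropped, keep[worst])
      keep <- keep[-worst]
    } else break
  }
  structure(list(fit = fit, retained = keep, dropped = dropped,
                 outcomes = outcomes, factors = Xf,
                 participant_ids = pid, alpha = alpha),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> retained: %s; dropped: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
              if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Variance-wedge decomposition of a selected behavioral model
#'
#' Assigns the participant-effect block its R2 increment first (it enters
#' every ordering first), then attributes the remaining model R2 to the
#' retained factors by averaging R2 increments over all orderings of the
#' factors (Shapley / LMG). Shares are nonnegative and sum exactly to the
#' model R2.
#'
#' @param sel a `stepwise_fit` from [stepwise_select()].
#' @return `wedge_table` data.frame: one row per component (`participant`
#'   block plus each retained factor) with its variance share, plus the
#'   model R2 and residual share as attributes.
#' @export
variance_partition <- function(sel) {
  stopifnot(inherits(sel, "stepwise_fit"))
  y <- sel$outcomes
  P <- model.matrix(~ sel$participant_ids)[, -1, drop = FALSE]
  tss <- sum((y - mean(y))^2)
  r2_p <- 1 - sum(.lm.fit(cbind(1, P), y)$residuals^2) / tss
  vars <- sel$retained
  if (length(vars)) {
    D <- as.matrix(sel$factors[, vars, drop = FALSE])
    shares <- r2_shapley(y, D, baseline = P)
    r2_full <- 1 - sum(.lm.fit(cbind(1, P, D), y)$residuals^2) / tss
  } else {
    shares <- numeric(0)
    r2_full <- r2_p
  }
  tab <- data.frame(component = c("participant", vars),
                    share = c(r2_p, unname(shares)),
                    stringsAsFactors = FALSE)
  attr(tab, "r2_model") <- r2_full
  attr(tab, "residual_share") <- 1 - r2_full
  class(tab) <- c("wedge_table", "data.frame")
  tab
}

#' @export
print.wedge_table <- function(x, ...) {
  cat(sprintf("<wedge_table> model R2 = %.3f (residual %.3f)\n",
              attr(x, "r2_model"), attr(x, "residual_share")))
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Behavioral wedge analysis of a quartile dataset
#'
#' Convenience driver: runs [stepwise_select()] and [variance_partition()]
#' on a study's (or pooled) quartiled rows using the active factor
#' schemas. In the pooled analysis each factor is z-scored within the
#' studies that manipulated it and set to zero elsewhere (a study that did
#' not manipulate a factor contributes no variance for it).
#'
#' @param qdata a [quartile_dataset()].
#' @param study optional study id to subset to; default pools all rows.
#' @param alpha stepwise retention threshold.
#' @return A `wedge_table`.
#' @export
behavioral_wedges <- function(qdata, study = NULL, alpha = 0.05) {
  rows <- if (is.null(study)) seq_len(nrow(qdata$meta)) else
    which(qdata$meta$study == study)
  meta <- qdata$meta[rows, , drop = FALSE]
  schema <- if (is.null(study)) unique(unlist(qdata$factor_schema)) else
    qdata$factor_schema[[study]]
  fac <- meta[, intersect(schema, names(meta)), drop = FALSE]
  for (cl in names(fac)) {
    v <- fac[[cl]]
    for (s in unique(meta$study)) {
      ii <- which(meta$study == s)
      if (all(is.na(v[ii])) || sd(v[ii], na.rm = TRUE) == 0) {
        v[ii] <- 0
      } else {
        v[ii] <- as.vector(scale(v[ii]))
      }
    }
    fac[[cl]] <- v
  }
  fac <- fac[, vapply(fac, function(v) sd(v) > 0, TRUE), drop = FALSE]
  sel <- stepwise_select(meta$rating, fac, meta$participant_id, alpha = alpha)
  variance_partition(sel)
}
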