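#' Dimension-optimization settings
#'
#' @param method "grid" evaluates the inner-CV mean squared error at every
#'   admissible component count (deterministic); "bayes" explores the
#'   integer range with a Gaussian-process surrogate and expected-
#'   improvement acquisition, spending `n_evals` evaluations.
#' @param n_evals evaluation budget for the Bayesian mode (default 30).
#' @param k_cap optional upper bound on the component count searched
#'   (defaults to the training-matrix rank).
#' @return list of class `opt_config`.
#' @export
opt_config <- function(method = c("grid", "bayes"), n_evals = 30L, k_cap = Inf) {
  method <- match.arg(method)
  if (method == "bayes" && n_evals < 2) stop("n_evals must be at least 2")
  structure(list(method = method, n_evals = as.integer(n_evals), k_cap = k_cap),
            class = "opt_config")
}

# Economical PCA of a centered matrix: works on crossprod(X) when p <= n and
# on tcrossprod(X) otherwise. Returns singular values above the rank
# tolerance max(n,p) * eps * d1, training scores, and enough to project new
# rows and to back-project coefficients into voxel space.
pcr_decomp <- function(X) {
  n <- nrow(X); p <- ncol(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (p <= n) {
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    d <- sqrt(ev)
    keep <- d > max(n, p) * .Machine$double.eps * d[1]
    d <- d[keep]
    Vmat <- e$vectors[, keep, drop = FALSE]
    scores <- Xc %*% Vmat
    list(center = center, d = d, V = Vmat, scores = scores, Xc = Xc, wide = FALSE)
  } else {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    d <- sqrt(ev)
    keep <- d > max(n, p) * .Machine$double.eps * d[1]
    d <- d[keep]
    U <- e$vectors[, keep, drop = FALSE]
    scores <- sweep(U, 2, d, "*")
    list(center = center, d = d, U = U, scores = scores, Xc = Xc, wide = TRUE)
  }
}

pcr_test_scores <- function(dec, Xte) {
  Xte_c <- sweep(Xte, 2, dec$center)
  if (dec$wide) {
    (Xte_c %*% t(dec$Xc)) %*% sweep(dec$U, 2, dec$d, "/")
  } else {
    Xte_c %*% dec$V
  }
}

pcr_component_coefs <- function(dec, y) {
  yc <- y - mean(y)
  as.vector(crossprod(dec$scores, yc)) / dec$d^2
}

#' Fit a principal component regression decoder
#'
#' Computes the principal components of the column-centered feature matrix
#' (no column scaling: images are already standardized per trial) and
#' regresses the outcome on the first `k` component scores by ordinary
#' least squares, back-projecting the coefficients to a voxel weight
#' vector. Intercept-only models (`k = 0`) are precluded.
#'
#' @param X numeric matrix (rows = observations, columns = voxels).
#' @param y numeric outcome.
#' @param k number of components, `1 <= k <= rank(X)`.
#' @return Object of class `pcr_model` with fields `W` (voxel weights),
#'   `b0` (mean outcome), `center` (training column means), `k`.
#' @export
fit_pcr <- function(X, y, k) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (k < 1L) stop("k = 0 (intercept-only) models are precluded; k must be >= 1")
  dec <- pcr_decomp(X)
  r <- length(dec$d)
  if (k > r) stop(sprintf("k = %d exceeds the training-matrix rank %d", k, r))
  beta <- pcr_component_coefs(dec, y)[seq_len(k)]
  Vk <- if (dec$wide) {
    crossprod(dec$Xc, sweep(dec$U[, seq_len(k), drop = FALSE], 2,
                            dec$d[seq_len(k)], "/"))
  } else dec$V[, seq_len(k), drop = FALSE]
  W <- as.vector(Vk %*% beta)
  structure(list(W = W, b0 = mean(y), center = dec$center, k = as.integer(k),
                 d = dec$d, n_train = nrow(X)),
            class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model> k = %d components over %d voxels (n = %d)\n",
              x$k, length(x$W), x$n_train))
  if (!is.null(x$space_id))
    cat(sprintf("  space %s%s\n", x$space_id,
                if (!is.null(x$module)) paste0(", module ", x$module) else ""))
  invisible(x)
}

#' Predict from a fitted PCR model
#' @param object a [fit_pcr()] model.
#' @param newdata matrix with the same columns as the training matrix.
#' @param ... unused.
#' @return Numeric predictions: centered features times weights plus
#'   intercept.
#' @export
predict.pcr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$W)) stop("voxel-set mismatch")
  as.vector(sweep(newdata, 2, object$center) %*% object$W) + object$b0
}

#' Apply a frozen model to images
#'
#' Scores images with a trained decoder: centered dot product with the
#' weight map plus intercept, restricted to the model's voxel set. Accepts
#' a matrix over the model's voxel set, a matrix over the full in-mask
#' grid (columns are subset via the stored voxel set), or a
#' `quartile_dataset` / `study_dataset`.
#'
#' @param model a `pcr_model` from [train_final()] or [fit_pcr()].
#' @param images matrix or dataset; images must be standardized the same
#'   way as the training data (per-image mean 0, SD 1).
#' @return Numeric score per image.
#' @export
apply_model <- function(model, images) {
  X <- if (inherits(images, c("quartile_dataset", "study_dataset")))
    images$features else as.matrix(images)
  p <- length(model$W)
  if (ncol(X) == p) return(predict(model, X))
  if (!is.null(model$voxel_set) && ncol(X) == model$n_mask)
    return(predict(model, X[, model$voxel_set, drop = FALSE]))
  stop(sprintf("voxel-set mismatch: images have %d columns; model expects %d%s",
               ncol(X), p,
               if (!is.null(model$n_mask)) sprintf(" (or full mask %d)", model$n_mask) else ""))
}

# Inner-CV MSE for every component count 1..K in one pass: per fold one
# decomposition; component scores are orthogonal, so predictions for k
# components are the cumulative sum of per-component contributions.
cv_mse_curve <- function(X, y, foldid, k_cap = Inf) {
  folds <- sort(unique(foldid))
  K <- Inf
  sse <- NULL
  n_tot <- 0L
  for (f in folds) {
    te <- which(foldid == f); tr <- which(foldid != f)
    dec <- pcr_decomp(X[tr, , drop = FALSE])
    kf <- min(length(dec$d), k_cap)
    beta <- pcr_component_coefs(dec, y[tr])[seq_len(kf)]
    ste <- pcr_test_scores(dec, X[te, , drop = FALSE])[, seq_len(kf), drop = FALSE]
    contrib <- sweep(ste, 2, beta, "*")
    cum <- if (ncol(contrib) > 1L) t(apply(contrib, 1, cumsum)) else contrib
    err2 <- (matrix(y[te] - mean(y[tr]), nrow = length(te), ncol = kf) - cum)^2
    fold_sse <- colSums(err2)
    K <- min(K, kf)
    sse <- if (is.null(sse)) fold_sse[seq_len(K)] else
      sse[seq_len(K)] + fold_sse[seq_len(K)]
    n_tot <- n_tot + length(te)
  }
  sse[seq_len(K)] / n_tot
}

# Gaussian-process expected-improvement search over an integer grid,
# evaluating obj (a vectorless function of k) at most n_evals times.
bo_minimize_int <- function(obj, K, n_evals, seed) {
  set.seed(seed)
  xs <- unique(round(seq(1, K, length.out = min(4L, K, n_evals))))
  ys <- vapply(xs, obj, 0)
  ell <- max(K / 8, 1)
  while (length(xs) < min(n_evals, K)) {
    cand <- setdiff(seq_len(K), xs)
    mu_y <- mean(ys); sd_y <- max(sd(ys), 1e-12)
    yn <- (ys - mu_y) / sd_y
    Km <- exp(-outer(xs, xs, "-")^2 / (2 * ell^2)) + diag(1e-8, length(xs))
    Ks <- exp(-outer(cand, xs, "-")^2 / (2 * ell^2))
    L <- chol(Km)
    alpha <- backsolve(L, forwardsolve(t(L), yn))
    mu <- as.vector(Ks %*% alpha)
    vsolve <- forwardsolve(t(L), t(Ks))
    s2 <- pmax(1 - colSums(vsolve^2), 1e-12)
    s <- sqrt(s2)
    best <- min(yn)
    z <- (best - mu) / s
    ei <- (best - mu) * pnorm(z) + s * dnorm(z)
    pick <- cand[which.max(ei)]
    xs <- c(xs, pick); ys <- c(ys, obj(pick))
  }
  xs[which.min(ys)]
}

#' Choose the PCR dimensionality by inner cross-validation
#'
#' Searches component counts 1..R (R = training-matrix rank, optionally
#' capped) for the count minimizing inner-CV mean squared error, with
#' inner folds grouped by participant. `method = "grid"` scans the whole
#' range deterministically; `method = "bayes"` runs a seeded Gaussian-
#' process / expected-improvement search with `n_evals` evaluations.
#'
#' @param X,y training data.
#' @param foldid integer inner-fold assignment per row (participant-
#'   grouped).
#' @param opt an [opt_config()].
#' @param seed seed for the Bayesian search.
#' @return Chosen k, with the evaluated MSE values in `attr(, "mse")`.
#' @export
optimize_dims <- function(X, y, foldid, opt = opt_config(), seed = 1L) {
  curve <- cv_mse_curve(X, y, foldid, k_cap = opt$k_cap)
  K <- length(curve)
  if (K == 1L) return(structure(1L, mse = curve))
  k <- if (opt$method == "grid") which.min(curve) else
    bo_minimize_int(function(k) curve[k], K, opt$n_evals, seed)
  structure(as.integer(k), mse = curve)
}

# Participant-grouped, study-stratified fold assignment: shuffle each
# study's participants, deal round-robin to folds, rows inherit their
# participant's fold. Per study, fold sizes differ by at most one
# participant.
make_group_folds <- function(participant, study, n_folds, seed) {
  set.seed(seed)
  fold_of <- c()
  for (s in unique(study)) {
    ps <- sample(unique(participant[study == s]))
    fold_of[ps] <- rep_len(seq_len(n_folds), length(ps))
  }
  unname(fold_of[participant])
}

#' Repeated, participant-grouped, study-balanced CV scheme
#'
#' @param meta data.frame with `participant_id` and `study` columns.
#' @param repeats,folds scheme shape (default 2 x 5).
#' @param seed integer seed; each repeat uses a distinct sub-seed.
#' @return Matrix rows x repeats of fold ids, class `cv_scheme`.
#' @export
make_cv_scheme <- function(meta, repeats = 2L, folds = 5L, seed = 1L) {
  m <- vapply(seq_len(repeats), function(r)
    make_group_folds(meta$participant_id, meta$study, folds,
                     derive_seed(seed, paste0("cv_repeat_", r))),
    integer(nrow(meta)))
  structure(m, class = "cv_scheme", folds = as.integer(folds))
}

#' Exhaustive best-module selection by nested inner CV
#'
#' For every candidate module of a modular space, estimates inner-CV MSE
#' with a further innermost CV choosing the PCR dimensionality inside each
#' inner training set (three nesting levels in total when called from the
#' outer CV). Returns the index of the MSE-minimizing module; ties go to
#' the module with fewer voxels, then label order.
#'
#' @param qdata a [quartile_dataset()] (already subset to training rows).
#' @param space a modular [model_space()].
#' @param cfg an [analysis_config()].
#' @param seed integer seed (fold construction, Bayesian search).
#' @return Integer module index with per-module MSEs in `attr(, "mse")`.
#' @export
select_module <- function(qdata, space, cfg = analysis_config(), seed = 1L) {
  stopifnot(inherits(space, "model_space"))
  y <- qdata$meta$rating
  inner <- make_group_folds(qdata$meta$participant_id, qdata$meta$study,
                            cfg$inner_folds, derive_seed(seed, "module_inner"))
  mse <- rep(NA_real_, length(space$modules))
  for (i in seq_along(space$modules)) {
    X <- extract_features(qdata, space$modules[[i]])
    sse <- 0
    ok <- TRUE
    for (f in sort(unique(inner))) {
      tr <- which(inner != f); te <- which(inner == f)
      Xtr <- X[tr, , drop = FALSE]
      innermost <- make_group_folds(qdata$meta$participant_id[tr],
                                    qdata$meta$study[tr], cfg$innermost_folds,
                                    derive_seed(seed, paste0("innermost_", i, "_", f)))
      k <- tryCatch(optimize_dims(Xtr, y[tr], innermost, cfg$opt,
                                  derive_seed(seed, paste0("bo_", i, "_", f))),
                    error = function(e) NA_integer_)
      if (is.na(k)) { ok <- FALSE; break }
      fit <- fit_pcr(Xtr, y[tr], k)
      sse <- sse + sum((y[te] - predict(fit, X[te, , drop = FALSE]))^2)
    }
    if (ok) mse[i] <- sse / length(y)
  }
  if (all(is.na(mse))) stop("all candidate modules degenerate")
  best <- which(mse <= min(mse, na.rm = TRUE) + 1e-12)
  if (length(best) > 1L) {
    sizes <- vapply(space$modules[best], length, 1L)
    best <- best[order(sizes, best)][1]
  } else best <- best[1]
  structure(as.integer(best), mse = mse)
}

#' Nested cross-validated predictions for one model space
#'
#' Runs the repeated participant-grouped outer CV: per outer fold, modular
#' spaces first select their best module by nested inner CV, then the PCR
#' dimensionality is optimized by inner CV on the outer training set, the
#' model is fit, and the held-out rows are predicted. Every row is
#' predicted exactly once per repeat.
#'
#' @param qdata a [quartile_dataset()].
#' @param space a [model_space()].
#' @param cfg an [analysis_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param scheme optional pre-built [make_cv_scheme()] matrix.
#' @return A `prediction_set` data.frame: `row`, `repeat_`, `fold`,
#'   `participant`, `study`, `observed`, `predicted`, `module`, `k`.
#' @export
nested_cv_predict <- function(qdata, space, cfg = analysis_config(),
                              seed = cfg$seed, scheme = NULL) {
  y <- qdata$meta$rating
  if (is.null(scheme))
    scheme <- make_cv_scheme(qdata$meta, cfg$cv_repeats, cfg$cv_folds,
                             derive_seed(seed, "outer_cv"))
  out <- list(); at <- 1L
  for (r in seq_len(ncol(scheme))) {
    foldid <- scheme[, r]
    for (f in sort(unique(foldid))) {
      te <- which(foldid == f); tr <- which(foldid != f)
      if (length(intersect(qdata$meta$participant_id[tr],
                           qdata$meta$participant_id[te])))
        stop("participant fragmented across train and test of one fold")
      qtr <- qd_subset(qdata, tr)
      mod_i <- 1L
      if (space$kind == "modular" && length(space$modules) > 1L)
        mod_i <- select_module(qtr, space, cfg,
                               derive_seed(seed, paste0("sel_", r, "_", f)))
      vox <- space$modules[[mod_i]]
      Xtr <- extract_features(qtr, vox)
      inner <- make_group_folds(qtr$meta$participant_id, qtr$meta$study,
                                cfg$inner_folds,
                                derive_seed(seed, paste0("dim_", r, "_", f)))
      k <- optimize_dims(Xtr, y[tr], inner, cfg$opt,
                         derive_seed(seed, paste0("dim_bo_", r, "_", f)))
      fit <- fit_pcr(Xtr, y[tr], k)
      pred <- predict(fit, extract_features(qdata, vox)[te, , drop = FALSE])
      out[[at]] <- data.frame(
        row = te, repeat_ = r, fold = f,
        participant = qdata$meta$participant_id[te],
        study = qdata$meta$study[te],
        observed = y[te], predicted = pred,
        module = names(space$modules)[mod_i] %||% as.character(mod_i),
        k = as.integer(k), stringsAsFactors = FALSE)
      at <- at + 1L
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$repeat_, res$row), ]
  rownames(res) <- NULL
  attr(res, "space_id") <- space$space_id
  class(res) <- c("prediction_set", "data.frame")
  res
}

#' Train a single frozen model on all rows
#'
#' For modular spaces the best module is first chosen by inner CV on the
#' full dataset; then the dimensionality is optimized and the final PCR
#' model is fit to every row. The result can be applied to holdout
#' studies or task maps with [apply_model()].
#'
#' @inheritParams nested_cv_predict
#' @return A `pcr_model` carrying `space_id`, `module`, `voxel_set`,
#'   `n_mask`.
#' @export
train_final <- function(qdata, space, cfg = analysis_config(), seed = cfg$seed) {
  y <- qdata$meta$rating
  mod_i <- 1L
  if (space$kind == "modular" && length(space$modules) > 1L)
    mod_i <- select_module(qdata, space, cfg, derive_seed(seed, "final_sel"))
  vox <- space$modules[[mod_i]]
  X <- extract_features(qdata, vox)
  inner <- make_group_folds(qdata$meta$participant_id, qdata$meta$study,
                            cfg$inner_folds, derive_seed(seed, "final_dim"))
  k <- optimize_dims(X, y, inner, cfg$opt, derive_seed(seed, "final_bo"))
  fit <- fit_pcr(X, y, k)
  fit$space_id <- space$space_id
  fit$module <- names(space$modules)[mod_i] %||% as.character(mod_i)
  fit$voxel_set <- vox
  fit$n_mask <- ncol(qdata$features)
  fit
}

#' Pooled multistudy decoding driver
#'
#' Balances participants across studies (to `cfg$balance_n` per study),
#' then runs [nested_cv_predict()] for each supplied space on the pooled
#' data and summarizes per-participant performance.
#'
#' @param qdata a [quartile_dataset()] spanning several studies.
#' @param spaces named list of [model_space()] objects.
#' @param cfg an [analysis_config()].
#' @param seed integer seed.
#' @return list with `predictions` (per space), `performance` (stacked
#'   [participant_performance()] table, condition "multistudy").
#' @export
decode_multistudy <- function(qdata, spaces, cfg = analysis_config(),
                              seed = cfg$seed) {
  qb <- balance_participants(qdata, cfg$balance_n, derive_seed(seed, "ms_balance"))
  preds <- lapply(spaces, function(sp)
    nested_cv_predict(qb, sp, cfg, derive_seed(seed, paste0("ms_", sp$space_id))))
  perf <- do.call(rbind, lapply(preds, function(ps) {
    pf <- participant_performance(ps)
    pf$space <- attr(ps, "space_id"); pf$condition <- "multistudy"
    pf
  }))
  rownames(perf) <- NULL
  class(perf) <- c("performance_table", "data.frame")
  list(predictions = preds, performance = perf)
}

#' Study-wise decoding driver (learner generalization)
#'
#' Trains and cross-validates an independent model per study for each
#' space, so performance estimates vary independently across studies and
#' inference extends to new models trained on new studies.
#'
#' @inheritParams decode_multistudy
#' @return list with `predictions` (space -> study -> prediction set) and
#'   `performance` (condition "studywise").
#' @export
decode_studywise <- function(qdata, spaces, cfg = analysis_config(),
                             seed = cfg$seed) {
  studies <- unique(qdata$meta$study)
  preds <- lapply(spaces, function(sp) {
    per_study <- lapply(studies, function(s) {
      qs <- qd_subset(qdata, which(qdata$meta$study == s))
      nested_cv_predict(qs, sp, cfg, derive_seed(seed, paste0("sw_", sp$space_id, "_", s)))
    })
    names(per_study) <- studies
    per_study
  })
  perf <- do.call(rbind, unlist(lapply(names(preds), function(nm)
    lapply(preds[[nm]], function(ps) {
      pf <- participant_performance(ps)
      pf$space <- nm; pf$condition <- "studywise"
      pf
    })), recursive = FALSE))
  rownames(perf) <- NULL
  class(perf) <- c("performance_table", "data.frame")
  list(predictions = preds, performance = perf)
}
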