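#' Standardize trial images within study
#'
#' Per study, subtracts the study mean map from every trial image, then
#' rescales each trial image to mean voxel value 0 and voxel SD 1 (in that
#' order). After this, images differ only in the spatial configuration of
#' their response, not in net intensity; the per-image rescaling also means
#' the study mean of the output is no longer exactly zero.
#'
#' @param datasets list of [study_dataset()] (or a single one).
#' @return The datasets with standardized features.
#' @export
standardize_images <- function(datasets) {
  single <- inherits(datasets, "study_dataset")
  if (single) datasets <- list(datasets)
  out <- lapply(datasets, function(ds) {
    X <- ds$features
    if (nrow(X) < 1L) stop(sprintf("study %s has no trials", ds$study_id))
    Xc <- sweep(X, 2, colMeans(X))
    mu <- rowMeans(Xc)
    sdv <- apply(Xc, 1, sd)
    zero <- which(sdv < .Machine$double.eps * 100)
    if (length(zero))
      stop(sprintf("zero-variance image after demeaning: study %s trial %d",
                   ds$study_id, zero[1]))
    ds$features <- (Xc - mu) / sdv
    ds
  })
  if (single) out[[1]] else out
}

#' Z-score pain ratings within study
#'
#' Per study, maps raw ratings to mean 0 and SD 1 (an affine map, so
#' between-participant differences within study are preserved).
#'
#' @param datasets list of [study_dataset()] (or a single one).
#' @return The datasets with z-scored `rating` columns.
#' @export
zscore_ratings <- function(datasets) {
  single <- inherits(datasets, "study_dataset")
  if (single) datasets <- list(datasets)
  out <- lapply(datasets, function(ds) {
    r <- ds$meta$rating
    if (length(unique(r)) < 2L)
      stop(sprintf("constant ratings in study %s", ds$study_id))
    ds$meta$rating <- as.vector(scale(r))
    ds
  })
  if (single) out[[1]] else out
}

#' Rating-quartile dataset
#'
#' Rows are participant x rating-quartile cells with trial-averaged feature
#' vectors, ratings, and covariates. Constructed by [quartile_collapse()].
#'
#' @param features matrix rows x voxels.
#' @param meta data.frame with `study`, `participant_id`, `quartile`,
#'   `rating`, `n_trials` and averaged covariate columns.
#' @param mask the shared [mask_geometry()].
#' @param factor_schema list (by study) of active factor names.
#' @return Object of class `quartile_dataset`.
#' @export
quartile_dataset <- function(features, meta, mask, factor_schema = list()) {
  stopifnot(nrow(features) == nrow(meta))
  structure(list(features = as.matrix(features),
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 mask = mask, factor_schema = factor_schema),
            class = "quartile_dataset")
}

#' @export
print.quartile_dataset <- function(x, ...) {
  cat(sprintf("<quartile_dataset> %d rows (%d participants, %d studies), %d voxels\n",
              nrow(x$features), length(unique(x$meta$participant_id)),
              length(unique(x$meta$study)), ncol(x$features)))
  invisible(x)
}

#' Collapse trials to per-participant rating quartiles
#'
#' For each participant, ranks trials by (z-scored) rating with ties broken
#' by trial order, splits them into 4 equal-count bins (remainder trials go
#' to the lower bins), and averages features, ratings, and covariates
#' within bin. Participants with fewer than 4 trials or all-equal ratings
#' are excluded and logged. Within every kept participant the averaged
#' ratings are non-decreasing in quartile index by construction.
#'
#' @param datasets list of standardized, rating-z-scored [study_dataset()].
#' @param n_bins number of rating bins (default 4; quartiles are the
#'   minimum at which every bin informs a linear intensity effect).
#' @return A [quartile_dataset()]; excluded participants are recorded in
#'   `attr(, "excluded")`.
#' @export
quartile_collapse <- function(datasets, n_bins = 4L) {
  if (inherits(datasets, "study_dataset")) datasets <- list(datasets)
  rows_feat <- list(); rows_meta <- list(); excluded <- list()
  schema <- list()
  mask <- datasets[[1]]$mask
  at <- 1L
  for (ds in datasets) {
    if (!same_grid(mask, ds$mask)) stop("datasets disagree on mask geometry")
    schema[[ds$study_id]] <- ds$factor_schema
    covs <- ds$factor_schema
    for (p in unique(ds$meta$participant_id)) {
      sel <- which(ds$meta$participant_id == p)
      if (length(sel) < n_bins) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(study = ds$study_id, participant_id = p,
                     reason = "fewer than 4 trials", stringsAsFactors = FALSE)
        next
      }
      r <- ds$meta$rating[sel]
      if (length(unique(r)) < 2L) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(study = ds$study_id, participant_id = p,
                     reason = "all-equal ratings", stringsAsFactors = FALSE)
        next
      }
      ord <- sel[order(r, seq_along(sel))]  # stable: ties by trial order
      n <- length(ord)
      base <- n %/% n_bins; rem <- n %% n_bins
      sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
      bin <- rep(seq_len(n_bins), times = sizes)
      for (q in seq_len(n_bins)) {
        take <- ord[bin == q]
        fm <- colMeans(ds$features[take, , drop = FALSE])
        m <- data.frame(study = ds$study_id, participant_id = p, quartile = q,
                        rating = mean(ds$meta$rating[take]),
                        n_trials = length(take), stringsAsFactors = FALSE)
        for (cv in covs) m[[cv]] <- mean(ds$meta[[cv]][take])
        rows_feat[[at]] <- fm; rows_meta[[at]] <- m; at <- at + 1L
      }
    }
  }
  if (!length(rows_feat)) stop("no participants survived quartile collapse")
  meta <- do.call(rbind, lapply(rows_meta, function(m) {
    all_covs <- unique(unlist(schema))
    for (cv in setdiff(all_covs, names(m))) m[[cv]] <- NA_real_
    m[c("study", "participant_id", "quartile", "rating", "n_trials", all_covs)]
  }))
  qd <- quartile_dataset(do.call(rbind, rows_feat), meta, mask, schema)
  excl <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(study = character(), participant_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(excl))
    message(sprintf("quartile_collapse: excluded %d participant(s): %s",
                    nrow(excl),
                    paste(sprintf("%s/%s (%s)", excl$study, excl$participant_id,
                                  excl$reason), collapse = "; ")))
  attr(qd, "excluded") <- excl
  qd
}

#' Full preprocessing path
#'
#' Study demeaning, per-image z-scoring, rating z-scoring, then quartile
#' collapse, in that order.
#'
#' @param datasets list of raw [study_dataset()].
#' @inheritParams quartile_collapse
#' @return A [quartile_dataset()].
#' @export
preprocess_datasets <- function(datasets, n_bins = 4L) {
  quartile_collapse(zscore_ratings(standardize_images(datasets)), n_bins = n_bins)
}

#' Subset a quartile dataset by row index
#' @param qdata a [quartile_dataset()].
#' @param rows integer row indices.
#' @return The row subset, same class.
#' @export
qd_subset <- function(qdata, rows) {
  quartile_dataset(qdata$features[rows, , drop = FALSE],
                   qdata$meta[rows, , drop = FALSE],
                   qdata$mask, qdata$factor_schema)
}

#' Balance participants across studies
#'
#' Randomly samples `n_per_study` participants from every study (the
#' pooled multistudy analysis balances to the smallest study's size).
#'
#' @param qdata a [quartile_dataset()].
#' @param n_per_study participants kept per study.
#' @param seed integer seed.
#' @return Row-subset [quartile_dataset()].
#' @export
balance_participants <- function(qdata, n_per_study, seed = 1L) {
  set.seed(derive_seed(seed, "balance"))
  keep <- unlist(lapply(split(qdata$meta$participant_id, qdata$meta$study),
                        function(p) {
    u <- unique(p)
    if (length(u) < n_per_study)
      stop(sprintf("a study has only %d participants (< %d)", length(u), n_per_study))
    sample(u, n_per_study)
  }))
  qd_subset(qdata, which(qdata$meta$participant_id %in% keep))
}
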