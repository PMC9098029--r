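#' Bootstrap-thresholded voxel weight map
#'
#' Resamples participants with replacement (a cluster bootstrap respecting
#' the repeated-measures structure), refits the PCR decoder with the
#' component count frozen at the full-data choice, and summarizes each
#' voxel's weight by its bootstrap mean, SE, z = mean/SE, and a two-tailed
#' normal-tail p value. The significance mask is `p < alpha`.
#'
#' @param qdata a [quartile_dataset()].
#' @param voxel_set voxel indices of the space or module to fit.
#' @param k component count (typically from [train_final()]); if `NULL`
#'   it is chosen by inner CV on the full data first.
#' @param n_boot bootstrap samples (default 5008).
#' @param alpha voxel-wise significance level.
#' @param seed integer seed.
#' @param cfg an [analysis_config()] (used only when `k` is `NULL`).
#' @return `weight_map`: list with `weights` (full-data fit), `boot_mean`,
#'   `boot_se`, `z`, `p`, `mask` (significance), `voxel_set`, `k`,
#'   `n_boot`, `alpha`.
#' @export
bootstrap_weight_map <- function(qdata, voxel_set, k = NULL, n_boot = 5008L,
                                 alpha = 0.05, seed = 1L,
                                 cfg = analysis_config()) {
  X <- extract_features(qdata, voxel_set)
  y <- qdata$meta$rating
  if (is.null(k)) {
    inner <- make_group_folds(qdata$meta$participant_id, qdata$meta$study,
                              cfg$inner_folds, derive_seed(seed, "wm_inner"))
    k <- as.integer(optimize_dims(X, y, inner, cfg$opt, derive_seed(seed, "wm_bo")))
  }
  full <- fit_pcr(X, y, k)
  parts <- split(seq_len(nrow(X)), qdata$meta$participant_id)
  np <- length(parts)
  if (np < 2L) stop("bootstrap requires at least 2 participants")
  set.seed(derive_seed(seed, "wm_boot"))
  p <- ncol(X)
  s1 <- numeric(p); s2 <- numeric(p)
  for (b in seq_len(n_boot)) {
    take <- unlist(parts[sample.int(np, np, replace = TRUE)], use.names = FALSE)
    # duplicated participants reduce distinct rows, hence attainable rank
    kb <- max(min(k, length(unique(take)) - 1L, p), 1L)
    fb <- fit_pcr(X[take, , drop = FALSE], y[take], kb)
    s1 <- s1 + fb$W
    s2 <- s2 + fb$W^2
  }
  bm <- s1 / n_boot
  bse <- sqrt(pmax(s2 / n_boot - bm^2, 0) * n_boot / (n_boot - 1))
  z <- ifelse(bse > 0, bm / bse, 0)
  pv <- 2 * pnorm(-abs(z))
  structure(list(weights = full$W, boot_mean = bm, boot_se = bse, z = z,
                 p = pv, mask = pv < alpha, voxel_set = voxel_set,
                 k = k, n_boot = as.integer(n_boot), alpha = alpha,
                 n_mask = ncol(qdata$features)),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> %d voxels, k = %d, %d bootstrap samples; %d significant (%.1f%%) at alpha = %g\n",
              length(x$weights), x$k, x$n_boot, sum(x$mask),
              100 * mean(x$mask), x$alpha))
  invisible(x)
}

# Expand a weight_map into full in-mask vectors (weights where significant,
# NA elsewhere) for conjunction and similarity.
wm_full_vectors <- function(map) {
  w <- rep(NA_real_, map$n_mask)
  w[map$voxel_set[map$mask]] <- map$weights[map$mask]
  m <- logical(map$n_mask)
  m[map$voxel_set[map$mask]] <- TRUE
  list(w = w, mask = m)
}

#' Conjoin bootstrap-thresholded maps across CV folds
#'
#' The conjunction mask is the union of the folds' significance masks; a
#' voxel's weight is the mean of the contributing maps' weights where that
#' voxel was significant. Voxels where contributing folds disagree in sign
#' are counted and flagged.
#'
#' @param maps list of `weight_map`s on the same grid.
#' @return `weight_map`-like list with union mask, mean weights, and a
#'   `sign_conflicts` count.
#' @export
conjoin_fold_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  nm <- maps[[1]]$n_mask
  if (any(vapply(maps, function(m) m$n_mask, 1L) != nm)) stop("grid mismatch")
  acc <- matrix(NA_real_, length(maps), nm)
  for (i in seq_along(maps)) acc[i, ] <- wm_full_vectors(maps[[i]])$w
  n_sig <- colSums(!is.na(acc))
  mask <- n_sig > 0L
  w <- rep(0, nm)
  w[mask] <- colMeans(acc[, mask, drop = FALSE], na.rm = TRUE)
  signs <- apply(acc[, mask, drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]; length(unique(sign(v))) > 1L
  })
  structure(list(weights = w, mask = mask, voxel_set = seq_len(nm),
                 n_mask = nm, n_boot = maps[[1]]$n_boot,
                 alpha = maps[[1]]$alpha, k = NA_integer_,
                 sign_conflicts = sum(signs)),
            class = "weight_map")
}

#' Spatial similarity of two thresholded weight maps
#'
#' Pearson correlation of the weights over the intersection of the two
#' significance masks; reported `NA` when the intersection has fewer than
#' 10 voxels.
#'
#' @param mapA,mapB `weight_map`s on the same in-mask grid.
#' @param min_overlap minimum intersection size (default 10).
#' @return Correlation with the overlap size in `attr(, "n_overlap")`.
#' @export
spatial_similarity <- function(mapA, mapB, min_overlap = 10L) {
  if (mapA$n_mask != mapB$n_mask) stop("grid mismatch")
  a <- wm_full_vectors(mapA); b <- wm_full_vectors(mapB)
  ov <- which(a$mask & b$mask)
  if (length(ov) < min_overlap)
    return(structure(NA_real_, n_overlap = length(ov)))
  structure(cor(a$w[ov], b$w[ov]), n_overlap = length(ov))
}

#' Region-coverage permutation test
#'
#' Per region, compares the observed fraction of significant voxels to a
#' null built by shuffling the significance mask across all in-mask
#' voxels: `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param map a thresholded `weight_map` covering the full in-mask grid.
#' @param parc the [parcellation()].
#' @param n_perm number of permutations (at least 999).
#' @param seed integer seed.
#' @return data.frame per region: label, n_voxels, coverage (percent),
#'   p value.
#' @export
region_coverage_test <- function(map, parc, n_perm = 5000L, seed = 1L) {
  if (n_perm < 999L) stop("n_perm must be at least 999")
  full <- wm_full_vectors(map)
  mask <- full$mask
  V <- length(mask)
  if (V != n_voxels(parc$mask)) stop("map and parcellation disagree on mask size")
  labs <- sort(unique(parc$region))
  region_idx <- split(seq_len(V), parc$region)
  obs <- vapply(region_idx, function(ii) mean(mask[ii]), 0)
  set.seed(derive_seed(seed, "coverage"))
  exceed <- numeric(length(labs))
  for (b in seq_len(n_perm)) {
    perm <- mask[sample.int(V)]
    cov_b <- vapply(region_idx, function(ii) mean(perm[ii]), 0)
    exceed <- exceed + (cov_b >= obs)
  }
  data.frame(label = labs,
             n_voxels = lengths(region_idx),
             coverage = 100 * obs,
             p = (1 + exceed) / (n_perm + 1),
             row.names = NULL)
}
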