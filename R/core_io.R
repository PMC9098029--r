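#' Mask geometry for a voxel grid
#'
#' Describes the 3-D grid a dataset lives on together with the ordered list
#' of in-mask voxel (linear, 1-based) indices. All feature vectors in a
#' [study_dataset()] are stored over this ordered index list, so any voxel
#' vector can be reconstructed into a full volume exactly.
#'
#' @param dim integer(3), grid dimensions.
#' @param idx integer vector of in-mask linear indices (1-based, strictly
#'   increasing) into the flattened grid.
#' @param affine 4x4 voxel-to-world matrix (defaults to identity spacing).
#' @return An object of class `mask_geometry`.
#' @export
mask_geometry <- function(dim, idx, affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > prod(dim))) stop("mask indices out of grid range")
  if (is.unsorted(idx, strictly = TRUE)) stop("mask indices must be strictly increasing")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1, 4] <- -dim[1] / 2; affine[2, 4] <- -dim[2] / 2; affine[3, 4] <- -dim[3] / 2
  }
  structure(list(dim = dim, idx = idx, affine = affine), class = "mask_geometry")
}

#' @export
print.mask_geometry <- function(x, ...) {
  cat(sprintf("<mask_geometry> grid %s, %d in-mask voxels\n",
              paste(x$dim, collapse = "x"), length(x$idx)))
  invisible(x)
}

n_voxels <- function(mask) length(mask$idx)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) < tol &&
    identical(a$idx, b$idx)
}

#' Trial-level dataset for one study
#'
#' Container for one study's trial-level beta maps (as a trials x voxels
#' matrix over an in-mask voxel list) together with trial metadata:
#' participant ids, trial indices, raw pain ratings, and experimental-factor
#' covariates. The set of factor names active in the study (its factor
#' schema) is carried along so downstream stages never assume a covariate
#' that the study did not manipulate.
#'
#' @param study_id character scalar.
#' @param features numeric matrix, trials x voxels.
#' @param meta data.frame with columns `participant_id`, `trial_index`,
#'   `rating`, plus one numeric column per active factor.
#' @param mask a [mask_geometry()].
#' @param factor_schema character vector of covariate column names present
#'   in `meta`; defaults to all columns other than the three required ones.
#' @return Object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, features, meta, mask, factor_schema = NULL) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  features <- as.matrix(features)
  if (!inherits(mask, "mask_geometry")) stop("mask must be a mask_geometry")
  if (ncol(features) != n_voxels(mask))
    stop(sprintf("feature width %d does not match mask size %d",
                 ncol(features), n_voxels(mask)))
  req <- c("participant_id", "trial_index", "rating")
  if (!all(req %in% names(meta))) stop("meta must have participant_id, trial_index, rating")
  if (nrow(meta) != nrow(features)) stop("metadata row count does not match image count")
  dup <- stats::ave(meta$trial_index, meta$participant_id,
                    FUN = function(v) any(duplicated(v)))
  if (any(dup > 0)) stop("trial_index must be unique within participant")
  if (is.null(factor_schema))
    factor_schema <- setdiff(names(meta), req)
  if (!all(factor_schema %in% names(meta))) stop("factor_schema names absent from meta")
  structure(list(study_id = study_id, features = features,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 mask = mask, factor_schema = factor_schema),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %s: %d trials, %d participants, %d voxels\n",
              x$study_id, nrow(x$features),
              length(unique(x$meta$participant_id)), ncol(x$features)))
  if (length(x$factor_schema))
    cat("  factors:", paste(x$factor_schema, collapse = ", "), "\n")
  invisible(x)
}

#' Load a study dataset from NIfTI images and a metadata table
#'
#' Reads trial-level beta maps (a single 4-D NIfTI stack, or a vector of 3-D
#' NIfTI paths on one grid) and a CSV/TSV metadata table whose rows match the
#' image order one-to-one. Row order is preserved: metadata row i describes
#' volume i. Features are extracted over `mask` when given, otherwise over
#' the computed in-mask set (voxels that are nonzero in at least one trial).
#' Non-finite values inside the mask are rejected with the offending voxel
#' named.
#'
#' @param images_path path to a 4-D NIfTI file, or character vector of 3-D
#'   NIfTI paths.
#' @param metadata_path path to a CSV (or tab-separated, by extension) table
#'   with columns `participant_id`, `trial_index`, `rating` and optional
#'   covariates.
#' @param study_id study identifier; defaults to a `study` column in the
#'   metadata if present, else the image file name.
#' @param mask optional logical array (grid-shaped) or NIfTI mask path.
#' @return A [study_dataset()].
#' @export
load_dataset <- function(images_path, metadata_path, study_id = NULL, mask = NULL) {
  vols <- read_volumes(images_path)
  meta <- read_table_auto(metadata_path)
  if (dim(vols$data)[4] != nrow(meta))
    stop(sprintf("metadata/image count mismatch: %d volumes vs %d rows",
                 dim(vols$data)[4], nrow(meta)))
  d3 <- dim(vols$data)[1:3]
  flat <- matrix(vols$data, nrow = prod(d3), ncol = dim(vols$data)[4])
  if (is.null(mask)) {
    in_mask <- rowSums(flat != 0, na.rm = TRUE) > 0
    if (!any(in_mask)) stop("all voxels are zero in every trial; cannot compute mask")
  } else {
    if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
    if (!identical(as.integer(dim(mask)[1:3]), as.integer(d3)))
      stop("mask grid does not match image grid")
    in_mask <- as.vector(mask != 0)
  }
  idx <- which(in_mask)
  feats <- t(flat[idx, , drop = FALSE])
  bad <- which(!is.finite(feats), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at in-mask voxel %d (linear index %d) of trial %d",
                 bad[1, 2], idx[bad[1, 2]], bad[1, 1]))
  mg <- mask_geometry(d3, idx, vols$affine)
  if (is.null(study_id))
    study_id <- if ("study" %in% names(meta)) as.character(meta$study[1]) else
      tools::file_path_sans_ext(basename(images_path[1]))
  meta$study <- NULL
  study_dataset(study_id, feats, meta, mg)
}

read_volumes <- function(images_path) {
  imgs <- lapply(images_path, RNifti::readNifti)
  ref_dim <- dim(imgs[[1]])[1:3]
  ref_aff <- unclass(RNifti::xform(imgs[[1]]))
  arrs <- lapply(seq_along(imgs), function(i) {
    im <- imgs[[i]]
    if (!identical(as.integer(dim(im)[1:3]), as.integer(ref_dim)))
      stop(sprintf("grid mismatch: image %d has dims %s, expected %s",
                   i, paste(dim(im)[1:3], collapse = "x"),
                   paste(ref_dim, collapse = "x")))
    aff <- unclass(RNifti::xform(im))
    if (max(abs(aff - ref_aff)) > 1e-4)
      stop(sprintf("affine mismatch at image %d", i))
    a <- as.array(im)
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    a
  })
  data <- array(0, dim = c(ref_dim, sum(vapply(arrs, function(a) dim(a)[4], 1L))))
  at <- 1L
  for (a in arrs) {
    nt <- dim(a)[4]
    data[, , , at:(at + nt - 1L)] <- a
    at <- at + nt
  }
  list(data = data, affine = ref_aff)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE)
}

#' Write a study dataset as a 4-D NIfTI stack plus CSV metadata
#'
#' Inverse of [load_dataset()]: emits `<prefix>.nii.gz` and `<prefix>.csv`
#' in the exact layout `load_dataset` consumes (a lossless roundtrip within
#' single-precision NIfTI tolerance).
#'
#' @param dataset a [study_dataset()].
#' @param prefix output path prefix (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "study_dataset"))
  m <- dataset$mask
  n <- nrow(dataset$features)
  arr <- array(0, dim = c(m$dim, n))
  flat <- matrix(0, prod(m$dim), n)
  flat[m$idx, ] <- t(dataset$features)
  arr[] <- flat
  nii <- RNifti::asNifti(arr)
  nii <- RNifti::`sform<-`(nii, structure(m$affine, code = 2L))
  img_path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, img_path, datatype = "double")
  meta <- dataset$meta
  meta$study <- dataset$study_id
  csv_path <- paste0(prefix, ".csv")
  write.csv(meta, csv_path, row.names = FALSE)
  invisible(c(images = img_path, metadata = csv_path))
}

#' Save a voxel weight vector as a NIfTI volume
#'
#' Places the weights at the in-mask voxels of `mask` (zero elsewhere) and
#' writes a 3-D NIfTI volume; [load_weight_map()] reproduces the vector.
#'
#' @param weights numeric vector of length `length(mask$idx)`.
#' @param mask a [mask_geometry()].
#' @param path output file path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
save_weight_map <- function(weights, mask, path) {
  stopifnot(inherits(mask, "mask_geometry"))
  if (length(weights) != n_voxels(mask))
    stop(sprintf("weight length %d does not match mask size %d",
                 length(weights), n_voxels(mask)))
  vol <- array(0, dim = mask$dim)
  vol[mask$idx] <- weights
  nii <- RNifti::asNifti(vol)
  nii <- RNifti::`sform<-`(nii, structure(mask$affine, code = 2L))
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Read a weight volume back into a vector over a mask
#'
#' @param path NIfTI file written by [save_weight_map()].
#' @param mask the [mask_geometry()] it was written with.
#' @return Numeric vector over the in-mask voxels.
#' @export
load_weight_map <- function(path, mask) {
  vol <- as.array(RNifti::readNifti(path))
  if (!identical(as.integer(dim(vol)[1:3]), mask$dim)) stop("grid mismatch")
  as.vector(vol)[mask$idx]
}

#' Load a parcellation from a label image and label table
#'
#' Reads an integer NIfTI label image plus a table mapping each label to a
#' region name, fine resting-state network (fRSN), coarse network (cRSN)
#' and a pain-pathway flag. Every nonzero voxel is assigned exactly one
#' region; labels present in the image but missing from the table are an
#' error.
#'
#' @param path NIfTI integer label image.
#' @param label_table_path CSV with columns `label`, `region`, `frsn`,
#'   `crsn`, `pathway` (0/1 or logical).
#' @param meta_mask_path optional NIfTI mask (nonzero = in meta-analytic
#'   mask), resliced/aligned to the label grid.
#' @return A [parcellation()] object.
#' @export
load_label_image <- function(path, label_table_path, meta_mask_path = NULL) {
  img <- as.array(RNifti::readNifti(path))
  aff <- unclass(RNifti::xform(RNifti::readNifti(path)))
  if (max(abs(img - round(img))) > 1e-6) stop("label image is not integer-valued")
  img <- round(img)
  tab <- read_table_auto(label_table_path)
  req <- c("label", "region", "frsn", "crsn", "pathway")
  if (!all(req %in% names(tab))) stop("label table needs columns label, region, frsn, crsn, pathway")
  present <- sort(unique(as.vector(img[img != 0])))
  missing <- setdiff(present, tab$label)
  if (length(missing))
    stop(sprintf("labels present in image but absent from table: %s",
                 paste(missing, collapse = ", ")))
  idx <- which(as.vector(img) != 0)
  mg <- mask_geometry(dim(img)[1:3], idx, aff)
  region <- as.vector(img)[idx]
  meta <- if (is.null(meta_mask_path)) NULL else {
    mm <- as.array(RNifti::readNifti(meta_mask_path))
    if (!identical(as.integer(dim(mm)[1:3]), mg$dim)) stop("meta mask grid mismatch")
    as.vector(mm)[idx] > 0
  }
  parcellation(mask = mg, region = region, labels = tab, meta = meta)
}

#' Write a parcellation as a NIfTI label image plus CSV label table
#'
#' @param parc a [parcellation()].
#' @param prefix output path prefix.
#' @return Invisibly, file paths written.
#' @export
write_parcellation <- function(parc, prefix) {
  stopifnot(inherits(parc, "parcellation"))
  vol <- array(0L, dim = parc$mask$dim)
  vol[parc$mask$idx] <- parc$region
  nii <- RNifti::asNifti(vol)
  nii <- RNifti::`sform<-`(nii, structure(parc$mask$affine, code = 2L))
  img_path <- paste0(prefix, "_labels.nii.gz")
  RNifti::writeNifti(nii, img_path, datatype = "int32")
  csv_path <- paste0(prefix, "_labels.csv")
  write.csv(parc$labels, csv_path, row.names = FALSE)
  out <- c(image = img_path, table = csv_path)
  if (!is.null(parc$meta)) {
    mv <- array(0L, dim = parc$mask$dim)
    mv[parc$mask$idx[parc$meta]] <- 1L
    mnii <- RNifti::asNifti(mv)
    mnii <- RNifti::`sform<-`(mnii, structure(parc$mask$affine, code = 2L))
    mpath <- paste0(prefix, "_meta.nii.gz")
    RNifti::writeNifti(mnii, mpath, datatype = "int32")
    out <- c(out, meta = mpath)
  }
  invisible(out)
}

#' Analysis configuration
#'
#' Bundles the knobs shared across pipeline stages: cross-validation shape,
#' bootstrap/permutation counts, alpha levels, and the per-study balancing
#' sample size used by the pooled multistudy analysis.
#'
#' @param seed global seed; per-stage sub-seeds are derived from it.
#' @param cv_repeats,cv_folds outer CV shape (defaults 2 x 5).
#' @param inner_folds,innermost_folds fold counts for hyperparameter CV.
#' @param n_boot_weights bootstrap samples for weight maps (default 5008).
#' @param n_boot_mediation bootstrap samples for mediation (default 5000).
#' @param n_perm_coverage permutations for region-coverage tests.
#' @param alpha significance level.
#' @param balance_n participants sampled per study in the pooled analysis
#'   (default 16, the smallest training study).
#' @param opt settings for dimension optimization, see [opt_config()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, cv_repeats = 2L, cv_folds = 5L,
                            inner_folds = 5L, innermost_folds = 5L,
                            n_boot_weights = 5008L, n_boot_mediation = 5000L,
                            n_perm_coverage = 5000L, alpha = 0.05,
                            balance_n = 16L, opt = opt_config()) {
  cfg <- list(seed = as.integer(seed), cv_repeats = as.integer(cv_repeats),
              cv_folds = as.integer(cv_folds), inner_folds = as.integer(inner_folds),
              innermost_folds = as.integer(innermost_folds),
              n_boot_weights = as.integer(n_boot_weights),
              n_boot_mediation = as.integer(n_boot_mediation),
              n_perm_coverage = as.integer(n_perm_coverage),
              alpha = alpha, balance_n = as.integer(balance_n), opt = opt)
  counts <- unlist(cfg[c("cv_repeats", "cv_folds", "inner_folds", "innermost_folds",
                         "n_boot_weights", "n_boot_mediation", "n_perm_coverage",
                         "balance_n")])
  if (any(counts <= 0)) stop("all counts must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @return [read_analysis_config()] returns an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  opt <- do.call(opt_config, raw$opt %||% list())
  raw$opt <- NULL
  do.call(analysis_config, c(raw, list(opt = opt)))
}

#' @rdname read_analysis_config
#' @param cfg an `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}
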