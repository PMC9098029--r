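#' Parcellation over an in-mask voxel set
#'
#' A parcellation assigns every in-mask voxel to exactly one elementary
#' region, every region to one fine resting-state network (fRSN), and every
#' fRSN to one coarse network (cRSN). A subset of regions is flagged as the
#' a priori pain-pathways set, and an optional boolean meta-analytic mask
#' (e.g. a thresholded reverse-inference map) marks a multisystem voxel set.
#' Real atlases need not nest regions inside networks; nesting is only
#' enforced by the synthetic generator.
#'
#' @param mask a [mask_geometry()].
#' @param region integer vector (length = in-mask voxels) of region labels.
#' @param labels data.frame with columns `label`, `region`, `frsn`, `crsn`,
#'   `pathway`.
#' @param meta optional logical vector over in-mask voxels.
#' @return Object of class `parcellation`.
#' @export
parcellation <- function(mask, region, labels, meta = NULL) {
  stopifnot(inherits(mask, "mask_geometry"))
  region <- as.integer(region)
  if (length(region) != n_voxels(mask)) stop("region vector length != mask size")
  labs <- sort(unique(region))
  if (!all(labs %in% labels$label)) stop("region labels missing from label table")
  labels$pathway <- as.logical(labels$pathway)
  if (!is.null(meta)) {
    meta <- as.logical(meta)
    if (length(meta) != n_voxels(mask)) stop("meta mask length != mask size")
  }
  structure(list(mask = mask, region = region,
                 labels = as.data.frame(labels, stringsAsFactors = FALSE),
                 meta = meta),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d voxels, %d regions, %d fRSN, %d cRSN, %d pathway regions\n",
              n_voxels(x$mask), length(unique(x$region)),
              length(unique(x$labels$frsn)), length(unique(x$labels$crsn)),
              sum(x$labels$pathway)))
  if (!is.null(x$meta))
    cat(sprintf("  meta mask: %d voxels (%.1f%%)\n", sum(x$meta),
                100 * mean(x$meta)))
  invisible(x)
}

#' Voxel index sets for each region / fRSN / cRSN
#'
#' @param parc a [parcellation()].
#' @param level one of "region", "frsn", "crsn".
#' @return Named list of integer vectors (indices into the in-mask voxel
#'   list), one per label at that level, in label order.
#' @export
parcel_voxel_sets <- function(parc, level = c("region", "frsn", "crsn")) {
  level <- match.arg(level)
  lab_of_region <- switch(level,
    region = setNames(parc$labels$label, parc$labels$label),
    frsn   = setNames(parc$labels$frsn, parc$labels$label),
    crsn   = setNames(parc$labels$crsn, parc$labels$label))
  vox_lab <- lab_of_region[as.character(parc$region)]
  split(seq_along(parc$region), factor(vox_lab, levels = sort(unique(lab_of_region))))
}

#' A model space: the voxel-set hypothesis a decoder may draw on
#'
#' Modular spaces (`REGION`, `FRSN`, `CRSN`) carry a list of candidate
#' modules, one voxel set per parcel, from which a single "best" module is
#' chosen by cross-validation. Fixed spaces (`PATHWAYS`, `META`, `FULL`)
#' carry one voxel set used as-is.
#'
#' @param space_id one of REGION, FRSN, CRSN, PATHWAYS, META, FULL.
#' @param kind "modular" or "fixed".
#' @param modules for modular spaces, named list of nonempty integer voxel
#'   index sets; for fixed spaces, a single-element list.
#' @return Object of class `model_space`.
#' @export
model_space <- function(space_id, kind = c("modular", "fixed"), modules) {
  kind <- match.arg(kind)
  space_id <- match.arg(space_id, c("REGION", "FRSN", "CRSN", "PATHWAYS", "META", "FULL"))
  if (!length(modules)) stop("model space needs at least one candidate")
  if (any(vapply(modules, length, 1L) == 0L)) stop("empty candidate module")
  if (kind == "fixed" && length(modules) != 1L) stop("fixed space must have one voxel set")
  structure(list(space_id = space_id, kind = kind, modules = modules),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %s (%s): %d candidate(s), %d voxels total\n",
              x$space_id, x$kind, length(x$modules),
              length(unique(unlist(x$modules)))))
  invisible(x)
}

#' Build the six model spaces from a parcellation
#'
#' Materializes the six scope-of-representation hypotheses: single best
#' elementary region, best fine network, best coarse network (modular
#' spaces with one candidate per parcel), the a priori pain-pathways union,
#' the meta-analytic mask, and the full brain (fixed spaces).
#'
#' @param parc a [parcellation()] with a nonempty pathway set and meta mask.
#' @return Named list of six [model_space()] objects.
#' @export
build_model_spaces <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  region_sets <- parcel_voxel_sets(parc, "region")
  frsn_sets <- parcel_voxel_sets(parc, "frsn")
  crsn_sets <- parcel_voxel_sets(parc, "crsn")
  path_regions <- parc$labels$label[parc$labels$pathway]
  if (!length(path_regions)) stop("empty pathway region set")
  path_vox <- sort(unlist(region_sets[as.character(path_regions)], use.names = FALSE))
  if (is.null(parc$meta) || !any(parc$meta)) stop("empty meta mask")
  list(
    REGION   = model_space("REGION", "modular", region_sets),
    FRSN     = model_space("FRSN", "modular", frsn_sets),
    CRSN     = model_space("CRSN", "modular", crsn_sets),
    PATHWAYS = model_space("PATHWAYS", "fixed", list(PATHWAYS = path_vox)),
    META     = model_space("META", "fixed", list(META = which(parc$meta))),
    FULL     = model_space("FULL", "fixed", list(FULL = seq_len(n_voxels(parc$mask))))
  )
}

#' Extract a feature matrix for a voxel set
#'
#' @param qdata a [quartile_dataset()] (or any object with a `features`
#'   matrix over the mask).
#' @param voxel_set integer indices into the in-mask voxel list.
#' @return Numeric matrix, rows in stored order, columns in `voxel_set`
#'   order.
#' @export
extract_features <- function(qdata, voxel_set) {
  X <- qdata$features
  if (any(voxel_set < 1L) || any(voxel_set > ncol(X)))
    stop("voxel set contains out-of-mask indices")
  X[, voxel_set, drop = FALSE]
}
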