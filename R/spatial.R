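#' Mirror a tumor mask to the right hemisphere
#'
#' Pools left- and right-sided lesions on one hemisphere, the standard
#' laterality-collapsing step before voxel-wise mapping.  The mask is
#' flipped along the x (left-right) axis iff its centre of mass lies more
#' than `midline_band_mm` to the left of the grid's midline plane; masks
#' whose centre of mass falls inside the midline band (falcine or
#' parasagittal lesions straddling the midline) are returned unchanged.
#' Set `midline_band_mm = 0` to flip every left-of-midline mask.
#'
#' The flip is the index reversal i -> (X - 1) - i along the first axis,
#' which mirrors about the grid's x-centre.  A warning is issued when the
#' grid centre is more than half a voxel away from `midline_plane`, since
#' the index flip then does not coincide with reflection about the
#' anatomical midline.
#'
#' @param mask a [mask_volume()].
#' @param midline_band_mm half-width of the midline band in mm (default 2).
#' @param force one of `"auto"` (centre-of-mass rule), `"flip"`,
#'   `"none"`.
#' @return A [mask_volume()] with identical voxel count; attribute
#'   `"flipped"` records whether the flip was applied.
#' @export
mirror_to_right <- function(mask, midline_band_mm = 2,
                            force = c("auto", "flip", "none")) {
  force <- match.arg(force)
  grid <- mask$grid
  if (mask_count(mask) == 0L) {
    warning("mirror_to_right: empty mask '", mask$label,
            "' returned unchanged", call. = FALSE)
    attr(mask, "flipped") <- FALSE
    return(mask)
  }
  centre_x <- voxel_to_world(grid, c((grid$shape[1] + 1) / 2, 1, 1))[1]
  if (abs(centre_x - grid$midline_plane) > grid$spacing[1] / 2) {
    warning("mirror_to_right: grid x-centre (", signif(centre_x, 4),
            ") is off the midline plane (", grid$midline_plane,
            "); index flip is not a reflection about the midline",
            call. = FALSE)
  }
  do_flip <- switch(force,
    flip = TRUE,
    none = FALSE,
    auto = mask_com(mask)[1] < grid$midline_plane - midline_band_mm
  )
  out <- mask
  if (do_flip) {
    out$data <- mask$data[grid$shape[1]:1, , , drop = FALSE]
  }
  attr(out, "flipped") <- do_flip
  out
}

#' Flip a mask along the left-right axis unconditionally
#' @param mask a [mask_volume()].
#' @return The x-flipped [mask_volume()].
#' @export
flip_x <- function(mask) {
  mask$data <- mask$data[mask$grid$shape[1]:1, , , drop = FALSE]
  mask
}

#' Binary dilation of a 3D array
#'
#' Iterated dilation with the 6-, 18-, or 26-connectivity structuring
#' element (one iteration per voxel of dilation).
#'
#' @param arr 3D logical or 0/1 array.
#' @param k number of dilation iterations (>= 0).
#' @param connectivity 6, 18, or 26 (default 26).
#' @return Logical array of the same shape.
#' @export
dilate_binary <- function(arr, k, connectivity = 26) {
  stopifnot(k >= 0, connectivity %in% c(6, 18, 26))
  out <- arr != 0
  if (k == 0) return(out)
  d <- dim(out)
  shifts <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  nz <- abs(shifts$a) + abs(shifts$b) + abs(shifts$c)
  keep <- nz > 0 & nz <= switch(as.character(connectivity),
                                "6" = 1L, "18" = 2L, "26" = 3L)
  shifts <- shifts[keep, ]
  for (iter in seq_len(k)) {
    acc <- out
    for (s in seq_len(nrow(shifts))) {
      a <- shifts$a[s]; b <- shifts$b[s]; cc <- shifts$c[s]
      src <- list(max(1, 1 - a):min(d[1], d[1] - a),
                  max(1, 1 - b):min(d[2], d[2] - b),
                  max(1, 1 - cc):min(d[3], d[3] - cc))
      dst <- list(src[[1]] + a, src[[2]] + b, src[[3]] + cc)
      acc[dst[[1]], dst[[2]], dst[[3]]] <-
        acc[dst[[1]], dst[[2]], dst[[3]]] | out[src[[1]], src[[2]], src[[3]]]
    }
    out <- acc
  }
  out
}

#' Extract the dural attachment zone (DAZ) of a tumor mask
#'
#' The DAZ is the intersection of the tumor mask with the dural domain
#' (dura + falx + tentorium), a proxy for the tumor's site of origin.  The
#' dural domain may be dilated by `dilation_voxels` (26-connectivity) to
#' tolerate about that many voxels of registration or segmentation jitter;
#' `dilation_voxels = 0` is the literal intersection.
#'
#' @param tumor a [mask_volume()] on the same grid as `dura`.
#' @param dura a [dural_template()].
#' @param dilation_voxels dilation of the dural domain in voxels
#'   (default 1).
#' @param on_unattached what to do when the intersection is empty:
#'   `"warn"` (default) or `"error"`.
#' @return A [mask_volume()] (subset of `tumor`); attribute `"unattached"`
#'   is `TRUE` when the intersection is empty.
#' @export
extract_daz <- function(tumor, dura, dilation_voxels = 1,
                        on_unattached = c("warn", "error")) {
  on_unattached <- match.arg(on_unattached)
  stopifnot(dilation_voxels >= 0)
  if (!grids_equal(tumor$grid, dura$grid)) {
    stop("extract_daz: tumor and dural template are on different grids",
         call. = FALSE)
  }
  dom <- dilate_binary(dural_domain(dura), dilation_voxels)
  out <- tumor
  out$data <- array(as.integer(tumor$data == 1L & dom), dim = dim(tumor$data))
  out$label <- paste0(tumor$label, "_daz")
  unattached <- sum(out$data) == 0L
  if (unattached) {
    msg <- paste0("extract_daz: tumor '", tumor$label,
                  "' has no dural attachment (empty DAZ)")
    if (on_unattached == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  attr(out, "unattached") <- unattached
  out
}

#' Cohort lesion-frequency map
#'
#' Per-voxel count of how many masks cover each voxel.  Frequency maps show
#' the cohort's spatial lesion distribution and drive the minimum-overlap
#' filter.
#'
#' @param masks nonempty list of [mask_volume()] objects on a shared grid.
#' @return An object of class `freq_map` with fields `grid`, `counts`
#'   (3D integer array), `n_patients`.
#' @export
frequency_map <- function(masks) {
  grid <- validate_cohort_grid(masks)
  counts <- array(0L, dim = grid$shape)
  for (m in masks) counts <- counts + m$data
  structure(list(grid = grid, counts = counts,
                 n_patients = length(masks)),
            class = "freq_map")
}

#' @export
print.freq_map <- function(x, ...) {
  cat("<freq_map> ", x$n_patients, " patients, max overlap ",
      max(x$counts), ", ", sum(x$counts > 0), " voxels covered\n", sep = "")
  invisible(x)
}

#' Connected components of a 3D binary map
#'
#' Deterministic flood-fill labeling (components numbered in raster-scan
#' order of their first voxel) under 6-, 18-, or 26-connectivity.
#'
#' @param binary_map 3D logical or 0/1 array.
#' @param connectivity 6, 18, or 26 (default 26).
#' @return A list with `labels` (3D integer array, 0 = background),
#'   `sizes` (voxels per component), `n_components`.
#' @export
connected_components <- function(binary_map, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(binary_map)
  stopifnot(length(d) == 3L)
  .cc3d_label(as.integer(binary_map != 0), as.integer(d),
              as.integer(connectivity))
}
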