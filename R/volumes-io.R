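#' Read a binary mask from a NIfTI file
#'
#' Reads a NIfTI-1 volume, populates the [grid_spec()] from the header, and
#' binarizes the data: any voxel with value >= `binarize_threshold` becomes 1.
#' Interpolated (fractional) masks are thereby rebinarized; integer 0/1 masks
#' pass through unchanged.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param binarize_threshold binarization cut-point, default 0.5.
#' @param label label stored on the result; defaults to the file name.
#' @param midline_plane world x of the midsagittal plane (default 0; for
#'   MNI-space masks the template midline is x = 0).
#' @return A [mask_volume()].  An all-zero mask triggers a warning, not an
#'   error.  4D input is a format error.
#' @export
read_mask <- function(path, binarize_threshold = 0.5, label = NULL,
                      midline_plane = 0) {
  if (!file.exists(path)) {
    stop("read_mask: file not found: ", path, call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_mask: not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- arr[, , , 1L]
    d <- dim(arr)
  }
  if (length(d) < 3L) {
    # NIfTI drops trailing singleton dimensions; restore them
    d <- c(d, rep(1L, 3L - length(d)))
    dim(arr) <- d
  }
  if (length(d) != 3L) {
    stop("read_mask: expected a 3D volume, got ", length(d), "D: ", path,
         call. = FALSE)
  }
  if (any(!is.finite(arr))) arr[!is.finite(arr)] <- 0
  sp <- c(RNifti::pixdim(img), rep(1, 3))[1:3]
  grid <- grid_spec(d, spacing = sp,
                    affine = structure(as.numeric(RNifti::xform(img)),
                                       dim = c(4L, 4L)),
                    midline_plane = midline_plane)
  data <- array(as.integer(arr >= binarize_threshold), dim = d)
  if (is.null(label)) label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  m <- mask_volume(grid, data, label = label)
  if (mask_count(m) == 0L) {
    warning("read_mask: mask '", label, "' is empty (all zero)", call. = FALSE)
  }
  m
}

#' Read a labeled dural template from a NIfTI file
#'
#' Like [read_mask()] but preserves the integer labels
#' (1 shell, 2 falx, 3 tentorium) instead of binarizing.
#'
#' @inheritParams read_mask
#' @param provenance free-text provenance string.
#' @return A [dural_template()].
#' @export
read_dural_template <- function(path, provenance = basename(path),
                                midline_plane = 0) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) < 3L) {
    dim(arr) <- c(dim(arr), rep(1L, 3L - length(dim(arr))))
  }
  if (length(dim(arr)) != 3L) {
    stop("read_dural_template: expected a 3D volume", call. = FALSE)
  }
  grid <- grid_spec(dim(arr),
                    spacing = c(RNifti::pixdim(img), rep(1, 3))[1:3],
                    affine = structure(as.numeric(RNifti::xform(img)),
                                       dim = c(4L, 4L)),
                    midline_plane = midline_plane)
  dural_template(grid, round(arr), provenance = provenance)
}

#' Write a volume to a NIfTI-1 file
#'
#' Binary masks and label volumes are stored as unsigned 8-bit integers
#' (bit-exact round trip); real-valued statistic maps as 32-bit float.
#'
#' @param volume a [mask_volume()], [dural_template()], or a list with
#'   elements `grid` (a [grid_spec()]) and `data` (3D numeric array) as
#'   produced by [stat_map_volume()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!dir.exists(dirname(path))) {
    stop("write_volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  grid <- volume$grid
  data <- volume$data
  if (is.null(grid) || is.null(data)) {
    stop("write_volume: volume must carry 'grid' and 'data'", call. = FALSE)
  }
  if (!identical(dim(data), grid$shape)) {
    stop("write_volume: data shape inconsistent with grid", call. = FALSE)
  }
  integral <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)) && max(abs(data)) <= 255 &&
       min(data) >= 0)
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (integral) "uint8" else "float")
  invisible(path)
}

#' Validate that a cohort of masks shares one template grid
#'
#' All voxel-wise analysis assumes a single common template space; this
#' checks that every mask has the same shape and the same affine (within an
#' absolute tolerance on affine entries) and returns the shared grid.
#'
#' @param masks nonempty list of [mask_volume()] objects.
#' @param tol absolute tolerance on affine entries, default 1e-4
#'   (accommodates header round-off across writers without admitting real
#'   misregistration).
#' @return The shared [grid_spec()].
#' @export
validate_cohort_grid <- function(masks, tol = 1e-4) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("validate_cohort_grid: need a nonempty list of masks", call. = FALSE)
  }
  ref <- masks[[1L]]$grid
  for (m in masks) {
    if (!identical(m$grid$shape, ref$shape)) {
      stop("validate_cohort_grid: mask '", m$label,
           "' has shape ", paste(m$grid$shape, collapse = "x"),
           ", expected ", paste(ref$shape, collapse = "x"), call. = FALSE)
    }
    if (!all(abs(m$grid$affine - ref$affine) <= tol)) {
      stop("validate_cohort_grid: mask '", m$label,
           "' has a mismatching affine (max |diff| = ",
           signif(max(abs(m$grid$affine - ref$affine)), 3), ")",
           call. = FALSE)
    }
  }
  ref
}
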