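#' Template grid specification
#'
#' A `grid_spec` describes the common template grid every volume in an
#' analysis lives on: array dimensions, voxel spacing in millimetres, the
#' 4x4 voxel-to-world affine, and the world x-coordinate of the midsagittal
#' plane.  The template is assumed RAS+ ("right" is larger world x).
#' Voxel indices are 1-based in R; the affine maps the *0-based* index,
#' following the NIfTI convention, so world(v) = A %*% c(i-1, j-1, k-1, 1).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric length 3, voxel size in mm (each > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine
#'   that places the grid centre at the world origin.
#' @param midline_plane world x-coordinate of the midsagittal plane.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 64))
#' g$spacing
#' @export
grid_spec <- function(shape, spacing = c(1, 1, 1), affine = NULL,
                      midline_plane = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -(shape - 1L) * spacing / 2
  }
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("grid_spec: affine must be invertible", call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = as.numeric(spacing), affine = affine,
         midline_plane = as.numeric(midline_plane)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, midline x = ", x$midline_plane, "\n", sep = "")
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [grid_spec()].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices, or a
#'   length-3 vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  h <- cbind(ijk - 1, 1)  # affine acts on 0-based indices
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

#' Binary mask volume on a template grid
#'
#' Bundles a 3D array of 0/1 values with its [grid_spec()] and a free-text
#' label (patient id or template name).
#'
#' @param grid a [grid_spec()].
#' @param data 3D array with values in {0, 1}; logical arrays are accepted.
#' @param label free-text label.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(grid, data, label = "") {
  stopifnot(inherits(grid, "grid_spec"))
  data <- as.array(data)
  if (!identical(dim(data), grid$shape)) {
    stop("mask_volume: data shape does not match grid shape", call. = FALSE)
  }
  if (!all(data == 0 | data == 1)) {
    stop("mask_volume: data must be binary (0/1)", call. = FALSE)
  }
  # plain integer array, free of any foreign attributes
  data <- array(as.integer(data), dim = grid$shape)
  structure(list(grid = grid, data = data, label = as.character(label)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> '", x$label, "': ", mask_count(x), " voxels (",
      signif(mask_volume_ml(x), 4), " ml) on ",
      paste(x$grid$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Voxel count and physical volume of a mask
#'
#' @param mask a [mask_volume()].
#' @return `mask_count()` returns the number of nonzero voxels;
#'   `mask_volume_ml()` the physical volume in millilitres
#'   (count x voxel volume / 1000).
#' @export
mask_count <- function(mask) sum(mask$data)

#' @rdname mask_count
#' @export
mask_volume_ml <- function(mask) {
  mask_count(mask) * prod(mask$grid$spacing) / 1000
}

#' Centre of mass of a mask in world coordinates
#' @param mask a [mask_volume()].
#' @return length-3 numeric, mm; `NA` for an empty mask.
#' @export
mask_com <- function(mask) {
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(rep(NA_real_, 3))
  colMeans(voxel_to_world(mask$grid, idx))
}

#' Labeled dural template
#'
#' A labeled 3D volume representing the dural domain: 0 = background,
#' 1 = convexity / skull-base shell, 2 = falx, 3 = tentorium.
#'
#' @param grid a [grid_spec()].
#' @param data 3D integer array with values in {0, 1, 2, 3}.
#' @param provenance free text describing where the template comes from.
#' @return An object of class `dural_template`.
#' @export
dural_template <- function(grid, data, provenance = "") {
  stopifnot(inherits(grid, "grid_spec"))
  data <- as.array(data)
  if (!identical(dim(data), grid$shape)) {
    stop("dural_template: data shape does not match grid shape", call. = FALSE)
  }
  if (!all(data %in% 0:3)) {
    stop("dural_template: labels must be in {0,1,2,3}", call. = FALSE)
  }
  data <- array(as.integer(data), dim = grid$shape)
  structure(list(grid = grid, data = data,
                 provenance = as.character(provenance)),
            class = "dural_template")
}

#' @export
print.dural_template <- function(x, ...) {
  tb <- table(factor(x$data, levels = 0:3,
                     labels = c("background", "shell", "falx", "tentorium")))
  cat("<dural_template> ", sum(x$data > 0), " dural voxels (shell ",
      tb[["shell"]], ", falx ", tb[["falx"]], ", tentorium ",
      tb[["tentorium"]], ")\n", sep = "")
  invisible(x)
}

dural_domain <- function(dura) dura$data > 0L
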