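#' Build a synthetic phantom space: brain ellipsoid plus dural template
#'
#' Constructs a deterministic stand-in for a template head: an ellipsoidal
#' "brain", a closed dural shell of configurable thickness around it, a
#' planar falx along the midline (upper interhemispheric plane), and a
#' planar tentorium over the posterior fossa.  The falx and tentorium
#' planes are carved out of the brain interior, so the dural domain and
#' the brain interior only meet along their shared boundary.  Dural voxels
#' are additionally partitioned into named compartments (falx, tentorium,
#' right/left convexity, frontal/posterior skull base) used by the cohort
#' generator's attachment sampling.
#'
#' @param grid_size integer triple, default `c(64, 64, 64)`.
#' @param brain_axes ellipsoid semi-axes in mm (x = left-right,
#'   y = posterior-anterior, z = inferior-superior), default
#'   `c(24, 27, 21)`.
#' @param shell_thickness dural shell thickness in mm (default 2).
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @return An object of class `phantom_space`: `grid`, `brain`
#'   ([mask_volume()]), `dura` ([dural_template()]), `compartments`
#'   (3D integer array), `compartment_names`, plus cached dural voxel
#'   indices.
#' @export
build_phantom_space <- function(grid_size = c(64, 64, 64),
                                brain_axes = c(24, 27, 21),
                                shell_thickness = 2,
                                spacing = c(1, 1, 1)) {
  grid <- grid_spec(grid_size, spacing = spacing)
  margin <- (grid$shape * grid$spacing) / 2 -
    (brain_axes + shell_thickness + 2 * grid$spacing)
  if (any(margin < 0)) {
    stop("build_phantom_space: brain does not fit in the grid with a ",
         "margin of shell_thickness + 2 voxels", call. = FALSE)
  }
  xs <- (seq_len(grid$shape[1]) - 1) * spacing[1] + grid$affine[1, 4]
  ys <- (seq_len(grid$shape[2]) - 1) * spacing[2] + grid$affine[2, 4]
  zs <- (seq_len(grid$shape[3]) - 1) * spacing[3] + grid$affine[3, 4]
  sq <- function(v, a) (v / a)^2
  rho_in <- outer(outer(sq(xs, brain_axes[1]), sq(ys, brain_axes[2]), `+`),
                  sq(zs, brain_axes[3]), `+`)
  out_axes <- brain_axes + shell_thickness
  rho_out <- outer(outer(sq(xs, out_axes[1]), sq(ys, out_axes[2]), `+`),
                   sq(zs, out_axes[3]), `+`)
  inner <- rho_in <= 1
  outer_e <- rho_out <= 1
  shell <- outer_e & !inner

  half <- spacing[1] / 2 + 1e-9
  falx_plane <- abs(xs - grid$midline_plane) <= half
  z_falx_floor <- -brain_axes[3] / 4
  falx <- outer(outer(falx_plane, rep(TRUE, grid$shape[2]), `&`),
                zs >= z_falx_floor, `&`) & outer_e
  z_tent <- -brain_axes[3] / 3
  tent_plane <- abs(zs - z_tent) <= spacing[3] / 2 + 1e-9
  tent <- outer(outer(rep(TRUE, grid$shape[1]), ys <= 0, `&`),
                tent_plane, `&`) & outer_e

  labels <- array(0L, dim = grid$shape)
  labels[shell] <- 1L
  labels[tent] <- 3L
  labels[falx] <- 2L
  brain_data <- inner & labels == 0L

  comp_names <- c("right_convexity", "left_convexity", "frontal_base",
                  "posterior_base", "falx", "tentorium")
  comp <- array(0L, dim = grid$shape)
  xw <- array(rep(xs, times = prod(grid$shape[2:3])), dim = grid$shape)
  yw <- aperm(array(rep(ys, times = prod(grid$shape[c(1, 3)])),
                    dim = grid$shape[c(2, 1, 3)]), c(2, 1, 3))
  zw <- aperm(array(rep(zs, times = prod(grid$shape[1:2])),
                    dim = grid$shape[c(3, 1, 2)]), c(2, 3, 1))
  is_shell <- labels == 1L
  base <- is_shell & zw < -0.3 * brain_axes[3]
  comp[is_shell & !base & xw >= 0] <- 1L
  comp[is_shell & !base & xw < 0] <- 2L
  comp[base & yw >= 0] <- 3L
  comp[base & yw < 0] <- 4L
  comp[labels == 2L] <- 5L
  comp[labels == 3L] <- 6L

  dural_index <- which(labels > 0L)
  structure(
    list(grid = grid,
         brain = mask_volume(grid, brain_data, label = "phantom_brain"),
         dura = dural_template(grid, labels, provenance = "synthetic phantom"),
         compartments = comp,
         compartment_names = comp_names,
         dural_index = dural_index,
         dural_compartment = comp[dural_index],
         brain_axes = brain_axes,
         shell_thickness = shell_thickness),
    class = "phantom_space"
  )
}

#' @export
print.phantom_space <- function(x, ...) {
  cat("<phantom_space> brain ", mask_count(x$brain), " voxels, dura ",
      length(x$dural_index), " voxels on ",
      paste(x$grid$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Locate a dural surface point along a world-space direction
#'
#' Utility for placing hotspots: returns the world coordinate where the
#' ray from the origin along `direction` crosses the middle of the dural
#' shell.
#'
#' @param space a [build_phantom_space()] result.
#' @param direction length-3 direction vector (need not be normalized).
#' @return Length-3 world coordinate in mm.
#' @export
dural_point <- function(space, direction) {
  d <- direction / sqrt(sum(direction^2))
  axes <- space$brain_axes + space$shell_thickness / 2
  t <- 1 / sqrt(sum((d / axes)^2))
  t * d
}

#' Grow a synthetic extra-axial tumor from a dural attachment point
#'
#' The tumor is a ball of the given radius around the attachment voxel,
#' clipped to the intracranial + dural domain (brain union dura) —
#' emulating displacing, non-infiltrating extra-axial growth without
#' modeling mass effect.  The result always contains its attachment voxel.
#'
#' @param space a [build_phantom_space()] result.
#' @param attachment length-3 voxel index (1-based) on the dural domain.
#' @param radius_mm ball radius in mm (> 0); radii below one voxel give a
#'   single-voxel mask.
#' @param label mask label.
#' @return A [mask_volume()].
#' @export
grow_tumor <- function(space, attachment, radius_mm, label = "tumor") {
  grid <- space$grid
  attachment <- as.integer(attachment)
  stopifnot(length(attachment) == 3L, radius_mm > 0)
  if (space$dura$data[attachment[1], attachment[2], attachment[3]] == 0L) {
    stop("grow_tumor: attachment voxel is not on the dural domain",
         call. = FALSE)
  }
  centre <- voxel_to_world(grid, attachment)[1, ]
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, attachment[ax] - ceiling(radius_mm / grid$spacing[ax]))
    hi <- min(grid$shape[ax], attachment[ax] + ceiling(radius_mm / grid$spacing[ax]))
    lo:hi
  })
  sub_idx <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  w <- voxel_to_world(grid, sub_idx)
  inside <- rowSums(sweep(w, 2, centre)^2) <= radius_mm^2
  data <- array(0L, dim = grid$shape)
  data[sub_idx[inside, , drop = FALSE]] <- 1L
  domain <- space$brain$data == 1L | dural_domain(space$dura)
  data[!domain] <- 0L
  data[attachment[1], attachment[2], attachment[3]] <- 1L
  mask_volume(grid, data, label = label)
}

#' Specification of a synthetic phantom cohort
#'
#' Defines the simulated study conditions: cohort size, the lognormal
#' tumor-volume law, where tumors attach on the dura, and how the binary
#' endpoint depends on attachment location and/or total volume.  Endpoint
#' probabilities follow
#' `logit(q) = logit(p0) + hot * (logit(p1) - logit(p0)) +
#'  volume_effect * (volume - cohort mean)`.
#'
#' @param n_patients cohort size (>= 1).
#' @param mean_volume_ml,sd_volume_ml targets of the lognormal volume law.
#'   Defaults: 4 ml mean at the 64-voxel desk scale, with the coefficient
#'   of variation of a published meningioma cohort (sd/mean = 17.6/31.6).
#' @param attachment_weights named non-negative weights over compartment
#'   names (see [build_phantom_space()]); `NULL` = uniform over all dural
#'   voxels.
#' @param hot_region either a compartment name, or a list
#'   `list(center = <world mm>, radius_mm = <mm>)` defining a spherical
#'   hot region; `NULL` for none.
#' @param hot_fraction fraction of patients whose attachment is drawn
#'   uniformly from the hot region (location hotspot); the rest follow
#'   `attachment_weights`.
#' @param p0 baseline endpoint probability (attachment outside the hot
#'   region).
#' @param p1 endpoint probability for hot-region attachment.
#' @param volume_effect logistic slope per ml of tumor volume (0 = no
#'   volume confound).
#' @param seed integer seed driving all cohort randomness.
#' @return A list of class `phantom_cohort_spec`.
#' @export
phantom_cohort_spec <- function(n_patients = 60,
                                mean_volume_ml = 4,
                                sd_volume_ml = mean_volume_ml * 17.6 / 31.6,
                                attachment_weights = NULL,
                                hot_region = NULL,
                                hot_fraction = 0,
                                p0 = 0.3, p1 = p0,
                                volume_effect = 0,
                                seed = 1) {
  stopifnot(n_patients >= 1, p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1,
            hot_fraction >= 0, hot_fraction <= 1,
            mean_volume_ml > 0, sd_volume_ml > 0)
  if (!is.null(attachment_weights)) {
    stopifnot(all(attachment_weights >= 0), any(attachment_weights > 0))
  }
  structure(
    list(n_patients = as.integer(n_patients),
         mean_volume_ml = mean_volume_ml, sd_volume_ml = sd_volume_ml,
         attachment_weights = attachment_weights,
         hot_region = hot_region, hot_fraction = hot_fraction,
         p0 = p0, p1 = p1, volume_effect = volume_effect,
         seed = as.integer(seed)),
    class = "phantom_cohort_spec"
  )
}

# Hot-region membership of attachment voxels (n x 3 index matrix).
hot_membership <- function(space, attachments, hot_region) {
  if (is.null(hot_region)) return(rep(FALSE, nrow(attachments)))
  if (is.character(hot_region)) {
    comp_id <- match(hot_region, space$compartment_names)
    if (is.na(comp_id)) {
      stop("unknown compartment: ", hot_region, call. = FALSE)
    }
    return(space$compartments[attachments] == comp_id)
  }
  w <- voxel_to_world(space$grid, attachments)
  rowSums(sweep(w, 2, hot_region$center)^2) <= hot_region$radius_mm^2
}

#' Centroid of the implanted hot dural region
#'
#' The implanted hot region is the set of dural voxels selected by
#' `hot_region` (compartment or sphere); its centroid in world mm is the
#' reference point for localization-recovery experiments.  For a sphere
#' this differs from the sphere centre, which lies on the curved shell
#' while the voxel set's centroid is pulled toward the brain's interior.
#'
#' @param space a [build_phantom_space()] result.
#' @param hot_region as in [phantom_cohort_spec()].
#' @return Length-3 world coordinate in mm.
#' @export
hot_region_centroid <- function(space, hot_region) {
  idx <- arrayInd(space$dural_index, space$grid$shape)
  hot <- hot_membership(space, idx, hot_region)
  if (!any(hot)) stop("hot_region_centroid: empty hot region", call. = FALSE)
  colMeans(voxel_to_world(space$grid, idx[hot, , drop = FALSE]))
}

#' Simulate binary endpoints for a phantom cohort
#'
#' Draws one Bernoulli endpoint per patient with
#' `logit(q) = logit(p0) + hot * (logit(p1) - logit(p0)) +
#'  volume_effect * (volume - mean(volume))`; probabilities escaping
#' (0, 1) after the volume term are clamped to `[0.001, 0.999]` with a
#' warning.
#'
#' @param space a [build_phantom_space()] result.
#' @param attachments n x 3 matrix of attachment voxel indices.
#' @param volumes_ml per-patient tumor volumes in ml.
#' @param spec a [phantom_cohort_spec()].
#' @param seed seed for the endpoint draws; `NULL` uses the current RNG
#'   stream (as inside [generate_cohort()]).
#' @return Integer 0/1 vector with attribute `"hot"` (logical membership)
#'   and `"prob"` (the per-patient Bernoulli probabilities).
#' @export
simulate_outcomes <- function(space, attachments, volumes_ml, spec,
                              seed = spec$seed) {
  if (is.null(dim(attachments))) attachments <- matrix(attachments, nrow = 1)
  stopifnot(nrow(attachments) == length(volumes_ml))
  hot <- hot_membership(space, attachments, spec$hot_region)
  eta <- stats::qlogis(spec$p0) +
    hot * (stats::qlogis(spec$p1) - stats::qlogis(spec$p0)) +
    spec$volume_effect * (volumes_ml - mean(volumes_ml))
  q <- stats::plogis(eta)
  if (any(q < 0.001 | q > 0.999)) {
    warning("simulate_outcomes: endpoint probabilities clamped to ",
            "[0.001, 0.999]", call. = FALSE)
    q <- pmin(pmax(q, 0.001), 0.999)
  }
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rbinom(length(q), 1L, q)
  attr(y, "hot") <- hot
  attr(y, "prob") <- q
  y
}

#' Generate a complete synthetic cohort
#'
#' Samples per-patient tumor volumes from the lognormal law, attachment
#' points from the attachment law (hot-region oversampling plus
#' compartment weights), grows the tumors, and simulates the endpoint.
#' All randomness is driven by `spec$seed`, so a fixed spec reproduces the
#' cohort exactly.
#'
#' @param space a [build_phantom_space()] result.
#' @param spec a [phantom_cohort_spec()].
#' @return An object of class `phantom_cohort`: `masks` (list of
#'   [mask_volume()]), `table` (tibble: `patient_id`, `endpoint`,
#'   `volume_ml`), `truth` (tibble with attachment indices, compartment,
#'   hot membership, radii, sampled and realized mask volumes), `space`,
#'   `spec`.
#' @export
generate_cohort <- function(space, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_patients

  cv2 <- (spec$sd_volume_ml / spec$mean_volume_ml)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(spec$mean_volume_ml) - sdlog^2 / 2
  volumes <- stats::rlnorm(n, meanlog, sdlog)
  radii <- (3 * volumes * 1000 / (4 * pi))^(1 / 3)

  hot_pool <- if (!is.null(spec$hot_region)) {
    all_idx <- arrayInd(space$dural_index, space$grid$shape)
    space$dural_index[hot_membership(space, all_idx, spec$hot_region)]
  } else integer(0)
  if (spec$hot_fraction > 0 && length(hot_pool) == 0L) {
    stop("generate_cohort: hot_fraction > 0 but the hot region contains ",
         "no dural voxel", call. = FALSE)
  }

  draw_background <- function() {
    if (is.null(spec$attachment_weights)) {
      sample(space$dural_index, 1L)
    } else {
      w <- spec$attachment_weights
      comp_id <- match(names(w), space$compartment_names)
      if (anyNA(comp_id)) {
        stop("generate_cohort: unknown compartment in attachment_weights: ",
             paste(names(w)[is.na(comp_id)], collapse = ", "), call. = FALSE)
      }
      cid <- comp_id[sample.int(length(w), 1L, prob = w)]
      pool <- space$dural_index[space$dural_compartment == cid]
      pool[sample.int(length(pool), 1L)]
    }
  }
  is_hot_draw <- stats::runif(n) < spec$hot_fraction
  att_lin <- vapply(seq_len(n), function(i) {
    if (is_hot_draw[i]) hot_pool[sample.int(length(hot_pool), 1L)]
    else draw_background()
  }, integer(1))
  attachments <- arrayInd(att_lin, space$grid$shape)

  ids <- sprintf("P%03d", seq_len(n))
  masks <- lapply(seq_len(n), function(i) {
    grow_tumor(space, attachments[i, ], radii[i], label = ids[i])
  })
  endpoint <- simulate_outcomes(space, attachments, volumes, spec,
                                seed = NULL)
  truth <- tibble::tibble(
    patient_id = ids,
    ai = attachments[, 1], aj = attachments[, 2], ak = attachments[, 3],
    compartment = space$compartment_names[space$dural_compartment[
      match(att_lin, space$dural_index)]],
    hot = attr(endpoint, "hot"),
    radius_mm = radii,
    volume_ml = volumes,
    mask_volume_ml = vapply(masks, mask_volume_ml, numeric(1)),
    prob = attr(endpoint, "prob")
  )
  tbl <- tibble::tibble(patient_id = ids,
                        endpoint = as.integer(endpoint),
                        volume_ml = volumes)
  structure(list(masks = masks, table = tbl, truth = truth,
                 space = space, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> n = ", nrow(x$table), ", endpoint prevalence ",
      signif(mean(x$table$endpoint), 3), ", mean volume ",
      signif(mean(x$table$volume_ml), 3), " ml\n", sep = "")
  invisible(x)
}

#' Preset phantom study conditions
#'
#' Three canonical simulation scenarios on the desk-scale 64-voxel
#' phantom:
#' \describe{
#'   \item{null}{no lesion-endpoint association (`p0 = p1 = 0.3`, no
#'     volume effect) — used for error-rate calibration.}
#'   \item{hotspot}{a 6 mm spherical hot region on the right convexity;
#'     half the attachments fall in it, with endpoint probability 0.6
#'     inside versus 0.1 outside — used for recovery experiments.}
#'   \item{volume-confound}{endpoint driven only by tumor volume: 6 ml
#'     mean volume and logistic slope 1.5 per ml, making the endpoint
#'     nearly a step function of volume (as decisive as the clinical
#'     size-grade association) — used to reproduce the volume-bias
#'     contrast between whole-tumor and attachment-zone mapping.}
#' }
#'
#' @param preset one of `"null"`, `"hotspot"`, `"volume-confound"`.
#' @param n cohort size (default 60).
#' @param seed cohort seed.
#' @param space optionally a prebuilt [build_phantom_space()]; default
#'   builds the 64-voxel desk-scale space.
#' @return A list with `space`, `spec`, and (for `"hotspot"`) the
#'   hot-region definition.
#' @export
phantom_preset <- function(preset = c("null", "hotspot", "volume-confound"),
                           n = 60, seed = 1, space = NULL) {
  preset <- match.arg(preset)
  if (is.null(space)) space <- build_phantom_space()
  spec <- switch(preset,
    "null" = phantom_cohort_spec(n_patients = n, p0 = 0.3, seed = seed),
    "hotspot" = {
      hot <- list(center = dural_point(space, c(1, 0, 0.25)),
                  radius_mm = 6)
      phantom_cohort_spec(n_patients = n, hot_region = hot,
                          hot_fraction = 0.5, p0 = 0.1, p1 = 0.6,
                          seed = seed)
    },
    "volume-confound" = phantom_cohort_spec(n_patients = n,
                                            mean_volume_ml = 6,
                                            p0 = 0.3, volume_effect = 1.5,
                                            seed = seed)
  )
  list(space = space, spec = spec, hot_region = spec$hot_region)
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI mask per patient, the dural template, the cohort TSV
#' (`patient_id`, `mask`, `endpoint`, `volume_ml`), and a JSON truth
#' sidecar sufficient to recover hot-region membership and the implanted
#' effect without re-simulation.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, a list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_paths <- file.path(dir, paste0(cohort$table$patient_id, ".nii.gz"))
  for (i in seq_along(cohort$masks)) {
    write_volume(cohort$masks[[i]], mask_paths[i])
  }
  dura_path <- file.path(dir, "dural_template.nii.gz")
  write_volume(cohort$space$dura, dura_path)
  tbl <- cohort$table
  tbl$mask <- basename(mask_paths)
  tbl <- tbl[, c("patient_id", "mask", "endpoint", "volume_ml")]
  table_path <- file.path(dir, "cohort.tsv")
  utils::write.table(tbl, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- list(spec = unclass(cohort$spec), truth = cohort$truth)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(masks = mask_paths, dura = dura_path,
                 table = table_path, truth = truth_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.tsv`, the masks, and
#'   `dural_template.nii.gz`.
#' @return A list with `masks`, `table`, `dura`.
#' @export
read_cohort <- function(dir) {
  table_path <- file.path(dir, "cohort.tsv")
  if (!file.exists(table_path)) {
    stop("read_cohort: no cohort.tsv in ", dir, call. = FALSE)
  }
  tbl <- tibble::as_tibble(utils::read.delim(table_path,
                                             check.names = FALSE))
  masks <- lapply(seq_len(nrow(tbl)), function(i) {
    read_mask(file.path(dir, tbl$mask[i]), label = tbl$patient_id[i])
  })
  dura_path <- file.path(dir, "dural_template.nii.gz")
  dura <- if (file.exists(dura_path)) read_dural_template(dura_path) else NULL
  list(masks = masks, table = tbl, dura = dura)
}
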