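#' Assemble the cohort lesion matrix with a minimum-overlap filter
#'
#' Builds the patients x voxels binary design used by voxel-wise mapping.
#' Only voxels lesioned in at least `min_overlap` patients are included,
#' which avoids statistically unstable estimates at sparsely sampled voxels
#' (the published cohort-scale default is 10 patients).
#'
#' @param masks nonempty list of [mask_volume()] objects on a shared grid.
#' @param min_overlap minimum number of patients lesioned at a voxel for it
#'   to enter the analysis (>= 1; default 10).
#' @param patient_ids optional character vector of row ids; defaults to the
#'   mask labels.
#' @return An object of class `lesion_matrix`: `L` (n x m 0/1 matrix),
#'   `voxel_index` (m x 3 matrix of 1-based voxel indices), `patients`,
#'   `n_lesioned` (column sums), `min_overlap`, `grid`.
#' @export
assemble_lesion_matrix <- function(masks, min_overlap = 10,
                                   patient_ids = NULL) {
  stopifnot(min_overlap >= 1)
  grid <- validate_cohort_grid(masks)
  fm <- frequency_map(masks)
  keep <- which(fm$counts >= min_overlap)
  if (length(keep) == 0L) {
    stop("assemble_lesion_matrix: no voxel is lesioned in at least ",
         min_overlap, " patients (max observed overlap: ", max(fm$counts),
         ")", call. = FALSE)
  }
  if (is.null(patient_ids)) patient_ids <- vapply(masks, `[[`, "", "label")
  n <- length(masks)
  L <- matrix(0L, nrow = n, ncol = length(keep),
              dimnames = list(patient_ids, NULL))
  for (i in seq_len(n)) L[i, ] <- masks[[i]]$data[keep]
  structure(
    list(L = L,
         voxel_index = arrayInd(keep, grid$shape),
         linear_index = keep,
         patients = patient_ids,
         n_lesioned = colSums(L),
         min_overlap = as.integer(min_overlap),
         grid = grid),
    class = "lesion_matrix"
  )
}

#' @export
print.lesion_matrix <- function(x, ...) {
  cat("<lesion_matrix> ", nrow(x$L), " patients x ", ncol(x$L),
      " voxels (min overlap ", x$min_overlap, ")\n", sep = "")
  invisible(x)
}

# Vectorized per-voxel regression t-statistics for a binary design.
# For each column of L, the slope t of lm(y ~ L[, v]) equals the pooled
# two-sample t comparing y between lesioned and non-lesioned patients;
# both are computed here in closed form from group sums.  Y may hold
# several outcome vectors (columns), e.g. permuted copies.
# Returns list(t = m x B matrix, degenerate = m logical), with t = 0 at
# degenerate columns (constant predictor or zero residual variance).
lesion_t_stats <- function(L, Y) {
  Y <- as.matrix(Y)
  n <- nrow(L)
  stopifnot(nrow(Y) == n)
  n1 <- colSums(L)
  n0 <- n - n1
  const_pred <- n1 == 0L | n1 == n
  S <- colSums(Y)
  Q <- colSums(Y^2)
  s1 <- crossprod(L, Y)                  # m x B sums of y over lesioned
  q1 <- crossprod(L, Y^2)
  s0 <- sweep(-s1, 2, S, `+`)
  q0 <- sweep(-q1, 2, Q, `+`)
  m1 <- s1 / n1
  m0 <- s0 / n0
  sse <- pmax(q1 - s1^2 / n1, 0) + pmax(q0 - s0^2 / n0, 0)
  se2 <- sse / (n - 2) * (1 / n1 + 1 / n0)
  tol <- 1e-12 * pmax(Q, 1)
  zero_var <- sweep(sse, 2, tol, `<=`)
  tt <- (m1 - m0) / sqrt(se2)
  tt[const_pred, ] <- 0
  tt[zero_var] <- 0
  degenerate <- const_pred | apply(zero_var, 1, any)
  list(t = tt, degenerate = degenerate, df = n - 2L)
}

#' Voxel-wise univariable regression mapping
#'
#' For every included voxel v, fits the univariable linear model
#' `outcome = b0 + b1 * lesion(v)` and reports the slope t-statistic with
#' n - 2 degrees of freedom, the one-sided p-value, and the standardized
#' Z-score (normal quantile of 1 - p).  For a binary lesion indicator this
#' t equals the pooled two-sample t comparing lesioned and non-lesioned
#' patients.  A positive Z means the observational group (outcome coded 1)
#' is enriched among patients lesioned at that voxel; `direction =
#' "negative"` tests the opposite tail.
#'
#' Degenerate voxels (constant lesion column, or zero residual variance,
#' e.g. perfect separation) get z = 0 and are flagged for exclusion from
#' inference rather than carried as infinities.
#'
#' @param Lm a [assemble_lesion_matrix()] result.
#' @param outcome numeric per-patient vector (dummy-coded 0/1 endpoint or a
#'   continuous outcome); must not be constant.
#' @param direction `"positive"` (default) or `"negative"` tail.
#' @param z_clamp absolute bound on |z| to keep extreme quantiles finite
#'   (default 8.2).
#' @return An object of class `stat_map` with a per-voxel tibble
#'   (`stats`), the 3D `included` mask, `df`, `grid`.
#' @export
voxelwise_glm <- function(Lm, outcome, direction = c("positive", "negative"),
                          z_clamp = 8.2) {
  direction <- match.arg(direction)
  stopifnot(inherits(Lm, "lesion_matrix"))
  if (length(outcome) != nrow(Lm$L)) {
    stop("voxelwise_glm: outcome length (", length(outcome),
         ") does not match number of patients (", nrow(Lm$L), ")",
         call. = FALSE)
  }
  if (anyNA(outcome)) {
    stop("voxelwise_glm: outcome contains missing values; drop those ",
         "patients and rebuild the lesion matrix", call. = FALSE)
  }
  if (stats::var(outcome) == 0) {
    stop("voxelwise_glm: outcome is constant", call. = FALSE)
  }
  ts <- lesion_t_stats(Lm$L, matrix(outcome, ncol = 1))
  tv <- as.numeric(ts$t)
  if (direction == "negative") tv <- -tv
  df <- ts$df
  p <- stats::pt(tv, df = df, lower.tail = FALSE)
  z <- stats::qnorm(p, lower.tail = FALSE)
  z <- pmin(pmax(z, -z_clamp), z_clamp)
  z[ts$degenerate] <- 0
  p[ts$degenerate] <- NA_real_
  included <- array(FALSE, dim = Lm$grid$shape)
  included[Lm$linear_index] <- TRUE
  stats_tbl <- tibble::tibble(
    i = Lm$voxel_index[, 1], j = Lm$voxel_index[, 2], k = Lm$voxel_index[, 3],
    n_lesioned = as.integer(Lm$n_lesioned),
    t = tv, p = p, z = z,
    degenerate = ts$degenerate
  )
  structure(
    list(grid = Lm$grid, stats = stats_tbl, df = df,
         linear_index = Lm$linear_index, included = included,
         n_patients = nrow(Lm$L), direction = direction),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- !x$stats$degenerate
  cat("<stat_map> ", nrow(x$stats), " voxels (", sum(!ok), " degenerate), df = ",
      x$df, ", max z = ", signif(max(x$stats$z[ok], -Inf), 4), "\n", sep = "")
  invisible(x)
}

#' Materialize a stat-map column as a 3D volume
#'
#' @param sm a [voxelwise_glm()] result.
#' @param what one of `"z"`, `"t"`, `"p"`, `"n_lesioned"`.
#' @param fill value outside the included voxels (default 0; `NA` is often
#'   right for p-maps).
#' @return A list with `grid` and `data` (3D array), writable with
#'   [write_volume()].
#' @export
stat_map_volume <- function(sm, what = c("z", "t", "p", "n_lesioned"),
                            fill = 0) {
  what <- match.arg(what)
  vol <- array(as.numeric(fill), dim = sm$grid$shape)
  vol[sm$linear_index] <- sm$stats[[what]]
  list(grid = sm$grid, data = vol)
}

#' Dummy-code a two-level categorical endpoint
#'
#' Maps the reference category to 0 and the single other category to 1
#' (0 = reference group, 1 = observational group).  Endpoints with more
#' than two levels must be binarized explicitly by the caller (e.g.
#' resection completeness dichotomized at Simpson grade > 3).
#'
#' @param raw_column vector of categorical values; missing values are
#'   dropped from the level count and propagated as `NA`.
#' @param reference the reference category (coded 0).
#' @return Integer 0/1 vector with attribute `"mapping"` (named vector
#'   recording the code of each level).
#' @export
dummy_code <- function(raw_column, reference) {
  lev <- unique(raw_column[!is.na(raw_column)])
  if (length(lev) != 2L) {
    stop("dummy_code: expected exactly 2 categories, got ", length(lev),
         " (", paste(utils::head(lev, 5), collapse = ", "),
         "); binarize the endpoint explicitly first", call. = FALSE)
  }
  if (!reference %in% lev) {
    stop("dummy_code: reference level '", reference,
         "' not present in the data", call. = FALSE)
  }
  other <- setdiff(as.character(lev), as.character(reference))
  out <- ifelse(is.na(raw_column), NA_integer_,
                ifelse(as.character(raw_column) == as.character(reference),
                       0L, 1L))
  attr(out, "mapping") <- stats::setNames(c(0L, 1L),
                                          c(as.character(reference), other))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a voxel-wise stat map into a per-voxel tibble
#'
#' @param x a `stat_map`.
#' @param ... unused.
#' @return Tibble with voxel indices, lesion counts, `t`, `p`, `z`, and
#'   the degeneracy flag.
#' @export
tidy.stat_map <- function(x, ...) x$stats

#' One-row summary of a voxel-wise stat map
#'
#' @param x a `stat_map`.
#' @param ... unused.
#' @return Tibble with the number of patients, included and degenerate
#'   voxel counts, degrees of freedom, and the maximum Z.
#' @export
glance.stat_map <- function(x, ...) {
  ok <- !x$stats$degenerate
  tibble::tibble(
    n_patients = x$n_patients,
    n_voxels = nrow(x$stats),
    n_degenerate = sum(!ok),
    df = x$df,
    max_z = if (any(ok)) max(x$stats$z[ok]) else NA_real_,
    min_p = if (any(ok)) min(x$stats$p[ok]) else NA_real_
  )
}
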