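#' TFCE tuning parameters
#'
#' Height exponent `H = 2` and extent exponent `E = 0.5` are the standard
#' choices for 3D statistic maps and the defaults here.  `dh` is the
#' threshold step of the discretized enhancement integral; `NULL` means
#' "max observed statistic / 100", the common practice.
#'
#' @param H height exponent (>= 0, default 2).
#' @param E extent exponent (>= 0, default 0.5).
#' @param dh threshold step (> 0), or `NULL` for max/100.
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26, the
#'   standard for 3D cluster-based neuroimaging inference).
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  stopifnot(H >= 0, E >= 0, is.null(dh) || dh > 0,
            connectivity %in% c(6, 18, 26))
  structure(list(H = H, E = E, dh = dh, connectivity = connectivity),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement (TFCE)
#'
#' Enhances a voxel-wise statistic map by integrating cluster support over
#' all thresholds, avoiding an arbitrary cluster-forming threshold:
#' `TFCE(v) = sum_{h = dh, 2dh, ... <= z(v)} e(h,v)^E * h^H * dh`, where
#' `e(h,v)` is the voxel extent of the connected component containing `v`
#' in the supra-threshold set `{z >= h}`.  Enhancement is one-sided:
#' negative values are treated as 0, matching one-tailed mapping; enhance
#' `-z` separately for the opposite tail.
#'
#' @param stat_map a `stat_map` from [voxelwise_glm()] (degenerate voxels
#'   enter as 0), or a 3D numeric array.
#' @param params a [tfce_params()].
#' @return If given an array, the 3D array of TFCE scores; if given a
#'   `stat_map`, a list with `grid` and `data` (writable with
#'   [write_volume()]).
#' @export
tfce <- function(stat_map, params = tfce_params()) {
  is_sm <- inherits(stat_map, "stat_map")
  z <- if (is_sm) stat_map_volume(stat_map, "z")$data else stat_map
  stopifnot(length(dim(z)) == 3L, all(is.finite(z)))
  z <- pmax(z, 0)
  dh <- params$dh
  if (is.null(dh)) {
    mx <- max(z)
    if (mx == 0) {
      out <- array(0, dim = dim(z))
      return(if (is_sm) list(grid = stat_map$grid, data = out) else out)
    }
    dh <- mx / 100
  }
  out <- .tfce_transform(as.numeric(z), as.integer(dim(z)),
                         params$H, params$E, dh,
                         as.integer(params$connectivity))
  if (is_sm) list(grid = stat_map$grid, data = out) else out
}

new_correction_result <- function(method, alpha, sm, significant_vec,
                                  critical_value, p_corrected = NULL,
                                  score = NULL, null_max = NULL) {
  sig_vol <- array(FALSE, dim = sm$grid$shape)
  sig_vol[sm$linear_index] <- significant_vec
  tbl <- sm$stats[, c("i", "j", "k", "n_lesioned", "z", "p", "degenerate")]
  if (!is.null(score)) tbl$score <- score
  if (!is.null(p_corrected)) tbl$p_corrected <- p_corrected
  tbl$significant <- significant_vec
  structure(
    list(method = method, alpha = alpha, voxels = tbl,
         significant = sig_vol, critical_value = critical_value,
         null_max = null_max, grid = sm$grid,
         linear_index = sm$linear_index),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> ", x$method, ": ", sum(x$voxels$significant),
      " / ", nrow(x$voxels), " voxels significant at alpha = ", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni correction of a voxel-wise p-map
#'
#' Family-wise error control by the per-voxel threshold `alpha / m`, where
#' `m` is the number of (non-degenerate) included voxels.  Simple and
#' widely reported, but conservative at whole-brain voxel counts.
#'
#' @param sm a `stat_map` from [voxelwise_glm()].
#' @param alpha family-wise error level (default 0.05).
#' @param m number of comparisons; defaults to the number of
#'   non-degenerate included voxels.
#' @return A `correction_result`; `critical_value` is the per-voxel p
#'   threshold `alpha / m`.
#' @export
bonferroni <- function(sm, alpha = 0.05, m = NULL) {
  ok <- !sm$stats$degenerate
  if (is.null(m)) m <- sum(ok)
  if (m < 1) stop("bonferroni: no testable voxels (m = 0)", call. = FALSE)
  crit <- alpha / m
  sig <- ok & !is.na(sm$stats$p) & sm$stats$p < crit
  new_correction_result("bonferroni", alpha, sm, sig, crit)
}

#' Benjamini-Hochberg FDR correction of a voxel-wise p-map
#'
#' Standard step-up procedure controlling the expected proportion of false
#' positives among the declared voxels: sort the m p-values ascending,
#' find the largest k with `p(k) <= k * alpha / m`, and reject the k
#' smallest.
#'
#' @param sm a `stat_map` from [voxelwise_glm()], or a bare numeric vector
#'   of p-values.
#' @param alpha FDR level (default 0.05).
#' @return A `correction_result` (or, for a bare p-vector, a list with
#'   `significant` logical vector and `critical_value`); `critical_value`
#'   is `p(k)` (0 if nothing is rejected).
#' @export
bh_fdr <- function(sm, alpha = 0.05) {
  if (is.numeric(sm)) {
    sig <- bh_reject(sm, alpha)
    return(list(significant = sig,
                critical_value = if (any(sig)) max(sm[sig]) else 0))
  }
  ok <- !sm$stats$degenerate & !is.na(sm$stats$p)
  p <- sm$stats$p[ok]
  sig_ok <- bh_reject(p, alpha)
  sig <- logical(nrow(sm$stats))
  sig[ok] <- sig_ok
  crit <- if (any(sig_ok)) max(p[sig_ok]) else 0
  new_correction_result("fdr", alpha, sm, sig, crit)
}

# BH step-up via the standard adjusted p-values (stats::p.adjust).
bh_reject <- function(p, alpha) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) == 0L) return(logical(0))
  stats::p.adjust(p, method = "BH") <= alpha
}

#' Max-statistic permutation correction (maxZ or maxTFCE)
#'
#' Family-wise error control by permutation: the outcome vector is
#' permuted jointly across all voxels (preserving the lesion maps' spatial
#' covariance), the voxel-wise map is recomputed for each permutation, and
#' the map maximum is recorded.  The corrected p-value at voxel v is
#' `(1 + #{b : null_max_b >= obs(v)}) / (B + 1)`, never 0, with ties
#' counted as exceedances (conservative).  With `statistic = "maxtfce"`
#' the observed and permuted maps are TFCE-enhanced before taking maxima.
#'
#' @param Lm a [assemble_lesion_matrix()] result.
#' @param outcome per-patient numeric vector.
#' @param n_permutations number of permutations B (default 5000).
#' @param seed integer seed for the permutation stream.
#' @param statistic `"maxz"` or `"maxtfce"`.
#' @param tfce a [tfce_params()]; its `dh` (if `NULL`) is fixed to
#'   max observed z / 100 and reused across permutations so observed and
#'   null maps share one enhancement scale.
#' @param alpha significance level on corrected p (default 0.05).
#' @param direction tail passed to [voxelwise_glm()].
#' @param z_clamp passed to [voxelwise_glm()].
#' @return A `correction_result`; `null_max` holds the B permutation
#'   maxima, `critical_value` the `1 - alpha` quantile of `null_max`.
#' @export
permutation_correct <- function(Lm, outcome, n_permutations = 5000,
                                seed = 1, statistic = c("maxz", "maxtfce"),
                                tfce = tfce_params(), alpha = 0.05,
                                direction = "positive", z_clamp = 8.2) {
  statistic <- match.arg(statistic)
  if (n_permutations < 1) {
    stop("permutation_correct: need at least 1 permutation", call. = FALSE)
  }
  B <- as.integer(n_permutations)
  sm <- voxelwise_glm(Lm, outcome, direction = direction, z_clamp = z_clamp)
  ok <- !sm$stats$degenerate
  df <- sm$df
  sign_flip <- if (direction == "negative") -1 else 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Y <- vapply(seq_len(B), function(b) sample(outcome), numeric(length(outcome)))

  t_to_z <- function(tt) {
    z <- stats::qnorm(stats::pt(tt, df = df, lower.tail = FALSE),
                      lower.tail = FALSE)
    pmin(pmax(z, -z_clamp), z_clamp)
  }

  if (statistic == "maxz") {
    obs <- sm$stats$z
    obs[!ok] <- -Inf
    TT <- lesion_t_stats(Lm$L, Y)
    Znull <- t_to_z(sign_flip * TT$t)
    Znull[!ok, ] <- -Inf
    null_max <- apply(Znull, 2, max)
  } else {
    zvol <- stat_map_volume(sm, "z")$data
    if (is.null(tfce$dh)) {
      tfce$dh <- max(max(zvol, 0) / 100, .Machine$double.eps)
    }
    obs_vol <- tfce(zvol, tfce)
    obs <- obs_vol[Lm$linear_index]
    obs[!ok] <- -Inf
    TT <- lesion_t_stats(Lm$L, Y)
    Znull <- t_to_z(sign_flip * TT$t)
    Znull[!ok, ] <- 0
    null_max <- numeric(B)
    vol <- array(0, dim = Lm$grid$shape)
    for (b in seq_len(B)) {
      vol[Lm$linear_index] <- Znull[, b]
      null_max[b] <- max(tfce(vol, tfce))
    }
  }

  # corrected p via the sorted null maxima: #(null >= obs) = B - #(null < obs)
  sorted <- sort(null_max)
  n_lt <- findInterval(obs, sorted, left.open = TRUE)
  p_corr <- (1 + (B - n_lt)) / (B + 1)
  p_corr[!ok] <- 1
  sig <- ok & p_corr <= alpha
  crit <- stats::quantile(null_max, probs = 1 - alpha, names = FALSE,
                          type = 1)
  obs_out <- obs
  obs_out[!ok] <- 0
  new_correction_result(
    if (statistic == "maxz") "maxz-perm" else "tfce-perm",
    alpha, sm, sig, crit, p_corrected = p_corr, score = obs_out,
    null_max = null_max
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Centre of mass of the significant voxels of a correction result
#'
#' Recovery experiments compare where a correction method localizes an
#' effect.  By default the centre of mass (world mm) of the largest
#' 26-connected significant cluster is returned — the natural summary of
#' "where the significant cluster is" that is robust to small satellite
#' clusters.
#'
#' @param result a `correction_result`.
#' @param largest_cluster use only the largest connected cluster
#'   (default TRUE); otherwise all significant voxels.
#' @return Length-3 world coordinate in mm, or `NA` if nothing is
#'   significant.
#' @export
significant_com <- function(result, largest_cluster = TRUE) {
  sig <- result$significant
  if (!any(sig)) return(rep(NA_real_, 3))
  if (largest_cluster) {
    cc <- connected_components(sig, 26)
    big <- which.max(cc$sizes)
    sig <- cc$labels == big
  }
  idx <- which(sig, arr.ind = TRUE)
  colMeans(voxel_to_world(result$grid, idx))
}

#' Tidy a correction result into a per-voxel tibble
#' @param x a `correction_result`.
#' @param ... unused.
#' @return Tibble of included voxels with z, p (and corrected p or TFCE
#'   score where applicable) and the significance flag.
#' @export
tidy.correction_result <- function(x, ...) x$voxels

#' One-row summary of a correction result
#' @param x a `correction_result`.
#' @param ... unused.
#' @return Tibble with method, alpha, critical value, and significant /
#'   tested voxel counts.
#' @export
glance.correction_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    alpha = x$alpha,
    critical_value = x$critical_value,
    n_voxels = nrow(x$voxels),
    n_significant = sum(x$voxels$significant)
  )
}
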