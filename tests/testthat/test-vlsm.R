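make_cohort_masks <- function(L, shape = c(ncol(L), 1, 1)) {
  g <- grid_spec(shape)
  lapply(seq_len(nrow(L)), function(i) {
    mask_volume(g, array(as.integer(L[i, ]), dim = shape),
                label = paste0("P", i))
  })
}

test_that("the minimum-overlap filter keeps exactly the voxels with enough patients", {
  # three voxels with lesion counts 3, 10, 12 across 12 patients
  L <- matrix(0L, nrow = 12, ncol = 3)
  L[1:3, 1] <- 1L
  L[1:10, 2] <- 1L
  L[1:12, 3] <- 1L
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 10)
  expect_equal(ncol(Lm$L), 2L)
  expect_equal(sort(Lm$n_lesioned), c(10, 12))

  # min_overlap 1: columns are the union of the masks
  L2 <- rbind(c(1L, 0L, 0L), c(0L, 0L, 1L))
  Lm2 <- assemble_lesion_matrix(make_cohort_masks(L2), min_overlap = 1)
  expect_equal(ncol(Lm2$L), 2L)

  # nothing survives: error reports the max observed overlap
  expect_error(assemble_lesion_matrix(make_cohort_masks(L2), min_overlap = 3),
               "max observed overlap: 1")
})

test_that("raising min_overlap never adds a column", {
  set.seed(21)
  masks <- lapply(1:15, function(i) random_mask(c(8, 8, 8), p = 0.4))
  cols <- sapply(1:6, function(k) {
    ncol(assemble_lesion_matrix(masks, min_overlap = k)$L)
  })
  expect_true(all(diff(cols) <= 0))
  # at min_overlap 1 the column set is the lesion union
  expect_equal(cols[1], sum(frequency_map(masks)$counts > 0))
})

test_that("the voxel-wise t matches the worked two-sample example", {
  L <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1)
  Lm <- assemble_lesion_matrix(make_cohort_masks(L, c(1, 1, 1)),
                               min_overlap = 1)
  sm <- voxelwise_glm(Lm, c(2, 3, 4, 1, 2, 3))
  expect_equal(sm$df, 4L)
  expect_equal(sm$stats$t, 1.2247, tolerance = 1e-4)
  # mean difference 1, pooled SD 1, SE = sqrt(2/3)
  expect_equal(sm$stats$t, 1 / sqrt(2 / 3), tolerance = 1e-10)
})

test_that("voxel-wise regression t equals the lm slope t", {
  set.seed(5)
  n <- 18
  L <- matrix(rbinom(n * 6, 1, 0.5), nrow = n)
  L <- L[, colSums(L) > 0 & colSums(L) < n, drop = FALSE]
  y <- rnorm(n)
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 1)
  sm <- voxelwise_glm(Lm, y)
  for (v in seq_len(ncol(Lm$L))) {
    fit <- summary(lm(y ~ Lm$L[, v]))
    expect_equal(sm$stats$t[v], fit$coefficients[2, "t value"],
                 tolerance = 1e-10)
  }
})

test_that("constant lesion columns are degenerate with z = 0", {
  L <- cbind(rep(1L, 12), c(rep(1L, 10), 0L, 0L))
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 10)
  sm <- voxelwise_glm(Lm, rep(c(0, 1), 6))
  deg <- sm$stats$degenerate[match(1, Lm$voxel_index[, 1])]
  expect_true(deg)
  expect_equal(sm$stats$z[sm$stats$degenerate], 0)
  expect_true(all(is.na(sm$stats$p[sm$stats$degenerate])))
})

test_that("swapping dummy codes negates t and z at non-degenerate voxels", {
  set.seed(9)
  L <- matrix(rbinom(20 * 8, 1, 0.4), nrow = 20)
  L <- L[, colSums(L) > 0 & colSums(L) < 20, drop = FALSE]
  y <- rbinom(20, 1, 0.5)
  if (var(y) == 0) y[1] <- 1 - y[1]
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 1)
  sm_pos <- voxelwise_glm(Lm, y)
  sm_swp <- voxelwise_glm(Lm, 1 - y)
  ok <- !sm_pos$stats$degenerate & !sm_swp$stats$degenerate
  expect_equal(sm_swp$stats$t[ok], -sm_pos$stats$t[ok], tolerance = 1e-12)
  expect_equal(sm_swp$stats$z[ok], -sm_pos$stats$z[ok], tolerance = 1e-8)
})

test_that("outcome misuse raises usage errors", {
  L <- matrix(rbinom(10 * 3, 1, 0.5), nrow = 10)
  L[, 1] <- c(rep(1L, 5), rep(0L, 5))
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 1)
  expect_error(voxelwise_glm(Lm, rep(1, 10)), "constant")
  expect_error(voxelwise_glm(Lm, rep(1, 7)), "length")
  expect_error(voxelwise_glm(Lm, c(rep(0, 9), NA)), "missing")
})

test_that("one-sided p-values are calibrated under label permutation", {
  set.seed(31)
  n <- 30
  L <- matrix(rbinom(n * 50, 1, 0.5), nrow = n)
  L <- L[, colSums(L) >= 5 & colSums(L) <= n - 5, drop = FALSE]
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 1)
  y <- rnorm(n)
  # p at a fixed voxel over repeated permuted outcomes is ~ uniform
  p1 <- replicate(400, voxelwise_glm(Lm, sample(y))$stats$p[1])
  ks <- suppressWarnings(ks.test(p1, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p1 < 0.05) - 0.05), 0.04)
})

test_that("dummy coding maps reference to 0 and the other level to 1", {
  who <- c(1, 2, 2, 1, 2)
  coded <- dummy_code(who, reference = 1)
  expect_equal(as.integer(coded), c(0L, 1L, 1L, 0L, 1L))
  expect_equal(attr(coded, "mapping"), c(`1` = 0L, `2` = 1L))

  simpson <- c("<=3", ">3", "<=3", NA, ">3")
  coded2 <- dummy_code(simpson, reference = "<=3")
  expect_equal(as.integer(coded2), c(0L, 1L, 0L, NA, 1L))

  expect_error(dummy_code(c("a", "b", "c"), "a"), "exactly 2")
  expect_error(dummy_code(c("a", "b"), "z"), "not present")
})

test_that("stat maps tidy and glance like model objects", {
  L <- matrix(rbinom(16 * 5, 1, 0.5), nrow = 16)
  L[, 1] <- c(rep(1L, 8), rep(0L, 8))
  Lm <- assemble_lesion_matrix(make_cohort_masks(L), min_overlap = 1)
  sm <- voxelwise_glm(Lm, rnorm(16))
  td <- tidy(sm)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("i", "j", "k", "t", "p", "z") %in% names(td)))
  gl <- glance(sm)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$df, 14L)
  expect_equal(gl$n_voxels, nrow(td))
})
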