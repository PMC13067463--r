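test_that("mirroring flips a left-sided voxel by index reversal", {
  g <- grid_spec(c(64, 64, 64))
  data <- array(0L, dim = c(64, 64, 64))
  data[11, 21, 31] <- 1L  # 0-based (10, 20, 30), well left of midline
  m <- mask_volume(g, data, label = "left")
  out <- mirror_to_right(m)
  expect_true(attr(out, "flipped"))
  expect_equal(which(out$data == 1L, arr.ind = TRUE)[1, ],
               c(dim1 = 54, dim2 = 21, dim3 = 31))  # 0-based 53, 20, 30
  expect_equal(mask_count(out), mask_count(m))
})

test_that("masks inside the midline band are left unflipped", {
  g <- grid_spec(c(64, 64, 64))
  data <- array(0L, dim = c(64, 64, 64))
  data[31:34, 30:34, 30:34] <- 1L  # symmetric falcine block on the midline
  m <- mask_volume(g, data)
  out <- mirror_to_right(m)
  expect_false(attr(out, "flipped"))
  expect_identical(out$data, m$data)
})

test_that("mirroring is idempotent after the first application", {
  m <- random_mask(c(32, 16, 16), p = 0.1, seed = 7)
  m$data[17:32, , ] <- 0L  # purely left-sided
  once <- mirror_to_right(m)
  twice <- mirror_to_right(once)
  expect_identical(once$data, twice$data)
  expect_equal(mask_count(once), mask_count(m))
  # the raw flip is an involution
  expect_identical(flip_x(flip_x(m))$data, m$data)
})

test_that("empty masks are returned unchanged with a warning", {
  g <- grid_spec(c(8, 8, 8))
  m <- mask_volume(g, array(0L, dim = c(8, 8, 8)))
  expect_warning(out <- mirror_to_right(m), "empty")
  expect_identical(out$data, m$data)
})

test_that("DAZ is the tumor/dura intersection and contains the attachment", {
  space <- build_phantom_space()
  att <- arrayInd(space$dural_index[123], space$grid$shape)[1, ]
  tumor <- grow_tumor(space, att, radius_mm = 8)
  daz <- extract_daz(tumor, space$dura, dilation_voxels = 0)
  expect_equal(daz$data[att[1], att[2], att[3]], 1L)
  expect_true(all(daz$data <= tumor$data))          # DAZ subset of tumor
  expect_false(isTRUE(attr(daz, "unattached")))
})

test_that("an interior ball has an empty DAZ and raises the unattached flag", {
  space <- build_phantom_space()
  data <- array(0L, dim = space$grid$shape)
  # deep in the left hemisphere, clear of the falx and tentorium planes
  ctr <- c(18L, 40L, 26L)
  data[ctr[1] + (-2:2), ctr[2] + (-2:2), ctr[3] + (-2:2)] <- 1L
  ball <- mask_volume(space$grid, data, label = "interior")
  expect_warning(daz <- extract_daz(ball, space$dura, dilation_voxels = 0),
                 "no dural attachment")
  expect_equal(mask_count(daz), 0L)
  expect_true(attr(daz, "unattached"))
  expect_error(extract_daz(ball, space$dura, 0, on_unattached = "error"),
               "no dural attachment")
})

test_that("DAZ grows monotonically with the dural dilation", {
  space <- build_phantom_space()
  att <- arrayInd(space$dural_index[5000], space$grid$shape)[1, ]
  tumor <- grow_tumor(space, att, radius_mm = 10)
  d0 <- extract_daz(tumor, space$dura, 0)
  d1 <- extract_daz(tumor, space$dura, 1)
  d2 <- extract_daz(tumor, space$dura, 2)
  expect_true(all(d0$data <= d1$data))
  expect_true(all(d1$data <= d2$data))
})

test_that("frequency maps count coverage and conserve total lesion volume", {
  g <- grid_spec(c(4, 1, 1))
  mk <- function(v) mask_volume(g, array(as.integer(v), dim = c(4, 1, 1)))
  A <- mk(c(1, 1, 0, 0))  # v1, v2
  B <- mk(c(0, 1, 1, 0))  # v2, v3
  fm <- frequency_map(list(A, B))
  expect_equal(as.vector(fm$counts), c(1L, 2L, 1L, 0L))
  expect_equal(sum(fm$counts), mask_count(A) + mask_count(B))
  expect_equal(fm$n_patients, 2L)

  single <- frequency_map(list(A))
  expect_identical(single$counts, A$data)
  expect_error(frequency_map(list()), "nonempty")
})

test_that("frequency-map conservation holds on random cohorts", {
  set.seed(11)
  masks <- lapply(1:7, function(i) random_mask(c(10, 10, 10), p = 0.3))
  fm <- frequency_map(masks)
  expect_equal(sum(fm$counts), sum(vapply(masks, mask_count, numeric(1))))
  expect_true(max(fm$counts) <= length(masks))
})

test_that("corner-touching voxels join under 26- but not 6-connectivity", {
  arr <- array(0L, dim = c(3, 3, 3))
  arr[1, 1, 1] <- 1L
  arr[2, 2, 2] <- 1L
  expect_equal(connected_components(arr, 26)$n_components, 1L)
  expect_equal(connected_components(arr, 6)$n_components, 2L)
  expect_equal(connected_components(array(0L, dim = c(3, 3, 3)))$n_components,
               0L)
})

test_that("component labeling agrees with a BFS flood-fill oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    arr <- array(rbinom(12^3, 1, 0.25), dim = c(12, 12, 12))
    for (conn in c(6, 26)) {
      got <- connected_components(arr, conn)
      ref <- bfs_components(arr, conn)
      expect_equal(length(got$sizes), length(ref$sizes))
      expect_equal(sort(got$sizes), sort(ref$sizes))
      # same partition: labels must be a relabeling of each other
      key <- paste(got$labels[arr == 1], ref$labels[arr == 1])
      expect_equal(length(unique(key)), length(got$sizes))
    }
  }
})
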