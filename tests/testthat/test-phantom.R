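space <- build_phantom_space()

test_that("the dural shell closes around the brain", {
  # every brain-boundary voxel must have a dural voxel in its
  # 26-neighborhood after one dilation step of the brain
  brain <- space$brain$data == 1L
  ring <- dilate_binary(brain, 1) & !brain
  dura <- dural_domain(space$dura)
  near_dura <- dilate_binary(dura, 1)
  uncovered <- ring & !near_dura & !brain
  # the carved falx/tentorium fissures are interior, not boundary gaps:
  # the outward boundary must be fully covered
  outer_ring <- ring & !dilate_binary(brain & !near_dura, 1)
  expect_equal(sum(outer_ring & !near_dura), 0L)
})

test_that("falx voxels hug the midline and the partition covers the dura", {
  falx <- which(space$dura$data == 2L, arr.ind = TRUE)
  xw <- voxel_to_world(space$grid, falx)[, 1]
  expect_true(all(abs(xw - space$grid$midline_plane) <=
                    space$grid$spacing[1]))
  # compartments partition the dural domain
  expect_equal(sum(space$compartments > 0L), length(space$dural_index))
  expect_true(all(space$compartments[space$dural_index] > 0L))
  expect_equal(sum(table(space$dural_compartment)),
               length(space$dural_index))
})

test_that("falx and tentorium connect to the shell as one dural complex", {
  cc <- connected_components(dural_domain(space$dura), 26)
  main <- which.max(cc$sizes)
  labs2 <- unique(cc$labels[space$dura$data == 2L])
  labs3 <- unique(cc$labels[space$dura$data == 3L])
  expect_equal(unique(c(labs2, labs3)), main)
})

test_that("an oversized brain is rejected", {
  expect_error(build_phantom_space(c(32, 32, 32), c(24, 27, 21)),
               "does not fit")
})

test_that("grown tumors contain their attachment and respect the ball bound", {
  set.seed(14)
  for (r in 1:5) {
    att <- arrayInd(sample(space$dural_index, 1), space$grid$shape)[1, ]
    radius <- runif(1, 3, 12)
    tm <- grow_tumor(space, att, radius)
    expect_equal(tm$data[att[1], att[2], att[3]], 1L)
    expect_lte(mask_count(tm), ceiling(4 / 3 * pi * radius^3 /
                                         prod(space$grid$spacing)))
    # connected under 26-connectivity
    expect_equal(connected_components(tm$data, 26)$n_components, 1L)
    # cross-module: the zero-dilation DAZ contains the attachment
    daz <- extract_daz(tm, space$dura, 0)
    expect_equal(daz$data[att[1], att[2], att[3]], 1L)
  }
  # (18, 40, 26) is deep left-hemisphere parenchyma, not dura
  expect_error(grow_tumor(space, c(18, 40, 26), 5), "dural domain")
})

test_that("outcome simulation is seeded and respects the null construction", {
  n <- 200
  set.seed(77)
  att <- arrayInd(sample(space$dural_index, n, replace = TRUE),
                  space$grid$shape)
  vols <- rlnorm(n, log(4), 0.5)
  spec <- phantom_cohort_spec(n_patients = n, p0 = 0.3, seed = 99)
  y1 <- simulate_outcomes(space, att, vols, spec)
  y2 <- simulate_outcomes(space, att, vols, spec)
  expect_identical(as.integer(y1), as.integer(y2))
  # null construction: prevalence close to p0 (binomial CI at n = 200)
  expect_lt(abs(mean(y1) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("implanted hot-region log-odds are recoverable by logistic fit", {
  hot <- list(center = dural_point(space, c(1, 0, 0.25)), radius_mm = 8)
  ok <- 0
  for (r in 1:10) {
    spec <- phantom_cohort_spec(n_patients = 200, hot_region = hot,
                                hot_fraction = 0.3, p0 = 0.1, p1 = 0.6,
                                seed = 300 + r)
    set.seed(300 + r)
    all_idx <- arrayInd(space$dural_index, space$grid$shape)
    hot_pool <- space$dural_index[dazvlsm:::hot_membership(space, all_idx,
                                                           hot)]
    att_lin <- c(sample(hot_pool, 60, replace = TRUE),
                 sample(space$dural_index, 140, replace = TRUE))
    att <- arrayInd(att_lin, space$grid$shape)
    vols <- rlnorm(200, log(4), 0.5)
    y <- simulate_outcomes(space, att, vols, spec, seed = 300 + r)
    hot_m <- attr(y, "hot")
    if (sum(hot_m) < 5) next
    fit <- glm(as.integer(y) ~ hot_m, family = binomial)
    implanted <- qlogis(0.6) - qlogis(0.1)
    est <- coef(summary(fit))["hot_mTRUE", ]
    ok <- ok + (abs(est["Estimate"] - implanted) <= 2 * est["Std. Error"])
  }
  expect_gte(ok, 8)
})

test_that("generated cohorts are reproducible and grid-consistent", {
  spec <- phantom_cohort_spec(n_patients = 20, seed = 6)
  c1 <- generate_cohort(space, spec)
  c2 <- generate_cohort(space, spec)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$masks, `[[`, "data"),
                   lapply(c2$masks, `[[`, "data"))
  expect_silent(validate_cohort_grid(c1$masks))
  # written cohorts are byte-identical across reruns
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("sampled volumes track the lognormal law's target mean", {
  spec <- phantom_cohort_spec(n_patients = 200, mean_volume_ml = 4, seed = 8)
  co <- generate_cohort(space, spec)
  expect_lt(abs(mean(co$table$volume_ml) - 4) / 4, 0.15)
  expect_equal(co$truth$radius_mm,
               (3 * co$truth$volume_ml * 1000 / (4 * pi))^(1 / 3))
  # every tumor has a nonempty zero-dilation DAZ by construction
  daz_counts <- vapply(co$masks[1:20], function(m) {
    mask_count(extract_daz(m, space$dura, 0))
  }, numeric(1))
  expect_true(all(daz_counts > 0))
})

test_that("attachment sampling respects compartment weights", {
  w <- c(right_convexity = 3, left_convexity = 1)
  spec <- phantom_cohort_spec(n_patients = 500, attachment_weights = w,
                              seed = 10)
  co <- generate_cohort(space, spec)
  tab <- table(co$truth$compartment)
  expect_true(all(names(tab) %in% names(w)))
  frac <- tab[["right_convexity"]] / 500
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 500))
})

test_that("cohort tables round trip through the on-disk layout", {
  spec <- phantom_cohort_spec(n_patients = 6, seed = 3)
  co <- generate_cohort(space, spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$table$patient_id, co$table$patient_id)
  expect_equal(back$table$endpoint, co$table$endpoint)
  expect_identical(back$masks[[2]]$data, co$masks[[2]]$data)
  expect_identical(back$dura$data, space$dura$data)
})
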