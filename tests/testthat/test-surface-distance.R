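single_voxel_mask <- function(grid, at, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = grid)
  arr[at[1], at[2], at[3]] <- TRUE
  binary_mask(arr, spacing)
}

test_that("boundary distances match hand computations", {
  a <- single_voxel_mask(c(5, 5, 5), c(1, 1, 1))
  b <- single_voxel_mask(c(5, 5, 5), c(4, 1, 1))
  expect_equal(as.numeric(boundary_distances(a, b)), 3)

  # identical surfaces give all zeros
  cube <- solid_cube_mask(c(8, 8, 8), c(2, 2, 2), 4)
  expect_true(all(boundary_distances(cube, cube) == 0))

  # anisotropic spacing enters the Euclidean distance
  aa <- single_voxel_mask(c(4, 4, 4), c(1, 1, 1), spacing = c(1, 2, 3))
  bb <- single_voxel_mask(c(4, 4, 4), c(2, 2, 2), spacing = c(1, 2, 3))
  expect_equal(as.numeric(boundary_distances(aa, bb)), sqrt(1 + 4 + 9))

  empty <- binary_mask(array(0, c(4, 4, 4)))
  expect_error(boundary_distances(empty, a), "empty")
  expect_error(boundary_distances(a, empty), "empty")
})

test_that("distance summaries use mean, median and interpolated percentile", {
  s <- summarize_distances(c(1, 2, 3, 4))
  expect_equal(s$asd_mm, 2.5)
  expect_equal(s$msd_mm, 2.5)
  expect_equal(s$n_distances, 4)

  s100 <- summarize_distances(as.numeric(1:100))
  expect_equal(s100$hd95_mm, 95.05)
  expect_equal(s100$hd95_mm, oracle_quantile(as.numeric(1:100), 0.95))

  z <- summarize_distances(rep(0, 10))
  expect_equal(c(z$hd95_mm, z$asd_mm, z$msd_mm), c(0, 0, 0))

  expect_error(summarize_distances(numeric(0)), "empty")
  expect_error(summarize_distances(c(1, -1)), "nonnegative")

  # HD95 dominates the median whenever there are >= 2 distances
  for (seed in 1:5) {
    set.seed(seed)
    d <- stats::rexp(50)
    ss <- summarize_distances(d)
    expect_gte(ss$hd95_mm, ss$msd_mm)
    expect_gte(min(max(d), ss$hd95_mm), ss$msd_mm)
    expect_true(ss$asd_mm >= min(d) && ss$asd_mm <= max(d))
  }
})

test_that("patient-wise summary is zero for identical masks and flags empties", {
  sp <- phantom_spec(c(20, 20, 20), c(1, 1, 1),
                     centers = c(9, 9, 9), radii = c(6, 6, 6))
  m <- render_phantom(sp)
  s <- patientwise_surface(m, m)
  expect_equal(c(s$hd95_mm, s$asd_mm, s$msd_mm), c(0, 0, 0))

  empty <- binary_mask(array(0, c(20, 20, 20)))
  s2 <- patientwise_surface(m, empty)
  expect_true(is.na(s2$hd95_mm))
  expect_equal(attr(s2, "flag"), "empty_prediction")
  s3 <- patientwise_surface(empty, m)
  expect_equal(attr(s3, "flag"), "empty_truth")
})

test_that("the distance set is directed: swapping arguments changes it", {
  # small structure inside a big one: outward distances are large,
  # inward distances from the big boundary are all far from the small blob
  big <- solid_cube_mask(c(20, 20, 20), c(2, 2, 2), 16)
  small <- solid_cube_mask(c(20, 20, 20), c(9, 9, 9), 2)
  fwd <- summarize_distances(boundary_distances(small, big))
  bwd <- summarize_distances(boundary_distances(big, small))
  expect_false(isTRUE(all.equal(fwd$asd_mm, bwd$asd_mm)))
  expect_false(isTRUE(all.equal(fwd$n_distances, bwd$n_distances)))
})

test_that("a distant false blob inflates patient-wise but not structure-wise", {
  sp <- phantom_spec(c(36, 36, 36), c(1, 1, 1),
                     centers = c(12, 12, 12), radii = c(7, 7, 7))
  truth <- render_phantom(sp)
  pred <- perturb(truth, "add_false_structure",
                  center = c(30, 30, 30), radii = c(2, 2, 2))
  pw_clean <- patientwise_surface(truth, truth)
  pw_dirty <- patientwise_surface(truth, pred)
  expect_gt(pw_dirty$hd95_mm, pw_clean$hd95_mm)
  sw <- structurewise_surface(truth, label_components(pred))
  expect_equal(nrow(sw), 1)
  expect_equal(c(sw$hd95_mm, sw$asd_mm, sw$msd_mm), c(0, 0, 0))
})

test_that("directed ASD of a translated cube approaches one third of the shift", {
  # only the two faces perpendicular to the shift sit at distance k; the
  # four parallel faces contribute ~0, so the directed mean tends to k/3
  for (k in c(1, 2)) {
    L <- 24
    grid <- c(L + k + 4, L + 4, L + 4)
    truth <- solid_cube_mask(grid, c(2, 2, 2), L)
    pred <- binary_mask(oracle_shift(truth$data, c(k, 0, 0), FALSE))
    s <- patientwise_surface(truth, pred)
    expect_gt(s$asd_mm, k / 3 * 0.9)
    expect_lt(s$asd_mm, k / 3 * 1.1)
    # and the brute-force oracle agrees exactly
    d_oracle <- oracle_min_dists(which(oracle_boundary(pred$data), arr.ind = TRUE),
                                 which(oracle_boundary(truth$data), arr.ind = TRUE),
                                 c(1, 1, 1))
    expect_equal(s$asd_mm, mean(d_oracle), tolerance = 1e-12)
  }
})

test_that("one-voxel dilation gives ASD of one voxel for large structures", {
  truth <- solid_cube_mask(c(22, 22, 22), c(4, 4, 4), 15)
  pred <- perturb(truth, "dilate")
  s <- patientwise_surface(truth, pred)
  expect_equal(s$asd_mm, 1, tolerance = 0.05)
  sw <- structurewise_surface(truth, label_components(pred))
  expect_equal(sw$asd_mm, 1, tolerance = 0.05)
})

test_that("structure-wise summaries cover exactly the detected structures", {
  sp <- phantom_spec(c(40, 40, 40), c(1, 1, 1),
                     centers = rbind(c(10, 10, 10), c(28, 28, 28)),
                     radii = rbind(c(6, 6, 6), c(5, 5, 5)))
  truth <- render_phantom(sp)
  pred <- perturb(truth, "add_false_structure",
                  center = c(32, 8, 8), radii = c(2.5, 2.5, 2.5))
  ps <- label_components(pred)
  sw <- structurewise_surface(truth, ps)
  expect_equal(nrow(sw), 2)
  expect_true(all(c(sw$hd95_mm, sw$asd_mm, sw$msd_mm) == 0))

  # empty truth is an error, not a silent zero
  empty <- binary_mask(array(0, c(40, 40, 40)))
  expect_error(structurewise_surface(empty, ps), "empty")

  # no detected structures: a zero-row frame
  far <- binary_mask(array(0, c(40, 40, 40)))
  far$data[2:4, 2:4, 2:4] <- TRUE
  sw0 <- structurewise_surface(truth, label_components(far))
  expect_equal(nrow(sw0), 0)
})

test_that("summaries are translation invariant and scale with spacing", {
  sp <- phantom_spec(c(30, 30, 30), c(1, 1, 1),
                     centers = c(10, 10, 10), radii = c(6, 5, 4))
  truth <- render_phantom(sp)
  pred <- perturb(truth, "dilate")

  base <- patientwise_surface(truth, pred)
  off <- c(4, 3, 2)
  t2 <- binary_mask(oracle_shift(truth$data, off, FALSE))
  p2 <- binary_mask(oracle_shift(pred$data, off, FALSE))
  moved <- patientwise_surface(t2, p2)
  expect_equal(moved$hd95_mm, base$hd95_mm)
  expect_equal(moved$asd_mm, base$asd_mm)
  expect_equal(moved$msd_mm, base$msd_mm)
  expect_equal(dice(t2, p2), dice(truth, pred))

  for (s in c(0.5, 2, 3.25)) {
    ts <- binary_mask(truth$data, truth$spacing * s)
    ps <- binary_mask(pred$data, pred$spacing * s)
    scaled <- patientwise_surface(ts, ps)
    expect_equal(scaled$hd95_mm, s * base$hd95_mm, tolerance = 1e-12)
    expect_equal(scaled$asd_mm, s * base$asd_mm, tolerance = 1e-12)
    expect_equal(scaled$msd_mm, s * base$msd_mm, tolerance = 1e-12)
  }
})

test_that("accelerated distances equal the all-pairs brute force", {
  for (seed in 1:10) {
    ta <- random_mask_array(c(8, 8, 8), p = 0.2, seed = seed + 900)
    pa <- random_mask_array(c(8, 8, 8), p = 0.2, seed = seed + 950)
    if (!any(ta) || !any(pa)) next
    spacing <- c(0.8, 1, 1.7)
    truth <- binary_mask(ta, spacing)
    pred <- binary_mask(pa, spacing)
    d <- boundary_distances(pred, truth)
    want <- oracle_min_dists(which(oracle_boundary(pa), arr.ind = TRUE),
                             which(oracle_boundary(ta), arr.ind = TRUE),
                             spacing)
    expect_equal(as.numeric(d), unname(want), tolerance = 1e-9)
  }
})

test_that("symmetric pooling unions both directed sets", {
  big <- solid_cube_mask(c(16, 16, 16), c(2, 2, 2), 12)
  small <- solid_cube_mask(c(16, 16, 16), c(6, 6, 6), 4)
  sym <- patientwise_surface(big, small, symmetric = TRUE)
  fwd <- boundary_distances(small, big)
  bwd <- boundary_distances(big, small)
  expect_equal(sym$n_distances, length(fwd) + length(bwd))
  expect_equal(sym$asd_mm, mean(c(fwd, bwd)))
})
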