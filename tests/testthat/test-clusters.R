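# Segmentation, single-cell calibration, integrated-signal counting,
# clustering summaries, and cluster morphometrics.

test_that("segmentation finds well-separated nuclei and is deterministic", {
  sim <- simulate_stack(phantom_spec(0, n_singles = 5, seed = 21,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  seg1 <- segment_objects(sim$stack)
  expect_identical(seg1$n_objects, 5L)
  seg2 <- segment_objects(sim$stack)
  expect_identical(seg1$labels, seg2$labels)
  blank <- image_stack(list(nuclei = array(7, c(8, 8, 3))),
                       pixel_size = 1.8, slice_thickness = 6.7)
  expect_error(segment_objects(blank), "no objects")
})

test_that("touching cluster nuclei merge into one 3D connected component", {
  sim <- simulate_stack(phantom_spec(10, n_singles = 4, seed = 22,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  seg <- segment_objects(sim$stack)
  expect_identical(seg$n_objects, 5L)  # 1 cluster + 4 singles
  # the cluster spans several slices (3D organization)
  m <- measure_cluster(largest_object(seg), sim$stack, seg = seg)
  expect_gt(m$height, sim$stack$slice_thickness)
})

test_that("noiseless calibration reproduces the exact nucleus integral", {
  sim <- simulate_stack(phantom_spec(0, n_singles = 6, seed = 23))
  seg <- segment_objects(sim$stack)
  cal <- calibrate_single_cell(sim$stack, seg)
  expect_equal(cal$single_cell_signal, mean(sim$truth$nuclei$integral),
               tolerance = 1e-3)
  expect_equal(cal$background_per_voxel, 0, tolerance = 1e-8)
  expect_identical(cal$n_reference_cells, 6L)
})

test_that("calibration is centred on the true mean under intensity variation", {
  sim <- simulate_stack(phantom_spec(0, n_singles = 10, seed = 24,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  seg <- segment_objects(sim$stack)
  cal <- calibrate_single_cell(sim$stack, seg)
  true_mean <- mean(sim$truth$nuclei$integral)
  se <- stats::sd(sim$truth$nuclei$integral) / sqrt(10)
  expect_lt(abs(cal$single_cell_signal - true_mean), 2 * se + 1e-9)
})

test_that("a uniform intensity offset is absorbed by background correction", {
  sim <- simulate_stack(phantom_spec(8, n_singles = 6, seed = 25,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  seg <- segment_objects(sim$stack)
  cal <- calibrate_single_cell(sim$stack, seg)
  est <- count_cluster_cells(largest_object(seg), sim$stack, cal, seg = seg)
  shifted <- sim$stack
  shifted$channels$nuclei <- shifted$channels$nuclei + 300
  seg_s <- segment_objects(shifted)
  cal_s <- calibrate_single_cell(shifted, seg_s)
  expect_equal(cal_s$single_cell_signal, cal$single_cell_signal,
               tolerance = 5e-3)
  expect_equal(cal_s$background_per_voxel - cal$background_per_voxel, 300,
               tolerance = 1)
  est_s <- count_cluster_cells(largest_object(seg_s), shifted, cal_s, seg = seg_s)
  expect_equal(est_s, est, tolerance = 5e-3)
})

test_that("estimates are invariant to a global intensity gain", {
  sim <- simulate_stack(phantom_spec(8, n_singles = 6, seed = 26,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  run <- function(stack) {
    seg <- segment_objects(stack)
    cal <- calibrate_single_cell(stack, seg)
    count_cluster_cells(largest_object(seg), stack, cal, seg = seg)
  }
  est <- run(sim$stack)
  gained <- sim$stack
  gained$channels$nuclei <- gained$channels$nuclei * 3.7
  expect_equal(run(gained), est, tolerance = 1e-9)
})

test_that("counting is exact on noiseless equal-intensity phantoms", {
  sim <- simulate_stack(phantom_spec(12, n_singles = 6, seed = 27))
  seg <- segment_objects(sim$stack)
  cal <- calibrate_single_cell(sim$stack, seg)
  est <- count_cluster_cells(largest_object(seg), sim$stack, cal, seg = seg)
  expect_lt(abs(est - 12) / 12, 0.005)
  # a volume holding exactly one reference nucleus estimates ~1 cell
  single_id <- cal$reference_ids[1]
  expect_equal(count_cluster_cells(single_id, sim$stack, cal, seg = seg), 1,
               tolerance = 0.05)
  # an empty background-only volume estimates 0 cells
  corner <- 1:20  # voxels in the field corner, far from any nucleus
  est0 <- suppressWarnings(
    count_cluster_cells(corner + seg$n_objects, sim$stack, cal, dilate = FALSE))
  expect_equal(est0, 0, tolerance = 0.02)
  expect_error(count_cluster_cells(largest_object(seg), sim$stack,
                                   structure(list(single_cell_signal = 0),
                                             class = "nucleus_calibration"),
                                   seg = seg),
               "calibration")
})

test_that("ground-truth cluster counts are recovered within the validation bound", {
  sim <- simulate_stack(phantom_spec(20, n_singles = 8, seed = 28,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  seg <- segment_objects(sim$stack)
  cal <- calibrate_single_cell(sim$stack, seg)
  est <- count_cluster_cells(largest_object(seg), sim$stack, cal, seg = seg)
  expect_lt(abs(est - 20) / 20, 0.15)
})

test_that("clustering summaries classify fields and conserve totals", {
  # isolated cells only: nothing clustered
  iso <- simulate_stack(phantom_spec(0, n_singles = 7, seed = 29,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  s_iso <- summarize_clustering(iso$stack)
  expect_equal(s_iso$percent_clustered, 0)
  expect_identical(s_iso$n_clusters, 0L)
  # a single 10-cell cluster with reference singles: the summary respects
  # exact conservation clustered + singles = total
  mix <- simulate_stack(phantom_spec(10, n_singles = 6, seed = 30,
                                    intensity_cv = 0.1,
                                    background_level = 0.05))
  s_mix <- summarize_clustering(mix$stack)
  expect_identical(s_mix$n_clusters, 1L)
  expect_equal(s_mix$n_clustered_cells + s_mix$n_single_cells,
               s_mix$n_total_cells)
  expect_equal(s_mix$percent_clustered,
               100 * s_mix$n_clustered_cells / s_mix$n_total_cells)
  # all cells clustered when calibrated externally on a singles-only field
  iso_seg <- segment_objects(iso$stack)
  ext_cal <- calibrate_single_cell(iso$stack, iso_seg)
  only <- simulate_stack(small_stack_spec(
    cluster_specs = list(list(cell_count = 10)), n_single_cells = 0,
    intensity_cv = 0.1, background_level = 0.05, rng_seed = 31))
  s_only <- summarize_clustering(only$stack, cal = ext_cal)
  expect_equal(s_only$percent_clustered, 100)
})

test_that("percent clustered tracks the true clustered fraction", {
  sim <- simulate_stack(small_stack_spec(
    field_size = c(220, 220),
    cluster_specs = list(list(cell_count = 25), list(cell_count = 15)),
    n_single_cells = 10, intensity_cv = 0.1, background_level = 0.05,
    rng_seed = 32))
  s <- summarize_clustering(sim$stack)
  expect_identical(s$n_clusters, 2L)
  expect_lt(abs(s$percent_clustered - 80), 5)
})

test_that("percent clustered increases as cells move from singles to clusters", {
  pct <- vapply(seq_len(5), function(i) {
    in_cluster <- c(5, 12, 20, 28, 36)[i]
    sim <- simulate_stack(small_stack_spec(
      field_size = c(260, 260),
      cluster_specs = list(list(cell_count = in_cluster)),
      n_single_cells = 40 - in_cluster,
      intensity_cv = 0.1, background_level = 0.05, rng_seed = 33 + i))
    summarize_clustering(sim$stack)$percent_clustered
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("cluster morphometrics match analytic geometry", {
  # synthetic ellipsoid, semi-axes (20, 12, 10) um, built directly as voxels
  px <- 1.8; dz <- 6.7
  dims <- c(64, 64, 9)
  ax <- (seq_len(dims[1]) - 0.5) * px
  ay <- (seq_len(dims[2]) - 0.5) * px
  az <- (seq_len(dims[3]) - 0.5) * dz
  ctr <- c(mean(range(ax)), mean(range(ay)), mean(range(az)))
  inside <- outer(outer((ax - ctr[1])^2 / 20^2, (ay - ctr[2])^2 / 12^2, "+"),
                  (az - ctr[3])^2 / 10^2, "+") <= 1
  stack <- image_stack(list(nuclei = array(as.numeric(inside), dims)),
                       pixel_size = px, slice_thickness = dz)
  m <- measure_cluster(which(inside), stack)
  expect_lt(abs(m$height - 2 * 10), dz + 1e-9)          # slices spanned x dz
  expect_lt(abs(m$max_dimension - 2 * 20), 2 * px)      # in-plane Feret
  expect_lt(abs(m$projected_area - pi * 20 * 12),
            2 * pi * (20 + 12) * px)                    # one-pixel band around perimeter
  # slice-count convention: a set spanning 3 slices is 3 x 6.7 um high
  idx3 <- which(array(seq_len(dims[3]), dims)[rep(TRUE, prod(dims))] %in% 1)
  three <- c(1, 1 + prod(dims[1:2]), 1 + 2 * prod(dims[1:2]))
  expect_equal(measure_cluster(three, stack)$height, 3 * 6.7)
  # single-voxel degenerate case: pixel area, diagonal max dimension
  m1 <- measure_cluster(1L, stack)
  expect_equal(m1$projected_area, px^2)
  expect_equal(m1$max_dimension, sqrt(2) * px)
  expect_error(measure_cluster(integer(0), stack), "empty voxel set")
})
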