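maps_from_arrays <- function(pe_early, ser) {
  # assemble enhancement maps directly for mask-level tests
  structure(list(pe_early = pe_early, pe_late = NULL, ser = ser,
                 valid = array(TRUE, dim(pe_early)), s0_floor = 0),
            class = "enhancement_maps")
}

test_that("the default grid enumerates 18 x 11 = 198 cells", {
  g <- default_grid()
  expect_equal(g$pe_thresholds, seq(30, 200, 10))
  expect_equal(g$ser_thresholds, seq(0, 2, 0.2))
  expect_equal(length(g$pe_thresholds) * length(g$ser_thresholds), 198)
  expect_equal(default_cell(), c(pe_t = 70, ser_t = 0))
  expect_error(threshold_grid(c(30, 30, 40)), "increasing")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(61)
  for (conn in c(6, 18, 26)) {
    m <- random_blob_mask(c(7, 6, 5), n_blobs = 3, salt = 0.05)
    lab <- label_components(m, conn)
    ref <- oracle_label(m, conn)
    expect_equal(max(lab), max(ref))
    # same partition: label images equal up to renumbering
    expect_equal(length(unique(paste(lab, ref))), max(ref) + (0 %in% lab))
  }
})

test_that("the connectivity filter removes exactly the small components", {
  m <- array(FALSE, c(10, 6, 4))
  m[2:4, 2:3, 2] <- TRUE        # 6-voxel slab... grown below to 10
  m[2:5, 2:3, 3] <- TRUE        # connected to the slab: total 14 voxels
  m[9, 5, 4] <- TRUE            # isolated voxel
  maps <- maps_from_arrays(array(200, dim(m)), array(1, dim(m)))
  maps$pe_early[!m] <- 0
  got <- enhancing_mask(maps, array(TRUE, dim(m)), pe_t = 100,
                        min_cluster_voxels = 3)
  expect_true(all(got[2:4, 2:3, 2]))
  expect_false(got[9, 5, 4])
  # min_cluster 1 leaves the raw threshold mask untouched
  got1 <- enhancing_mask(maps, array(TRUE, dim(m)), pe_t = 100,
                         min_cluster_voxels = 1)
  expect_identical(got1, m)
  # a threshold above the PE maximum empties the mask
  got2 <- enhancing_mask(maps, array(TRUE, dim(m)), pe_t = 1000,
                         min_cluster_voxels = 1)
  expect_false(any(got2))
})

test_that("FTV converts passing-voxel counts at the scanner voxel size", {
  shape <- c(10, 10, 4)
  pe <- array(0, shape); ser <- array(0, shape)
  pe[1:10, 1:10, 1] <- 200; ser[1:10, 1:10, 1] <- 1.5  # 100 passing voxels
  st <- dce_study(array(100, shape), array(300, shape), array(200, shape))
  maps <- maps_from_arrays(pe, ser)
  ftv <- compute_ftv(st, maps, array(TRUE, shape), pe_t = 70, ser_t = 1,
                     min_cluster_voxels = 1)
  expect_equal(ftv, 100 * 0.7 * 0.94 * 2.0 / 1000)
  # SER_t = 0 gates nothing with non-negative SER
  expect_equal(compute_ftv(st, maps, array(TRUE, shape), 70, 0, 1), ftv)
})

test_that("compute_ftv equals the brute-force enumeration oracle", {
  set.seed(62)
  for (rep in 1:4) {
    shape <- c(12, 12, 6)
    st <- random_study(shape)
    maps <- enhancement_maps(st, s0_floor = 10)
    voi <- array(runif(prod(shape)) > 0.3, shape)
    for (tt in 1:5) {
      pe_t <- runif(1, 30, 200); ser_t <- runif(1, 0, 2)
      got <- compute_ftv(st, maps, voi, pe_t, ser_t, min_cluster_voxels = 4)
      ref <- oracle_ftv(maps$pe_early, maps$ser, maps$valid, voi,
                        voxel_volume_cc(st), pe_t, ser_t, 4)
      expect_equal(got, ref)
    }
  }
})

test_that("FTV surfaces match direct per-cell computation and are monotone", {
  set.seed(63)
  st <- random_study(c(12, 12, 6))
  maps <- enhancement_maps(st, s0_floor = 10)
  voi <- array(TRUE, dim(st$s0))
  g <- default_grid()
  surf <- ftv_surface(st, maps, voi, g, min_cluster_voxels = 4)
  expect_equal(dim(surf), c(18, 11))
  for (s in 1:10) {
    i <- sample(18, 1); j <- sample(11, 1)
    expect_equal(surf[i, j],
                 compute_ftv(st, maps, voi, g$pe_thresholds[i],
                             g$ser_thresholds[j], min_cluster_voxels = 4))
  }
  expect_true(all(diff(unclass(surf)) <= 0))       # down pe rows
  expect_true(all(t(diff(t(unclass(surf)))) <= 0)) # across ser columns
  expect_true(all(surf >= 0))

  # constant-zero PE gives the all-zero surface
  maps0 <- maps_from_arrays(array(0, dim(st$s0)), array(0, dim(st$s0)))
  surf0 <- ftv_surface(st, maps0, voi, g, 1)
  expect_true(all(surf0 == 0))
})

test_that("FTV is monotone in thresholds and cluster size, linear in voxel volume", {
  set.seed(64)
  st <- random_study(c(10, 10, 5))
  maps <- enhancement_maps(st, s0_floor = 10)
  voi <- array(TRUE, dim(st$s0))
  f <- function(pe, ser, mc) compute_ftv(st, maps, voi, pe, ser, mc)
  expect_gte(f(50, 0.5, 2), f(90, 0.5, 2))
  expect_gte(f(50, 0.5, 2), f(50, 1.2, 2))
  expect_gte(f(50, 0.5, 2), f(50, 0.5, 10))
  st2 <- dce_study(st$s0, st$s_early, st$s_late, voxel_size_mm = c(1, 1, 1))
  expect_equal(compute_ftv(st2, maps, voi, 50, 0.5, 2) * (0.7 * 0.94 * 2.0),
               f(50, 0.5, 2))
})

test_that("surfaces export to long format with one row per visit and cell", {
  set.seed(65)
  st <- random_study(c(8, 8, 4))
  maps <- enhancement_maps(st, s0_floor = 10)
  voi <- array(TRUE, dim(st$s0))
  g <- threshold_grid(c(50, 100), c(0, 1, 2))
  s <- ftv_surface(st, maps, voi, g, 1)
  long <- surface_long(list(MRI_1 = s, MRI_f = s), "P007")
  expect_equal(nrow(long), 2 * 6)
  expect_named(long, c("patient_id", "visit", "pe_t", "ser_t", "ftv_cc"))
  row <- long[long$visit == "MRI_1" & long$pe_t == 100 & long$ser_t == 1, ]
  expect_equal(row$ftv_cc, s["100", "1"], ignore_attr = TRUE)
})

test_that("predictors implement percent change with missing-data rules", {
  g <- threshold_grid(c(50, 100), c(0, 1))
  mk_surf <- function(vals) {
    structure(matrix(vals, 2, 2), class = c("ftv_surface", "matrix"),
              pe_thresholds = g$pe_thresholds,
              ser_thresholds = g$ser_thresholds)
  }
  s1 <- mk_surf(c(40, 20, 10, 0))
  s2 <- mk_surf(c(40, 10, 5, 0))
  sf <- mk_surf(c(10, 5, 2, 1))
  pr <- build_predictors(list(MRI_1 = s1, MRI_2 = s2, MRI_f = sf))
  expect_equal(pr$delta_ftvf[1, 1], -75)
  expect_equal(pr$delta_ftv2[1, 1], 0)
  # zero baseline: deltas missing, absolute final volume still defined
  expect_true(is.na(pr$delta_ftvf[2, 2]))
  expect_equal(pr$ftv_f[2, 2], 1)
  # missing early exam: all-missing delta_ftv2
  pr2 <- build_predictors(list(MRI_1 = s1, MRI_f = sf))
  expect_true(all(is.na(pr2$delta_ftv2)))
  expect_false(anyNA(pr2$ftv_f))
  expect_error(build_predictors(list(MRI_2 = s2)), "baseline")
})
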