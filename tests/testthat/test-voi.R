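test_that("MIP collapses the requested axis to the per-line maximum", {
  v <- array(3, c(2, 2, 2))
  expect_equal(project_mip(v, 3), matrix(3, 2, 2))

  v2 <- array(0, c(4, 5, 3)); v2[2, 4, 1] <- 9
  for (ax in 1:3) {
    m <- project_mip(v2, ax)
    expect_equal(dim(m), dim(v2)[-ax])
    expect_equal(sum(m == 9), 1)
  }
  expect_error(project_mip(v2, 4), "axis")
})

test_that("MIP matches a triple-loop oracle on random volumes", {
  set.seed(51)
  v <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  for (ax in 1:3) expect_equal(project_mip(v, ax), oracle_mip(v, ax))
})

test_that("voi_mask is the intersection of back-projected rectangles", {
  shape <- c(6, 6, 6)
  # full-plane rectangles on two axes give an all-true mask
  full_a <- list(axis = 1, rect = list(c(0, 6), c(0, 6)))
  full_b <- list(axis = 2, rect = list(c(0, 6), c(0, 6)))
  expect_true(all(voi_mask(voi_spec(full_a, full_b), shape)))

  # disjoint back-projections give an empty mask with a warning flag
  a <- list(axis = 1, rect = list(c(0, 2), c(0, 6)))   # dims 2,3
  b <- list(axis = 3, rect = list(c(0, 6), c(4, 6)))   # dims 1,2
  expect_warning(m <- voi_mask(voi_spec(a, b), shape), "empty")
  expect_false(any(m))
  expect_true(attr(m, "empty_voi"))
})

test_that("voi_mask equals a brute-force membership predicate", {
  shape <- c(6, 6, 6)
  spec <- voi_spec(list(axis = 1, rect = list(c(2, 5), c(1, 4))),
                   list(axis = 3, rect = list(c(0, 3), c(1, 4))))
  m <- voi_mask(spec, shape)
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    # 0-based voxel (i-1, j-1, k-1); roi_a on axis 1 constrains (dim2, dim3),
    # roi_b on axis 3 constrains (dim1, dim2)
    expected <- (j - 1) >= 2 && (j - 1) < 5 && (k - 1) >= 1 && (k - 1) < 4 &&
      (i - 1) >= 0 && (i - 1) < 3 && (j - 1) >= 1 && (j - 1) < 4
    expect_identical(m[i, j, k], expected)
  }
})

test_that("box and polygon exclusions are subtracted after intersection", {
  shape <- c(6, 6, 6)
  full <- voi_spec(list(axis = 1, rect = list(c(0, 6), c(0, 6))),
                   list(axis = 2, rect = list(c(0, 6), c(0, 6))))
  with_box <- voi_spec(full$roi_a, full$roi_b,
                       list(list(box = list(c(0, 2), c(0, 2), c(0, 6)))))
  m <- voi_mask(with_box, shape)
  expect_false(any(m[1:2, 1:2, ]))
  expect_true(all(m[3:6, , ]))

  # square polygon swept along axis 3 covering 0-based cells 1..3 x 1..3
  poly <- matrix(c(0.5, 0.5, 3.5, 0.5, 3.5, 3.5, 0.5, 3.5),
                 ncol = 2, byrow = TRUE)
  with_poly <- voi_spec(full$roi_a, full$roi_b,
                        list(list(axis = 3, poly = poly, range = c(0, 2))))
  mp <- voi_mask(with_poly, shape)
  expect_false(any(mp[2:4, 2:4, 1:2]))
  expect_true(all(mp[, , 3:6]))
  expect_true(all(mp[1, , ], mp[5:6, , ]))
})

test_that("shrinking a rectangle never adds voxels", {
  set.seed(52)
  shape <- c(8, 8, 8)
  big <- voi_spec(list(axis = 1, rect = list(c(1, 7), c(1, 7))),
                  list(axis = 3, rect = list(c(0, 8), c(0, 8))))
  small <- voi_spec(list(axis = 1, rect = list(c(2, 6), c(2, 6))),
                    list(axis = 3, rect = list(c(0, 8), c(0, 8))))
  mb <- voi_mask(big, shape)
  ms <- voi_mask(small, shape)
  expect_true(all(mb | !ms))
})

test_that("degenerate rectangles and equal axes are rejected", {
  expect_error(voi_spec(list(axis = 1, rect = list(c(2, 2), c(0, 4))),
                        list(axis = 2, rect = list(c(0, 4), c(0, 4)))),
               "degenerate")
  expect_error(voi_spec(list(axis = 2, rect = list(c(0, 4), c(0, 4))),
                        list(axis = 2, rect = list(c(0, 4), c(0, 4)))),
               "different axes")
})

test_that("VOI specs round-trip through JSON", {
  spec <- voi_spec(list(axis = 1, rect = list(c(2, 5), c(1, 4))),
                   list(axis = 3, rect = list(c(0, 3), c(1, 4))),
                   list(list(box = list(c(0, 2), c(1, 3), c(0, 6)))))
  f <- withr::local_tempfile(fileext = ".json")
  write_voi_spec(spec, f)
  spec2 <- read_voi_spec(f)
  expect_equal(voi_mask(spec2, c(6, 6, 6)), voi_mask(spec, c(6, 6, 6)))
})
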