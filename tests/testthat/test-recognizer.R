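test_that("extract_patch fills the neighborhood with zero padding", {
  dims <- c(4, 4, 4)
  full <- as_voxel_grid(array(1L, dim = dims))
  # interior center: all 27 present
  expect_equal(sum(extract_patch(full, c(2, 2, 2))), 27)
  # corner center: only the 2x2x2 in-bounds octant
  expect_equal(sum(extract_patch(full, c(1, 1, 1))), 8)
  # empty grid: all-zero patch
  empty <- voxel_grid(dims)
  expect_equal(sum(extract_patch(empty, c(2, 3, 2))), 0)
  expect_error(extract_patch(full, c(0, 1, 1)), "out of bounds")
  expect_error(extract_patch(full, c(5, 1, 1)), "out of bounds")
})

test_that("local profile singles out the template matching a centered triple", {
  dims <- c(5, 5, 5)
  for (id in c(1, 2, 3, 4, 7, 10, 13)) {
    u <- template_direction(id)
    ctr <- c(3, 3, 3)
    g <- voxel_grid(dims, coords = rbind(ctr - u, ctr, ctr + u))
    prof <- local_profile(extract_patch(g, ctr))
    expect_equal(unname(prof[id]), 1, tolerance = 1e-10)
    expect_lt(max(prof[-id]), 1e-10)
  }
  # fully occupied neighborhood activates all 13 cells
  full <- as_voxel_grid(array(1L, dim = dims))
  expect_equal(unname(local_profile(extract_patch(full, c(3, 3, 3)))),
               rep(1, 13), tolerance = 1e-10)
  # all-empty neighborhood activates none
  expect_lt(max(local_profile(extract_patch(voxel_grid(dims), c(3, 3, 3)))),
            1e-10)
})

test_that("global response matches brute-force triple counting on random grids", {
  set.seed(101)
  for (rep in 1:200) {
    dims <- sample(3:8, 3, replace = TRUE)
    g <- random_grid(dims, p = runif(1, 0.05, 0.5))
    expect_equal(unname(global_response(g)), brute_force_response(g),
                 tolerance = 1e-6)
  }
})

test_that("a straight segment yields response L - 2 on its own template only", {
  dims <- c(11, 11, 11)
  for (id in 1:13) for (L in c(3, 5, 7)) {
    g <- segment_grid(dims, id, L)
    resp <- global_response(g)
    expect_equal(unname(resp[id]), L - 2, tolerance = 1e-9)
    expect_lt(max(resp[-id]), 1e-9)
    expect_equal(classify_orientation(g)$predicted, id)
  }
})

test_that("classification handles empty input, isolated voxels and ties", {
  # empty and isolated-voxel grids are featureless -> NONE sentinel
  expect_true(is.na(classify_orientation(voxel_grid(c(4, 4, 4)))$predicted))
  lone <- voxel_grid(c(5, 5, 5), coords = matrix(c(3, 3, 3), 1))
  expect_true(is.na(classify_orientation(lone)$predicted))
  expect_equal(classify_orientation(lone)$n_centers, 1)

  # two equal-length orthogonal segments tie -> lowest template id wins
  g <- voxel_grid(c(9, 9, 9))
  g <- set_voxels(g, cbind(2:6, 2, 2))  # x-segment (id 1)
  g <- set_voxels(g, cbind(8, 2:6, 8))  # y-segment (id 2), same length
  r <- classify_orientation(g)
  expect_equal(unname(r$responses[1]), unname(r$responses[2]))
  expect_equal(r$predicted, 1L)

  # body-diagonal segment of length 4 -> its id with response ~2
  gd <- segment_grid(c(8, 8, 8), 10, 4)
  rd <- classify_orientation(gd)
  expect_equal(rd$predicted, 10L)
  expect_equal(unname(rd$responses[10]), 2, tolerance = 1e-9)
})

test_that("responses are equivariant under the 48 signed axis permutations", {
  g <- random_grid(c(6, 7, 5), p = 0.25, seed = 77)
  base <- global_response(g)
  for (op in octahedral_group()) {
    tg <- transform_grid(g, op)
    tresp <- global_response(tg)
    for (id in 1:13) {
      expect_equal(unname(tresp[transform_direction_id(id, op)]),
                   unname(base[id]), tolerance = 1e-9)
    }
  }
})

test_that("trace normalization scales each cell by its own maximum", {
  tr <- rbind(c(1, 0, 5), c(2, 0, 10), c(4, 0, 2.5))
  nm <- normalize_responses(tr)
  expect_equal(nm[, 1], c(0.25, 0.5, 1))
  expect_equal(nm[, 2], c(0, 0, 0))    # all-zero series stays zero
  expect_equal(nm[, 3], c(0.5, 1, 0.25))
  # constant positive series maps to all ones
  expect_equal(normalize_responses(cbind(rep(3, 4)))[, 1], rep(1, 4))
  expect_error(normalize_responses(matrix(numeric(0), ncol = 13)), "nonempty")
})
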