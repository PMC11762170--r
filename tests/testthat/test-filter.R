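test_that("orientation counts reflect the local triple census", {
  dims <- c(7, 7, 7)
  # isolated voxel: no triple
  lone <- voxel_grid(dims, coords = matrix(c(4, 4, 4), 1))
  expect_equal(orientation_count(lone, c(4, 4, 4)), 0)
  # interior voxel of an axis segment: exactly the along-axis triple
  seg <- voxel_grid(dims, coords = cbind(2:6, 4, 4))
  expect_equal(orientation_count(seg, c(4, 4, 4)), 1)
  expect_equal(orientation_count(seg, c(2, 4, 4)), 0)  # endpoint
  # center of a fully occupied 3x3x3 block: all 13
  block <- as.matrix(expand.grid(3:5, 3:5, 3:5))
  full3 <- voxel_grid(dims, coords = block)
  expect_equal(orientation_count(full3, c(4, 4, 4)), 13)
})

test_that("the default rule reproduces preserve/discard semantics", {
  dims <- c(7, 7, 7)
  seg <- voxel_grid(dims, coords = cbind(2:6, 4, 4))
  expect_equal(is_positive(seg, c(4, 4, 4)), 1L)          # interior
  expect_equal(is_positive(seg, c(2, 4, 4)), 0L)          # endpoint
  noisy <- set_voxels(seg, matrix(c(6, 6, 6), 1))
  expect_equal(is_positive(noisy, c(6, 6, 6)), 0L)        # isolated noise
  # rule variants at an m = 1 element
  expect_equal(is_positive(seg, c(4, 4, 4), rule = "single"), 1L)
  expect_equal(is_positive(seg, c(4, 4, 4), rule = "multi"), 0L)
  expect_equal(is_positive(seg, c(4, 4, 4), rule = "all"), 0L)
})

test_that("separation of a segment plus scattered noise matches brute force", {
  dims <- c(9, 9, 9)
  g <- voxel_grid(dims, coords = cbind(3:7, 5, 5))  # L = 5 segment
  # 10 isolated noise voxels chosen so no accidental triple forms
  noise <- rbind(c(1, 1, 1), c(9, 1, 1), c(1, 9, 1), c(9, 9, 1),
                 c(1, 1, 9), c(9, 1, 9), c(1, 9, 9), c(9, 9, 9),
                 c(1, 5, 9), c(9, 5, 1))
  g <- set_voxels(g, noise)
  parts <- separate_features(g)
  expect_equal(n_occupied(parts$positive), 3)   # the 3 interior voxels
  expect_equal(n_occupied(parts$negative), 12)  # 2 endpoints + 10 noise
  oracle <- brute_force_positive(g)
  expect_equal(occupied_coords(parts$positive), oracle$positive,
               ignore_attr = TRUE)
  expect_equal(occupied_coords(parts$negative), oracle$negative,
               ignore_attr = TRUE)
  # empty grid -> both parts empty
  both <- separate_features(voxel_grid(dims))
  expect_equal(n_occupied(both$positive) + n_occupied(both$negative), 0)
})

test_that("separation invariants hold on random volumes", {
  set.seed(202)
  for (rep in 1:60) {
    g <- random_grid(sample(4:8, 3, replace = TRUE), p = runif(1, 0.05, 0.4))
    occ <- occupied_coords(g)
    parts <- separate_features(g)
    # partition: positive and negative are disjoint and cover the occupied set
    expect_equal(n_occupied(parts$positive) + n_occupied(parts$negative),
                 nrow(occ))
    expect_equal(sum(unclass(parts$positive) & unclass(parts$negative)), 0)
    # oracle agreement
    expect_equal(occupied_coords(parts$positive),
                 brute_force_positive(g)$positive, ignore_attr = TRUE)
    # rule partition: any = single + multi + all, elementwise
    n_any <- n_occupied(separate_features(g, rule = "any")$positive)
    n_parts <- vapply(c("single", "multi", "all"), function(r) {
      n_occupied(separate_features(g, rule = r)$positive)
    }, numeric(1))
    expect_equal(n_any, sum(n_parts))
  }
})

test_that("adding voxels never flips a positive element negative (any rule)", {
  set.seed(303)
  for (rep in 1:40) {
    g <- random_grid(c(6, 6, 6), p = 0.15)
    pos_before <- unclass(separate_features(g)$positive)
    empties <- which(unclass(g) == 0L)
    g2 <- g
    g2[sample(empties, min(5, length(empties)))] <- 1L
    pos_after <- unclass(separate_features(as_voxel_grid(unclass(g2)))$positive)
    expect_true(all(pos_after[pos_before == 1L] == 1L))
  }
})

test_that("voxel grids round-trip through point clouds", {
  g <- voxel_grid(c(5, 6, 7), coords = rbind(c(1, 1, 1), c(3, 4, 5), c(5, 6, 7)))
  cloud <- to_point_cloud(g)
  expect_equal(n_points(cloud), 3)
  expect_equal(cloud$points[1, ], c(x = 0, y = 0, z = 0))  # 0-based geometry
  back <- rasterize_cloud(cloud, c(5, 6, 7))
  expect_equal(unclass(back), unclass(g), ignore_attr = TRUE)
  expect_equal(n_points(to_point_cloud(voxel_grid(c(3, 3, 3)))), 0)
})

test_that("random subsampling is uniform-without-replacement and seeded", {
  cloud <- point_cloud(matrix(runif(90), ncol = 3))
  expect_equal(n_points(sample_random(cloud, 0, seed = 1)), 0)
  whole <- sample_random(cloud, 30, seed = 1)
  expect_setequal(asplit(whole$points, 1), asplit(cloud$points, 1))
  a <- sample_random(cloud, 10, seed = 99)
  b <- sample_random(cloud, 10, seed = 99)
  expect_equal(a$points, b$points)
  expect_error(sample_random(cloud, 31), "0..30")
})

test_that("farthest point sampling spreads points and hits segment extremes", {
  # n = 2 on a collinear cloud picks the two extreme endpoints
  segment <- point_cloud(cbind(0:10, 0, 0))
  for (s in 1:5) {
    picked <- sample_fps(segment, 2, seed = s)$points[, 1]
    expect_true(picked[2] %in% c(0, 10))  # farthest from any start is an end
    expect_gte(abs(diff(picked)), 5)  # start to the far end spans >= half
  }
  # n = |cloud| returns the whole cloud in some order
  all_pts <- sample_fps(segment, 11, seed = 1)
  expect_setequal(all_pts$points[, 1], 0:10)
  # FPS subsets are at least as spread out as random subsets (min pairwise
  # distance), on random clouds
  set.seed(404)
  wins <- 0
  for (rep in 1:20) {
    cloud <- point_cloud(matrix(runif(300, 0, 10), ncol = 3))
    mind <- function(p) min(dist(p))
    f <- mind(sample_fps(cloud, 12, seed = rep)$points)
    r <- mind(sample_random(cloud, 12, seed = rep)$points)
    if (f >= r) wins <- wins + 1
  }
  expect_gte(wins, 18)
  # determinism
  expect_equal(sample_fps(segment, 5, seed = 7)$points,
               sample_fps(segment, 5, seed = 7)$points)
})
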