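test_that("the grating sequence has the canonical block structure", {
  seqn <- gen_grating_sequence()
  ann <- seqn$annotation
  expect_equal(nrow(ann), 1600)
  expect_equal(sum(ann$state == "moving"), 800)
  expect_equal(sum(ann$state == "rest"), 800)
  # 4 orientations x 2 directions x 100 moving frames
  mov <- ann[ann$state == "moving", ]
  expect_equal(as.integer(table(mov$orientation_deg)), rep(200L, 4))
  expect_equal(unname(table(mov$orientation_deg, mov$direction)),
               matrix(100L, 4, 2), ignore_attr = TRUE)
  # blocks alternate: 100 moving then 100 rest
  expect_equal(ann$state[1:100], rep("moving", 100))
  expect_equal(ann$state[101:200], rep("rest", 100))
  # rest frames are all-zero
  rest_idx <- which(ann$state == "rest")
  expect_equal(sum(seqn$frames[, , rest_idx]), 0)
})

test_that("motion frames drift by one voxel per frame", {
  seqn <- gen_grating_sequence()
  ann <- seqn$annotation
  # 0-degree block, direction +1: stripes are level sets of y, so frame
  # t+1 equals frame t cyclically shifted by one voxel in -y
  # (period 8 divides H = 32, so the shift is an exact cyclic roll)
  b <- which(ann$state == "moving" & ann$orientation_deg == 0 &
               ann$direction == 1)
  for (t in b[1:5]) {
    cur <- seqn$frames[, , t]
    nxt <- seqn$frames[, , t + 1]
    rolled <- cur[, c(2:32, 1)]  # shift pattern down by one stripe phase
    expect_equal(nxt, rolled)
  }
  # the bar pattern itself: width 2 of every period 8
  f1 <- seqn$frames[, , b[1]]
  expect_equal(sum(f1), 32 * 8)  # 2/8 of 1024 voxels occupied
})

test_that("random-dot samples embed seeded orientation fragments", {
  cfg0 <- random_dot_config(n_moving = 0)
  s0 <- gen_random_dot_sample(cfg0, label = 4, seed = 11)
  expect_equal(n_occupied(s0$grid), 300)
  expect_null(s0$moving_centers)

  cfg2 <- random_dot_config(n_moving = 2)
  s2 <- gen_random_dot_sample(cfg2, label = 4, seed = 11)
  # each moving dot contributes a centered triple on the label template
  resp <- global_response(s2$grid)
  expect_gte(unname(resp[4]), 2)
  # determinism under a fixed seed
  s2b <- gen_random_dot_sample(cfg2, label = 4, seed = 11)
  expect_equal(unclass(s2$grid), unclass(s2b$grid), ignore_attr = TRUE)
  # a volume too small for any fragment triple errors out
  tiny <- random_dot_config(volume_dims = c(1, 1, 2), n_dots = 2, n_moving = 1)
  expect_error(gen_random_dot_sample(tiny, label = 1, seed = 1), "too small")
})

test_that("generated objects obey the segment law", {
  cfg <- object_dataset_config()
  # x-axis line, L = 5
  o1 <- gen_object(cfg, class_id = 1, length = 5, seed = 21)
  expect_equal(n_occupied(o1$grid), 5)
  expect_equal(classify_orientation(o1$grid)$predicted, 1L)
  # body diagonal, L = 3 -> response 1 on its template
  o2 <- gen_object(cfg, class_id = 10, length = 3, seed = 22)
  expect_equal(n_occupied(o2$grid), 3)
  expect_equal(unname(global_response(o2$grid)[10]), 1, tolerance = 1e-9)
  # thickness-2 axis bar, L = 6: four parallel lines -> c = 4 (L - 2)
  o3 <- gen_object(cfg, class_id = 2, length = 6, thickness = 2, seed = 23)
  expect_equal(n_occupied(o3$grid), 24)
  resp <- global_response(o3$grid)
  expect_equal(unname(resp[2]), 16, tolerance = 1e-9)
  expect_lt(max(resp[-2]), 1e-9)
  # thickness 2 is only defined for axis-aligned classes
  expect_error(gen_object(cfg, class_id = 5, length = 4, thickness = 2),
               "axis-aligned")
  # oversize objects are rejected
  expect_error(gen_object(cfg, class_id = 1, length = 17), "does not fit")
})

test_that("datasets are class-balanced, in-bounds and reproducible", {
  cfg <- object_dataset_config(split_sizes = c(train = 130, test = 65))
  ds <- gen_dataset(cfg, seed = 5)
  man <- ds$manifest
  expect_equal(nrow(man), 195)
  expect_equal(as.integer(table(man$split)), c(65L, 130L))
  # balance: size / 13 samples per class in each split
  expect_equal(as.integer(table(man$class_id[man$split == "train"])), rep(10L, 13))
  expect_equal(as.integer(table(man$class_id[man$split == "test"])), rep(5L, 13))
  # every realized object fits and is classified correctly when clean
  for (i in seq_len(nrow(man))) {
    smp <- realize_sample(ds, i %% 65 + 1, split = man$split[i])
    expect_true(all(occupied_coords(smp$grid) >= 1))
  }
  # regeneration under the same seed is identical
  ds2 <- gen_dataset(cfg, seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  # non-axis classes never get thickness 2
  expect_true(all(man$thickness[man$class_id > 3] == 1))
})

test_that("noise injection adds the rounded voxel count disjointly", {
  g <- gen_object(object_dataset_config(), 1, 6, seed = 31)$grid
  before <- n_occupied(g)
  # 16^3 at 5% -> round(0.05 * 4096) = 205 added voxels
  g5 <- inject_noise(g, 5, seed = 32)
  expect_equal(n_occupied(g5), before + 205)
  # original object voxels untouched
  expect_true(all(unclass(g5)[occupied_coords(g)] == 1L))
  # intensity 0 is the identity
  expect_identical(unclass(inject_noise(g, 0)), unclass(g))
  # seeded determinism
  expect_identical(unclass(inject_noise(g, 3, seed = 9)),
                   unclass(inject_noise(g, 3, seed = 9)))
  # requesting more noise than there are empty voxels errors
  tiny <- voxel_grid(c(2, 2, 2), coords = as.matrix(expand.grid(1:2, 1:2, 1:2))[1:7, ])
  expect_error(inject_noise(tiny, 50), "empty voxels")
})
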