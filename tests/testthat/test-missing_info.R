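test_that("intra_loss follows the thickness bookkeeping", {
  m <- data.frame(section_index = 1, cut_thickness_nm = 100,
                  et_slice_count = 135, voxel_size_nm = 0.664)
  # (100 - 135 * 0.664) / 0.664
  expect_equal(intra_loss(m), (100 - 135 * 0.664) / 0.664, tolerance = 1e-12)
  expect_equal(intra_loss(m), 15.60, tolerance = 0.01)

  m2 <- data.frame(section_index = 1, cut_thickness_nm = 66.4,
                   et_slice_count = 100, voxel_size_nm = 0.664)
  expect_equal(intra_loss(m2), 0, tolerance = 1e-9)

  m3 <- data.frame(section_index = 1, cut_thickness_nm = 10,
                   et_slice_count = 30, voxel_size_nm = 0.664)
  expect_warning(v <- intra_loss(m3), "thicker")
  expect_lt(v, 0)
  expect_true(isTRUE(attr(v, "negative")))

  m4 <- data.frame(section_index = 1, cut_thickness_nm = 100,
                   et_slice_count = 10, voxel_size_nm = 0)
  expect_error(intra_loss(m4), "voxel")
})

test_that("sensitivity map inverts the per-pixel z-gradient", {
  base <- matrix(runif(64, 0.2, 0.4), 8, 8)
  v1 <- array(0, dim = c(6, 8, 8))
  for (z in 1:6) v1[z, , ] <- base + (z - 1) * 1 # 1 gray per slice
  s1 <- sensitivity_map(image_stack(v1))
  expect_equal(unname(s1$raw[3, 4]), 1, tolerance = 1e-9)
  expect_true(all(abs(s1$raw - 1) < 1e-9))

  v2 <- array(0, dim = c(6, 8, 8))
  for (z in 1:6) v2[z, , ] <- base + (z - 1) * 2
  s2 <- sensitivity_map(image_stack(v2))
  expect_true(all(abs(s2$raw - 0.5) < 1e-9))

  # noisy ramp: raw map equals an independent finite-difference loop
  set.seed(2)
  v3 <- array(runif(6 * 8 * 8), dim = c(6, 8, 8))
  st3 <- image_stack(v3)
  s3 <- sensitivity_map(st3)
  eps <- diff(range(v3)) / 25500
  for (p in list(c(1, 1), c(4, 5), c(8, 8))) {
    acc <- 0
    for (z in 1:5) acc <- acc + abs(v3[z + 1, p[1], p[2]] - v3[z, p[1], p[2]])
    expect_equal(unname(s3$raw[p[1], p[2]]), 1 / max(acc / 5, eps),
                 tolerance = 1e-6)
  }
  expect_error(sensitivity_map(image_stack(array(1, c(1, 4, 4)))), "2 slices")
})

test_that("inter_loss recovers known deletion counts on uniform-change phantoms", {
  src <- make_phantom(phantom_spec(c(120, 96, 96), "ramp", seed = 7,
                                   ramp_rate = 0.004))
  ser0 <- slice_into_serial(src, 2, delete_top = c(0, 0),
                            delete_bot = c(0, 0), end_blur_frac = 0)
  # identical z-adjacent volumes with no gap: estimate 0
  expect_lt(inter_loss(ser0$sections[[1]], ser0$sections[[2]]), 1)
  same <- ser0$sections[[1]]
  expect_equal(inter_loss(same, same), 0)

  ser <- slice_into_serial(src, 2, delete_top = c(0, 4),
                           delete_bot = c(6, 0), end_blur_frac = 0)
  est <- inter_loss(ser$sections[[1]], ser$sections[[2]])
  expect_equal(est, 10, tolerance = 1)

  # a hot-pixel stain artifact is suppressed by the 10x10/sigma-3 filter
  s2 <- ser$sections[[2]]
  d <- s2$data
  d[, 48, 48] <- d[, 48, 48] + 0.2
  s2a <- image_stack(d, s2$voxel_size_nm)
  est_a <- inter_loss(ser$sections[[1]], s2a)
  expect_equal(est_a, est, tolerance = 1)

  expect_error(inter_loss(ser$sections[[1]],
                          image_stack(array(0.5, c(4, 10, 10)))),
               "common grid")
})

test_that("solve_distribution matches grid search and the KKT oracle", {
  # symmetric single volume
  sd1 <- solve_distribution(4)
  expect_equal(sd1$top, 2)
  expect_equal(sd1$bot, 2)

  # the two-volume instance has a known continuous optimum
  sd2 <- solve_distribution(c(4, 6), 5)
  expect_equal(c(sd2$top[1], sd2$bot[1], sd2$top[2], sd2$bot[2]),
               c(11 / 6, 13 / 6, 17 / 6, 19 / 6), tolerance = 1e-9)
  # oracle: dense grid search over the single free parameter
  obj <- function(th) {
    b1 <- 4 - th; t2 <- 5 - b1; b2 <- 6 - t2
    (th - b1)^2 + (t2 - b2)^2 + (t2 - b1)^2
  }
  ths <- seq(-5, 10, by = 1e-4)
  expect_equal(sd2$top[1], ths[which.min(vapply(ths, obj, numeric(1)))],
               tolerance = 1e-3)

  # random instances match an independent KKT solve
  set.seed(13)
  for (trial in 1:100) {
    n <- sample(1:5, 1)
    ci <- runif(n, 0, 12)
    cj <- if (n > 1) runif(n - 1, 0, 12) else numeric(0)
    sd <- solve_distribution(ci, cj)
    o <- oracle_gap_qp(ci, cj)
    expect_equal(sd$top, o$top, tolerance = 1e-8)
    expect_equal(sd$bot, o$bot, tolerance = 1e-8)
    # rounded intra sums within 1
    expect_true(all(abs(sd$rounded_top + sd$rounded_bot - ci) <= 1 + 1e-9))
    expect_true(all(sd$rounded_top >= 0 & sd$rounded_bot >= 0))
  }
})

test_that("time_parameter reproduces the printed schedule", {
  expect_equal(time_parameter(0, 10, 10, 5), 0)
  expect_equal(time_parameter(3, 4, 4, 3), 0.5)
  expect_equal(time_parameter(134, 135, 106, 15), 134 / 134.5)
  expect_equal(time_parameter(134, 135, 106, 15), 0.99628, tolerance = 1e-5)
  expect_error(time_parameter(1, 4, 4, -1), "nonnegative")
})

test_that("distillation loss combines the printed terms linearly", {
  cfg <- distillation_config(T = 2, alpha = 0.2)
  img <- matrix(runif(64), 8)
  # student equals teacher and reconstruction perfect: zero loss
  z <- distillation_loss(img, img, img, img, img, img, cfg)
  expect_equal(as.numeric(z), 0)

  # engineered L_rec = 1, L_dis = 1 gives 0.8 + 0.2 * 4 = 1.6
  ones <- matrix(1, 8, 8)
  zero <- matrix(0, 8, 8)
  l <- distillation_loss(ones, zero, 2 * ones, zero, 2 * ones, zero, cfg)
  expect_equal(attr(l, "L_rec"), 1)
  expect_equal(attr(l, "L_dis"), 1)
  expect_equal(as.numeric(l), 1.6)

  # alpha = 0 ignores the teacher entirely
  cfg0 <- distillation_config(T = 2, alpha = 0)
  l0 <- distillation_loss(ones, zero, matrix(runif(64), 8), zero,
                          matrix(runif(64), 8), zero, cfg0)
  expect_equal(as.numeric(l0), 1)

  # exact linearity in (L_rec, L_dis) for arbitrary (T, alpha)
  set.seed(4)
  for (trial in 1:10) {
    T_ <- runif(1, 0.5, 4)
    a <- runif(1)
    cfg_t <- distillation_config(T = T_, alpha = a)
    sf <- matrix(runif(64), 8); tf <- matrix(runif(64), 8)
    sa <- matrix(runif(64), 8); ta <- matrix(runif(64), 8)
    fr <- matrix(runif(64), 8); tr <- matrix(runif(64), 8)
    l <- distillation_loss(fr, tr, sf, tf, sa, ta, cfg_t)
    l_rec <- sqrt(mean((fr - tr)^2))
    l_dis <- 0.5 * mean(abs(sf / T_ - tf / T_)) +
      0.5 * mean(abs(sa / T_ - ta / T_))
    expect_equal(as.numeric(l), (1 - a) * l_rec + a * T_^2 * l_dis,
                 tolerance = 1e-12)
  }
  expect_error(distillation_loss(img, matrix(0, 4, 4), img, img, img, img,
                                 cfg), "shape")
})

test_that("gap interpolation honours the zero-flow and shift contracts", {
  ph <- make_phantom(phantom_spec(c(1, 128, 128), "blobs", seed = 21))
  img <- matrix(ph$data[1, , ], 128, 128)
  v <- image_stack(array(img, c(1, 128, 128)))
  # identical boundary slices reproduce themselves at every t
  gap <- interpolate_gap(v, v, 3)
  for (sl in gap) expect_lt(max(abs(sl - img)), 1e-6)
  expect_identical(interpolate_gap(v, v, 0), list())

  # shifted texture: the midpoint carries half the shift
  sh <- sset:::shift_image(img, 8, 0)
  v2 <- image_stack(array(sh, c(1, 128, 128)))
  gap2 <- interpolate_gap(v, v2, 3)
  expect_equal(best_shift(img, gap2[[2]]), c(4, 0), tolerance = 0.5)
})

test_that("fine-tuning the student decreases the loss, reproducibly", {
  ph <- make_phantom(phantom_spec(c(16, 48, 48), "blobs", seed = 31))
  # drifting texture: shift increases along z
  d <- ph$data
  for (z in 1:16) d[z, , ] <- sset:::shift_image(matrix(ph$data[1, , ], 48),
                                                 round((z - 1) / 3), 0)
  vol <- image_stack(d)
  v1 <- image_stack(d[1:8, , , drop = FALSE])
  v2 <- image_stack(d[9:16, , , drop = FALSE])
  cfg <- distillation_config(epochs = 15, lr = 0.2, seed = 5)
  st <- fine_tune_student(student_interpolator(seed = 5),
                          baseline_interpolator(), list(v1, v2), M = 0, cfg)
  traj <- attr(st, "loss_trajectory")
  expect_lt(traj[length(traj)], traj[1])
  expect_true(all(diff(traj) <= 1e-9)) # backtracking keeps it monotone

  # bitwise reproducibility under a fixed seed
  st2 <- fine_tune_student(student_interpolator(seed = 5),
                           baseline_interpolator(), list(v1, v2), M = 0, cfg)
  expect_identical(attr(st, "loss_trajectory"), attr(st2, "loss_trajectory"))
  expect_identical(st$params, st2$params)

  # pure distillation (alpha = 1, T = 1): student moves toward the teacher
  cfg1 <- distillation_config(T = 1, alpha = 1, epochs = 15, lr = 0.2,
                              seed = 5)
  st3 <- fine_tune_student(student_interpolator(seed = 5),
                           baseline_interpolator(), list(v1, v2), M = 0, cfg1)
  dis <- attr(st3, "l_dis_trajectory")
  expect_lt(median(dis[8:15]), median(dis[1:7]) + 1e-12)
})

test_that("assembly concatenates volumes and gaps with correct extents", {
  a <- image_stack(array(runif(5 * 6 * 7), c(5, 6, 7)))
  b <- image_stack(array(runif(5 * 6 * 7), c(5, 6, 7)))
  gap <- lapply(1:3, function(i) matrix(i, 6, 7))
  asm <- assemble_volume(list(a, b), list(gap))
  expect_identical(dim(asm$data), c(13L, 6L, 7L))
  expect_equal(asm$data[1:5, , ], a$data)
  expect_equal(asm$data[6, , ], matrix(1, 6, 7))
  expect_equal(asm$data[9:13, , ], b$data)

  plain <- assemble_volume(list(a, b), list(list()))
  expect_identical(dim(plain$data), c(10L, 6L, 7L))

  expect_error(assemble_volume(list(a, image_stack(array(1, c(2, 3, 3)))),
                               list(list())), "shape")
})

test_that("baseline interpolation restores z-continuity on phantoms", {
  src <- make_phantom(phantom_spec(c(60, 96, 96), "ramp", seed = 41,
                                   ramp_rate = 0.01))
  ser <- slice_into_serial(src, 2, delete_top = c(0, 3),
                           delete_bot = c(3, 0), end_blur_frac = 0)
  v1 <- ser$sections[[1]]; v2 <- ser$sections[[2]]
  jump_before <- mean(abs(v2$data[1, , ] - v1$data[dim(v1$data)[1], , ]))
  gap <- interpolate_gap(v1, v2, 6)
  asm <- assemble_volume(list(v1, v2), list(gap))
  nz1 <- dim(v1$data)[1]
  jumps_after <- vapply(nz1:(nz1 + 6), function(z) {
    mean(abs(asm$data[z + 1, , ] - asm$data[z, , ]))
  }, numeric(1))
  expect_lt(max(jumps_after), jump_before)

  # mean-intensity z profile is monotone where the ground truth ramp is
  prof <- vapply(seq_len(dim(asm$data)[1]), function(z) mean(asm$data[z, , ]),
                 numeric(1))
  expect_true(all(diff(prof) > 0))
})
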