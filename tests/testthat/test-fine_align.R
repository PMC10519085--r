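test_that("mean_image equals direct per-pixel summation", {
  const <- image_stack(array(7, dim = c(4, 5, 6)))
  expect_equal(mean_image(const), matrix(7, 5, 6))
  two <- image_stack(array(rep(c(0, 10), each = 1, times = 1),
                           dim = c(2, 3, 3)))
  two$data[1, , ] <- 0; two$data[2, , ] <- 10
  expect_equal(mean_image(two), matrix(5, 3, 3))
  set.seed(5)
  v <- image_stack(array(runif(4 * 6 * 7), dim = c(4, 6, 7)))
  oracle <- matrix(0, 6, 7)
  for (y in 1:6) for (x in 1:7) oracle[y, x] <- mean(v$data[, y, x])
  expect_equal(mean_image(v), oracle, tolerance = 1e-12)
})

test_that("block matching finds shifts, flags flat blocks, keeps decoys", {
  ph <- make_phantom(phantom_spec(c(1, 160, 160), "blobs", seed = 4))
  img <- matrix(ph$data[1, , ], 160, 160)
  g0 <- block_match(img, img, block_px = 32, stride_px = 32, search_px = 6)
  for (i in seq_along(g0$candidates)) {
    expect_equal(g0$candidates[[i]]$px[1], g0$nodes$cx[i])
    expect_equal(g0$candidates[[i]]$py[1], g0$nodes$cy[i])
    expect_gt(g0$candidates[[i]]$score[1], 0.999)
  }

  sh <- sset:::shift_image(img, 3, 0)
  g <- block_match(img, sh, block_px = 32, stride_px = 32, search_px = 8)
  interior <- g$nodes$ix > 1 & g$nodes$ix < max(g$nodes$ix)
  for (i in which(interior)) {
    d <- c(g$candidates[[i]]$px[1] - g$nodes$cx[i],
           g$candidates[[i]]$py[1] - g$nodes$cy[i])
    # oracle: exhaustive NCC over the window
    o <- oracle_ncc_best(img, sh, g$nodes$cx[i], g$nodes$cy[i], 32, 8)
    expect_equal(d, o[1:2])
    expect_equal(d, c(3, 0))
  }

  # flat block is textureless
  flat <- img
  flat[33:96, 33:96] <- 0.5
  gf <- block_match(flat, flat, block_px = 32, stride_px = 32, search_px = 4)
  centre <- which(gf$nodes$cx %in% c(48, 80) & gf$nodes$cy %in% c(48, 80))
  expect_true(any(gf$nodes$textureless[centre]))

  # repeated texture keeps several near-equal candidates: a periodic patch
  # has lattice-shifted self-matches inside the search window
  rep_img <- matrix(0.5, 160, 160)
  rep_img[49:112, 49:112] <- outer(0:63, 0:63, function(y, x) {
    0.5 + 0.4 * ((y %/% 8 + x %/% 8) %% 2)
  })
  gr <- block_match(rep_img, rep_img, block_px = 32, stride_px = 16,
                    search_px = 20, k_candidates = 3)
  multi <- vapply(gr$candidates, function(cc) {
    nrow(cc) >= 2 && cc$score[2] > 0.95
  }, logical(1))
  expect_true(any(multi))
})

test_that("bp_refine matches exhaustive enumeration on random small graphs", {
  for (trial in 1:30) {
    dims <- list(c(2, 3), c(3, 3), c(1, 5), c(2, 5), c(3, 2))[[
      (trial %% 5) + 1]]
    g <- random_match_graph(dims[1], dims[2], seed = trial)
    C <- c(25, 100, 400)[(trial %% 3) + 1]
    r <- bp_refine(g, C = C)
    expect_equal(r$objective, oracle_bp_minimum(g, C), tolerance = 1e-9)
    # the bp message-passing path is also near-optimal and monotone
    rb <- bp_refine(g, C = C, method = "bp")
    expect_true(all(diff(rb$trajectory) <= 1e-12))
  }
})

test_that("bp_refine resolves a decoy at the centre of a consistent grid", {
  nodes <- expand.grid(iy = 1:3, ix = 1:3)
  nodes$cx <- (nodes$ix - 1) * 10
  nodes$cy <- (nodes$iy - 1) * 10
  cands <- lapply(1:9, function(i) {
    data.frame(px = nodes$cx[i], py = nodes$cy[i], score = 1)
  })
  # centre node: a strong outlier candidate 15 px off, plus the consistent one
  cands[[5]] <- data.frame(px = nodes$cx[5] + c(15, 0),
                           py = nodes$cy[5] + c(0, 0),
                           score = c(0.99, 0.90))
  g <- match_graph(nodes, cands, 3, 3)
  r <- bp_refine(g, C = 1e4)
  expect_equal(r$assign[5], 2L)
  expect_equal(r$objective, 0)
  expect_equal(r$objective, oracle_bp_minimum(g, 1e4))

  # consistent single candidates: objective exactly zero
  cands0 <- cands
  cands0[[5]] <- data.frame(px = nodes$cx[5], py = nodes$cy[5], score = 1)
  g0 <- match_graph(nodes, cands0, 3, 3)
  expect_equal(bp_refine(g0, C = 100)$objective, 0)

  # C = 0 truncates everything; tie-break by score
  r0 <- bp_refine(g, C = 0)
  expect_equal(r0$assign[5], 1L) # score 0.99 beats 0.90
  expect_equal(r0$objective, 0)

  empty <- cands
  empty[[3]] <- data.frame(px = numeric(0), py = numeric(0),
                           score = numeric(0))
  expect_error(bp_refine(match_graph(nodes, empty, 3, 3), C = 1), "empty")
})

test_that("tps_field interpolates exactly and matches the kernel oracle", {
  # constant displacement reproduces everywhere
  src <- rbind(c(10, 10), c(50, 12), c(30, 40), c(15, 35))
  f <- tps_field(src, sweep(src, 2, c(-2, 1)), c(48, 64))
  expect_lt(max(abs(f$dx - 2)), 1e-8)
  expect_lt(max(abs(f$dy + 1)), 1e-8)

  # pure affine: zero bending energy, exact over the whole field
  gt <- affine_full(1.05, 0.1, 2, -0.08, 0.97, -1)
  dst <- apply_affine(gt, src)
  f2 <- tps_field(src, dst, c(40, 40))
  gx <- rep(0:39, each = 40); gy <- rep(0:39, 40)
  ref <- apply_affine(gt, cbind(gx, gy))
  expect_lt(max(abs(f2$dx - matrix(ref[, 1] - gx, 40, 40))), 1e-6)
  expect_lt(max(abs(f2$dy - matrix(ref[, 2] - gy, 40, 40))), 1e-6)

  # random control points: residual < 1e-8 at controls, oracle off-control
  set.seed(8)
  src6 <- cbind(runif(6, 5, 55), runif(6, 5, 55))
  disp <- matrix(rnorm(12, 0, 2), 6, 2)
  f3 <- tps_field(src6, src6 + disp, c(60, 60))
  at <- function(f, x, y) c(f$dx[round(y) + 1, round(x) + 1],
                            f$dy[round(y) + 1, round(x) + 1])
  probe <- rbind(c(7, 9), c(33, 21), c(48, 50))
  oracle <- oracle_tps_eval(src6, disp, probe)
  for (r in 1:3) {
    expect_equal(at(f3, probe[r, 1], probe[r, 2]), oracle[r, ],
                 tolerance = 1e-6)
  }
  idx <- cbind(round(src6[, 2]) + 1, round(src6[, 1]) + 1)
  # control-point residual on the continuous spline (integer grid probe is
  # only approximate): evaluate exactly via the oracle
  ctrl <- oracle_tps_eval(src6, disp, src6)
  expect_lt(max(abs(ctrl - disp)), 1e-8)

  expect_error(tps_field(cbind(1:3, 2 * (1:3)), cbind(1:3, 2 * (1:3)) + 1,
                         c(10, 10)), "collinear")
})

test_that("apply_field warps volumes per slice", {
  ph <- make_phantom(phantom_spec(c(3, 96, 96), "blobs", seed = 9))
  zero <- deformation_field(matrix(0, 96, 96), matrix(0, 96, 96))
  expect_equal(apply_field(ph, zero)$data, ph$data, tolerance = 1e-12)

  const <- deformation_field(matrix(3, 96, 96), matrix(0, 96, 96))
  warped <- apply_field(ph, const)
  core <- 10:80
  for (z in 1:3) {
    expect_equal(warped$data[z, core, core], ph$data[z, core, core + 3],
                 tolerance = 1e-9)
  }
  bad <- deformation_field(matrix(0, 10, 10), matrix(0, 10, 10))
  expect_error(apply_field(ph, bad), "shape")
})

test_that("block-match + consistency + TPS recovers a known elastic warp", {
  ph <- make_phantom(phantom_spec(c(4, 192, 192), "blobs", seed = 12))
  gt_field <- random_smooth_field(c(192, 192), max_disp = 3, seed = 5)
  mov <- apply_field(ph, gt_field)
  fa <- fine_align_pair(ph, mov, block_px = 32, stride_px = 32,
                        search_px = 8, C = 64)
  # mov already samples ph at x + gt, so warping mov back onto ph needs
  # the inverse displacement: field ~ -gt for smooth small fields
  core <- 33:160
  err <- sqrt((fa$field$dx[core, core] + gt_field$dx[core, core])^2 +
                (fa$field$dy[core, core] + gt_field$dy[core, core])^2)
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("consistency correction beats raw best-NCC under repeated-texture decoys", {
  wins <- 0
  n_trials <- 20
  for (trial in seq_len(n_trials)) {
    e <- decoy_trial(trial)
    if (e["bp"] < e["raw"] - 1e-9 ||
          (e["raw"] < 0.5 && e["bp"] <= e["raw"] + 1e-9)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, round(0.95 * n_trials))
})
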