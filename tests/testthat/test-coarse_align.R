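phantom_slice <- function(seed = 3, n = 256) {
  ph <- make_phantom(phantom_spec(c(1, n, n), "blobs", seed = seed))
  matrix(ph$data[1, , ], n, n)
}

test_that("rescale_to_common scales dimensions and preserves content", {
  img <- phantom_slice(1, 128)
  down <- rescale_to_common(img, 0.25)
  expect_identical(dim(down), c(32L, 32L))
  expect_identical(rescale_to_common(img, 1), img)
  # down then up restores dimensions with low-pass content
  restored <- rescale_to_common(rescale_to_common(img, 0.5), 2)
  expect_identical(dim(restored), dim(img))
  expect_gt(cor(as.vector(restored), as.vector(img)), 0.9)
  expect_error(rescale_to_common(img, 0.01), "8 px")
  # the 20K -> 5K bridge uses the magnification ratio: factor 4
  expect_identical(dim(rescale_to_common(matrix(0, 1024, 1024), 1 / 4)),
                   c(256L, 256L))
})

test_that("feature matching finds self-matches and known displacements", {
  img <- phantom_slice(5)
  m_self <- match_features(img, img)
  expect_gte(nrow(m_self$points_a), 10)
  disp <- m_self$points_b - m_self$points_a
  expect_lt(max(abs(disp)), 1e-6)

  sh <- sset:::shift_image(img, 20, 0)
  m <- match_features(img, sh)
  disp <- m$points_b - m$points_a
  med <- unname(apply(disp, 2, median))
  # oracle: exhaustive interior NCC peak
  expect_equal(med, best_shift(img, sh, search = 24), tolerance = 0.5)
  expect_equal(med, c(20, 0), tolerance = 0.5)

  set.seed(9)
  noise_a <- matrix(runif(96 * 96), 96)
  noise_b <- matrix(runif(96 * 96), 96)
  expect_error(match_features(noise_a, noise_b), "insufficient correspondence")
})

test_that("ransac_affine recovers models and rejects outliers", {
  set.seed(4)
  gt <- affine_full(1.04, 0.08, 6, -0.05, 0.97, -3)
  src <- matrix(runif(40, 0, 200), 20, 2)
  dst <- apply_affine(gt, src)
  r <- ransac_affine(list(points_a = src, points_b = dst), seed = 1)
  expect_equal(r$model$matrix, gt$matrix, tolerance = 1e-6)
  expect_true(all(r$inlier_mask))
  expect_lt(r$residual_rms_px, 1e-6)

  # 30% outliers, small inlier noise
  noise <- 0.3
  dst_n <- dst + matrix(rnorm(40, 0, noise), 20, 2)
  bad <- sample(20, 6)
  dst_n[bad, ] <- matrix(runif(12, 0, 200), 6, 2)
  r2 <- ransac_affine(list(points_a = src, points_b = dst_n),
                      inlier_threshold_px = 3, seed = 2)
  expect_true(all(!r2$inlier_mask[bad] |
                    sqrt(rowSums((apply_affine(gt, src) - dst_n)^2))[bad] < 3))
  # oracle: exhaustive 3-subset search on this small instance
  best <- -1
  combs <- combn(20, 3)
  for (ci in seq_len(ncol(combs))) {
    s <- combs[, ci]
    m <- tryCatch(fit_affine(src[s, ], dst_n[s, ]), error = function(e) NULL)
    if (is.null(m)) next
    inl <- sqrt(rowSums((apply_affine(m, src) - dst_n)^2)) <= 3
    best <- max(best, sum(inl))
  }
  expect_gte(sum(r2$inlier_mask), best - 1)
  # parameters within a small multiple of the noise scale
  expect_equal(r2$model$matrix[1:2, 1:2], gt$matrix[1:2, 1:2],
               tolerance = 2 * noise)
  expect_equal(r2$model$matrix[1:2, 3], gt$matrix[1:2, 3],
               tolerance = 3 * noise)

  col <- cbind(seq(0, 20, length.out = 3), seq(0, 40, length.out = 3))
  expect_error(ransac_affine(list(points_a = col, points_b = col), seed = 1),
               "consensus|collinear")
})

test_that("chain_affine multiplies in application order", {
  a <- affine_full(1.1, 0.2, 3, -0.1, 0.9, 1)
  expect_equal(chain_affine(list(a, affine_inverse(a)))$matrix, diag(3),
               tolerance = 1e-12)
  t12 <- chain_affine(list(affine_translation(1, 0), affine_translation(0, 2)))
  expect_equal(t12$matrix, affine_translation(1, 2)$matrix)
  set.seed(2)
  ms <- lapply(1:3, function(i) {
    affine_full(rnorm(1, 1, 0.1), rnorm(1, 0, 0.1), rnorm(1),
                rnorm(1, 0, 0.1), rnorm(1, 1, 0.1), rnorm(1))
  })
  expect_equal(chain_affine(ms)$matrix,
               ms[[3]]$matrix %*% ms[[2]]$matrix %*% ms[[1]]$matrix,
               tolerance = 1e-12)
})

test_that("apply_affine_to_volume warps slices and round-trips", {
  ph <- make_phantom(phantom_spec(c(3, 128, 128), "blobs", seed = 6))
  ident <- apply_affine_to_volume(ph, affine_model(diag(3)))
  expect_equal(ident$data, ph$data, tolerance = 1e-12)
  there <- apply_affine_to_volume(ph, affine_translation(5, -3))
  back <- apply_affine_to_volume(there, affine_translation(-5, 3))
  core <- 20:108
  rng <- diff(range(ph$data))
  expect_lt(mean(abs(back$data[, core, core] - ph$data[, core, core])) / rng,
            0.01)
  sing <- affine_model(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_error(apply_affine_to_volume(ph, sing), "singular")
})

test_that("full match-ransac-warp pipeline recovers a known affine to sub-pixel", {
  img <- phantom_slice(3)
  gt <- affine_similarity(1.03, 8 * pi / 180, 5, -7)
  vol <- image_stack(array(img, c(1, 256, 256)))
  warped <- matrix(apply_affine_to_volume(vol, gt)$data[1, , ], 256, 256)
  r <- estimate_pair_affine(warped, img, seed = 1, refine = TRUE)
  g <- as.matrix(expand.grid(x = seq(32, 223, 8), y = seq(32, 223, 8)))
  rms <- sqrt(mean(rowSums((apply_affine(r$model, g) -
                              apply_affine(gt, g))^2)))
  expect_lt(rms, 1)
})

test_that("the 5K-20K-ET chain agrees with the direct transform on phantoms", {
  # build a two-scale scene: the 5K view is the downscaled wide field, the
  # 20K view is a centred crop at full resolution
  wide <- phantom_slice(8, 512)
  crop20k_a <- wide[129:384, 129:384]
  k5_a <- rescale_to_common(wide, 0.5)
  gt <- affine_translation(14, -9) # inter-section motion at full resolution
  wide_b <- matrix(apply_affine_to_volume(
    image_stack(array(wide, c(1, 512, 512))), gt)$data[1, , ], 512, 512)
  crop20k_b <- wide_b[129:384, 129:384]
  k5_b <- rescale_to_common(wide_b, 0.5)

  # direct 20K(b) -> 20K(a)
  direct <- estimate_pair_affine(crop20k_b, crop20k_a, seed = 1,
                                 refine = TRUE)$model
  # bridged: 20K(b) -> 5K(b) -> 5K(a) -> 20K(a)
  b_to_5k <- estimate_pair_affine(crop20k_b, k5_b, scale_a = 0.5,
                                  seed = 1)$model
  k5_link <- estimate_pair_affine(k5_b, k5_a, seed = 1, refine = TRUE)$model
  a_from_5k <- affine_inverse(
    estimate_pair_affine(crop20k_a, k5_a, scale_a = 0.5, seed = 1)$model)
  chained <- chain_affine(list(b_to_5k, k5_link, a_from_5k))
  g <- as.matrix(expand.grid(x = seq(48, 208, 16), y = seq(48, 208, 16)))
  dev <- sqrt(rowSums((apply_affine(chained, g) - apply_affine(direct, g))^2))
  expect_lt(sqrt(mean(dev^2)), 0.5)
})
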