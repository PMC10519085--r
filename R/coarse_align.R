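# Coarse alignment of consecutive ET volumes: rescale multi-magnification
# images to a common physical pixel size, match local features, estimate a
# robust affine (RANSAC), optionally polish it against the intensities, and
# chain transforms across the 5K -> 20K -> ET-mean bridge.

#' Rescale an image to a common physical pixel size
#'
#' @param image numeric matrix
#' @param zoom_factor positive scale factor (output dims = round(input x
#'   factor)); e.g. comparing a 20K image against 5K uses 5000/20000 = 0.25
#'   on the 20K image (or 4 on the 5K one)
#' @return resized matrix (bilinear)
#' @export
rescale_to_common <- function(image, zoom_factor) {
  stopifnot(zoom_factor > 0)
  out_shape <- round(dim(image) * zoom_factor)
  if (any(out_shape < 8)) {
    stop("rescale_to_common: output smaller than 8 px per side")
  }
  resize_image(image, out_shape)
}

#' Robust affine estimation from putative matches (RANSAC)
#'
#' Samples minimal 3-point subsets, scores consensus at
#' `inlier_threshold_px`, and refits the best model on all inliers by least
#' squares. Reproducible for a fixed seed.
#'
#' @param matches a `feature_match_set` (or list with `points_a`,
#'   `points_b`)
#' @param inlier_threshold_px inlier residual threshold in pixels
#' @param n_iter number of random hypotheses
#' @param seed RNG seed
#' @return list (`robust_affine_result`): `model` (`affine2d` mapping
#'   a-coordinates to b-coordinates), `inlier_mask`, `residual_rms_px`
#' @export
ransac_affine <- function(matches, inlier_threshold_px = 3, n_iter = 2000,
                          seed = 1) {
  pa <- rbind_points(matches$points_a)
  pb <- rbind_points(matches$points_b)
  n <- nrow(pa)
  if (n < 3) stop("ransac_affine: need at least 3 matches")
  best_inl <- NULL
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 3)
      m <- tryCatch(fit_affine(pa[s, ], pb[s, ]), error = function(e) NULL)
      if (is.null(m)) next
      pred <- apply_affine(m, pa)
      res <- sqrt(rowSums((pred - pb)^2))
      inl <- res <= inlier_threshold_px
      if (sum(inl) >= 3 && (is.null(best_inl) || sum(inl) > sum(best_inl))) {
        best_inl <- inl
      }
    }
  })
  if (is.null(best_inl)) {
    stop("ransac_affine: no consensus of at least 3 matches ",
         "(degenerate or incompatible correspondences)")
  }
  model <- fit_affine(pa[best_inl, , drop = FALSE], pb[best_inl, , drop = FALSE])
  # one re-consensus pass after the least-squares refit
  res <- sqrt(rowSums((apply_affine(model, pa) - pb)^2))
  inl <- res <= inlier_threshold_px
  if (sum(inl) >= 3) {
    model <- fit_affine(pa[inl, , drop = FALSE], pb[inl, , drop = FALSE])
    res <- sqrt(rowSums((apply_affine(model, pa) - pb)^2))
    inl <- res <= inlier_threshold_px
  } else {
    inl <- best_inl
  }
  structure(
    list(
      model = model,
      inlier_mask = inl,
      residual_rms_px = sqrt(mean(res[inl]^2))
    ),
    class = "robust_affine_result"
  )
}

#' Intensity-based affine polish (Gauss-Newton on SSD)
#'
#' Refines a feature-estimated affine against the image intensities with an
#' additive Gauss-Newton scheme, for sub-pixel residuals on low-noise
#' pairs. `model` maps ref pixel coordinates to mov pixel coordinates.
#'
#' @param ref,mov numeric matrices
#' @param model initial `affine2d`
#' @param max_iter iteration cap
#' @param tol stop when the parameter update norm drops below this
#' @return refined `affine2d`
#' @export
refine_affine_intensity <- function(ref, mov, model, max_iter = 30,
                                    tol = 1e-4) {
  ref <- contrast_stretch(ref)
  mov <- contrast_stretch(mov)
  h <- nrow(ref); w <- ncol(ref)
  step <- max(1, floor(min(h, w) / 128))
  # skip a border margin: warped inputs carry fill there, which biases SSD
  my <- max(2, round(h * 0.12))
  mx <- max(2, round(w * 0.12))
  ys <- seq(my, h - my, by = step) - 1
  xs <- seq(mx, w - mx, by = step) - 1
  g <- expand.grid(y = ys, x = xs)
  gr <- img_gradients(mov)
  p <- model$matrix[1:2, ]
  # photometric gain/bias absorbs the contrast mismatch between the images
  pg <- 1; pb <- 0
  for (it in seq_len(max_iter)) {
    sx <- p[1, 1] * g$x + p[1, 2] * g$y + p[1, 3]
    sy <- p[2, 1] * g$x + p[2, 2] * g$y + p[2, 3]
    sm <- bilinear_sample(mov, sx, sy)
    ok <- sm$valid
    if (sum(ok) < 64) break
    vals <- sm$values[ok]
    err <- pg * vals + pb - ref[cbind(g$y[ok] + 1, g$x[ok] + 1)]
    gx <- pg * bilinear_sample(gr$gx, sx, sy)$values[ok]
    gy <- pg * bilinear_sample(gr$gy, sx, sy)$values[ok]
    # Jacobian wrt (a, b, c, d, e, f, gain, bias)
    j <- cbind(gx * g$x[ok], gx * g$y[ok], gx, gy * g$x[ok], gy * g$y[ok], gy,
               vals, 1)
    jtj <- crossprod(j) + diag(1e-8, 8)
    delta <- tryCatch(solve(jtj, -crossprod(j, err)), error = function(e) NULL)
    if (is.null(delta)) break
    p <- p + matrix(delta[1:6], 2, 3, byrow = TRUE)
    pg <- pg + delta[7]
    pb <- pb + delta[8]
    if (sqrt(sum(delta[1:6]^2)) < tol) break
  }
  affine_full(p[1, 1], p[1, 2], p[1, 3], p[2, 1], p[2, 2], p[2, 3])
}

#' Estimate the affine between two images at possibly different scales
#'
#' Rescales both images to a common physical pixel size, matches features,
#' runs RANSAC, optionally polishes against the intensities, and expresses
#' the result in the original pixel coordinates of each image.
#'
#' @param img_a,img_b numeric matrices
#' @param scale_a,scale_b zoom factors taking each image to the common
#'   scale (e.g. 0.25 for a 20K image matched against a 5K one)
#' @param ratio Lowe ratio
#' @param inlier_threshold_px RANSAC threshold at the common scale
#' @param n_iter,seed RANSAC controls
#' @param refine polish with [refine_affine_intensity()] (only meaningful
#'   when both images share one modality)
#' @return `robust_affine_result`; `model` maps img_a pixel coordinates to
#'   img_b pixel coordinates
#' @export
estimate_pair_affine <- function(img_a, img_b, scale_a = 1, scale_b = 1,
                                 ratio = 0.8, inlier_threshold_px = 3,
                                 n_iter = 2000, seed = 1, refine = FALSE) {
  a <- if (scale_a != 1) rescale_to_common(img_a, scale_a) else img_a
  b <- if (scale_b != 1) rescale_to_common(img_b, scale_b) else img_b
  m <- match_features(a, b, ratio = ratio)
  r <- ransac_affine(m, inlier_threshold_px = inlier_threshold_px,
                     n_iter = n_iter, seed = seed)
  model <- r$model
  if (refine) model <- refine_affine_intensity(a, b, model)
  if (scale_a != 1 || scale_b != 1) {
    to_common_a <- affine_similarity(scale_a, 0)
    from_common_b <- affine_similarity(1 / scale_b, 0)
    model <- chain_affine(list(to_common_a, model, from_common_b))
  }
  structure(
    list(model = model, inlier_mask = r$inlier_mask,
         residual_rms_px = r$residual_rms_px),
    class = "robust_affine_result"
  )
}

#' Apply a 2D affine to every slice of a volume
#'
#' Backward warping with bilinear interpolation: output pixel `(x, y)`
#' samples the input at `model(x, y)`, so `model` maps output coordinates
#' into input coordinates. Out-of-domain pixels are zero-filled and
#' recorded in a validity mask attribute.
#'
#' @param vol an `image_stack`
#' @param model `affine2d`
#' @param output_shape optional `(y, x)` output size (defaults to input)
#' @return warped `image_stack` with attribute `validity` (logical matrix)
#' @export
apply_affine_to_volume <- function(vol, model, output_shape = NULL) {
  stopifnot(inherits(vol, "image_stack"), inherits(model, "affine2d"))
  if (abs(det(model$matrix[1:2, 1:2])) < 1e-14) {
    stop("apply_affine_to_volume: singular model")
  }
  d <- dim(vol$data)
  if (is.null(output_shape)) output_shape <- d[2:3]
  oh <- output_shape[1]; ow <- output_shape[2]
  g <- expand.grid(y = seq_len(oh) - 1, x = seq_len(ow) - 1)
  src <- apply_affine(model, cbind(g$x, g$y))
  out <- array(0, dim = c(d[1], oh, ow))
  valid <- NULL
  for (z in seq_len(d[1])) {
    sm <- bilinear_sample(matrix(vol$data[z, , ], d[2], d[3]),
                          src[, 1], src[, 2])
    out[z, , ] <- matrix(sm$values, oh, ow)
    if (is.null(valid)) valid <- matrix(sm$valid, oh, ow)
  }
  prev <- attr(vol, "validity") # compose through successive warps
  if (!is.null(prev)) {
    pv <- bilinear_sample(prev * 1, src[, 1], src[, 2])$values
    valid <- valid & matrix(pv > 0.999, oh, ow)
  }
  res <- image_stack(out, vol$voxel_size_nm, vol$origin_label)
  attr(res, "validity") <- valid
  res
}

#' Coarse-align a series of sections across the multi-resolution bridge
#'
#' For each consecutive pair (i, i+1) the transform taking section i+1's
#' ET-mean coordinates into section i's is built by chaining
#' `ET(i+1) -> 20K(i+1) -> 5K(i+1) -> 5K(i) -> 20K(i) -> ET(i)`: the rich
#' low-magnification TEM image guides the inter-section step while the
#' same-magnification 20K image bridges the contrast gap between TEM and
#' tomographic reconstructions. When `tem5k`/`tem20k` are omitted the
#' inter-section affine is estimated directly between the ET mean images.
#'
#' @param et_means list of ET z-mean images (one per section)
#' @param tem20k optional list of 20K TEM images
#' @param tem5k optional list of 5K TEM images
#' @param mag_ratio magnification ratio 20K/5K (default 4)
#' @param et_scale zoom factor taking ET-mean pixels to 20K pixels
#' @param seed RANSAC seed
#' @param refine intensity polish for the same-modality inter-section step
#' @return list of `affine2d`, one per pair; element i maps section i+1
#'   ET-mean pixel coordinates into section i's frame
#' @export
coarse_align_sections <- function(et_means, tem20k = NULL, tem5k = NULL,
                                  mag_ratio = 4, et_scale = 1, seed = 1,
                                  refine = TRUE) {
  n <- length(et_means)
  stopifnot(n >= 2)
  use_bridge <- !is.null(tem20k) && !is.null(tem5k)
  models <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    if (!use_bridge) {
      r <- estimate_pair_affine(et_means[[i + 1]], et_means[[i]],
                                seed = seed, refine = refine)
      models[[i]] <- r$model
      next
    }
    # each link maps the first argument's coords into the second's
    et_to_20k_mov <- estimate_pair_affine(et_means[[i + 1]], tem20k[[i + 1]],
                                          scale_a = et_scale, seed = seed)$model
    k20_to_5k_mov <- estimate_pair_affine(tem20k[[i + 1]], tem5k[[i + 1]],
                                          scale_a = 1 / mag_ratio,
                                          seed = seed)$model
    k5_mov_to_ref <- estimate_pair_affine(tem5k[[i + 1]], tem5k[[i]],
                                          seed = seed, refine = refine)$model
    k5_to_20k_ref <- affine_inverse(
      estimate_pair_affine(tem20k[[i]], tem5k[[i]], scale_a = 1 / mag_ratio,
                           seed = seed)$model
    )
    k20_to_et_ref <- affine_inverse(
      estimate_pair_affine(et_means[[i]], tem20k[[i]], scale_a = et_scale,
                           seed = seed)$model
    )
    models[[i]] <- chain_affine(list(
      et_to_20k_mov, k20_to_5k_mov, k5_mov_to_ref, k5_to_20k_ref, k20_to_et_ref
    ))
  }
  models
}
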