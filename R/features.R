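# Scale/rotation-invariant local features: difference-of-Gaussian keypoint
# detection with subpixel refinement, dominant-orientation assignment and a
# 4x4x8 gradient-orientation-histogram descriptor. Deterministic given the
# input image.

half_sample <- function(img) {
  img[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

img_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# 3x3x3 local extrema of a DoG triplet above a contrast threshold.
dog_extrema <- function(d_prev, d_cur, d_next, thresh) {
  h <- nrow(d_cur); w <- ncol(d_cur)
  if (h < 3 || w < 3) return(NULL)
  core <- d_cur[2:(h - 1), 2:(w - 1)]
  is_max <- abs(core) > thresh
  is_min <- is_max
  for (dy in -1:1) for (dx in -1:1) {
    ys <- (2 + dy):(h - 1 + dy)
    xs <- (2 + dx):(w - 1 + dx)
    for (layer in list(d_prev, d_cur, d_next)) {
      nb <- layer[ys, xs]
      if (identical(layer, d_cur) && dy == 0 && dx == 0) next
      is_max <- is_max & core >= nb
      is_min <- is_min & core <= nb
    }
  }
  idx <- which(is_max | is_min, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(y = idx[, 1] + 1, x = idx[, 2] + 1) # back to full-layer indexing
}

detect_keypoints_octave <- function(img, octave, n_scales, sigma0,
                                    contrast_thresh, edge_ratio) {
  k <- 2^(1 / n_scales)
  n_layers <- n_scales + 3
  sigmas <- sigma0 * k^(0:(n_layers - 1))
  gs <- vector("list", n_layers)
  gs[[1]] <- gauss_filter(img, 2 * ceiling(3 * sigmas[1]) + 1, sigmas[1])
  for (i in 2:n_layers) {
    s_inc <- sqrt(max(sigmas[i]^2 - sigmas[i - 1]^2, 0.01))
    gs[[i]] <- gauss_filter(gs[[i - 1]], 2 * ceiling(3 * s_inc) + 1, s_inc)
  }
  dog <- lapply(1:(n_layers - 1), function(i) gs[[i + 1]] - gs[[i]])
  kps <- list()
  for (s in 2:(n_layers - 2)) {
    ext <- dog_extrema(dog[[s - 1]], dog[[s]], dog[[s + 1]], contrast_thresh)
    if (is.null(ext)) next
    d <- dog[[s]]
    h <- nrow(d); w <- ncol(d)
    for (r in seq_len(nrow(ext))) {
      y <- ext[r, "y"]; x <- ext[r, "x"]
      if (y < 3 || y > h - 2 || x < 3 || x > w - 2) next
      # in-plane Hessian for edge rejection and subpixel offset
      dxx <- d[y, x + 1] + d[y, x - 1] - 2 * d[y, x]
      dyy <- d[y + 1, x] + d[y - 1, x] - 2 * d[y, x]
      dxy <- (d[y + 1, x + 1] - d[y + 1, x - 1] -
                d[y - 1, x + 1] + d[y - 1, x - 1]) / 4
      tr <- dxx + dyy
      det_h <- dxx * dyy - dxy^2
      if (det_h <= 0 || tr^2 / det_h >= (edge_ratio + 1)^2 / edge_ratio) next
      gx <- (d[y, x + 1] - d[y, x - 1]) / 2
      gy <- (d[y + 1, x] - d[y - 1, x]) / 2
      den <- det_h
      ox <- -(dyy * gx - dxy * gy) / den
      oy <- -(-dxy * gx + dxx * gy) / den
      if (!is.finite(ox) || !is.finite(oy) || abs(ox) > 1 || abs(oy) > 1) {
        ox <- 0; oy <- 0
      }
      kps[[length(kps) + 1]] <- list(
        x = (x - 1) + ox, y = (y - 1) + oy, octave = octave, layer = s,
        sigma = sigmas[s], response = abs(d[y, x])
      )
    }
  }
  list(keypoints = kps, gauss = gs)
}

keypoint_orientations <- function(gx, gy, kp, n_bins = 36) {
  h <- nrow(gx); w <- ncol(gx)
  sig <- 1.5 * kp$sigma
  rad <- max(3, round(3 * sig))
  x0 <- round(kp$x) + 1; y0 <- round(kp$y) + 1
  xs <- max(2, x0 - rad):min(w - 1, x0 + rad)
  ys <- max(2, y0 - rad):min(h - 1, y0 + rad)
  if (length(xs) < 3 || length(ys) < 3) return(0)
  sgx <- gx[ys, xs]; sgy <- gy[ys, xs]
  mag <- sqrt(sgx^2 + sgy^2)
  ang <- atan2(sgy, sgx) %% (2 * pi)
  wgt <- outer(exp(-((ys - y0)^2) / (2 * sig^2)),
               exp(-((xs - x0)^2) / (2 * sig^2)))
  bins <- pmin(floor(ang / (2 * pi) * n_bins) + 1, n_bins)
  hist_ <- numeric(n_bins)
  acc <- tapply(as.vector(mag * wgt), as.vector(bins), sum)
  hist_[as.integer(names(acc))] <- acc
  for (i in 1:3) { # circular smoothing
    hist_ <- (c(tail(hist_, 1), head(hist_, -1)) + hist_ +
                c(tail(hist_, -1), head(hist_, 1))) / 3
  }
  pk <- max(hist_)
  if (pk <= 0) return(0)
  peaks <- which(hist_ >= 0.8 * pk &
                   hist_ >= c(tail(hist_, 1), head(hist_, -1)) &
                   hist_ >= c(tail(hist_, -1), head(hist_, 1)))
  if (length(peaks) == 0) peaks <- which.max(hist_)
  angs <- sapply(peaks, function(p) {
    l <- hist_[if (p == 1) n_bins else p - 1]
    c_ <- hist_[p]
    r <- hist_[if (p == n_bins) 1 else p + 1]
    den <- l - 2 * c_ + r
    off <- if (abs(den) < 1e-12) 0 else 0.5 * (l - r) / den
    ((p - 1 + off) / n_bins) * 2 * pi
  })
  head(sort(angs), 2)
}

keypoint_descriptor <- function(gx, gy, kp, theta, n_cells = 4, n_ori = 8) {
  h <- nrow(gx); w <- ncol(gx)
  spacing <- max(0.8, 0.75 * kp$sigma)
  n_samp <- n_cells * 4
  half <- (n_samp - 1) / 2
  ct <- cos(theta); st <- sin(theta)
  u <- rep(seq_len(n_samp) - 1 - half, times = n_samp)
  v <- rep(seq_len(n_samp) - 1 - half, each = n_samp)
  sx <- kp$x + spacing * (ct * u - st * v)
  sy <- kp$y + spacing * (st * u + ct * v)
  gxs <- bilinear_sample(gx, sx, sy)
  gys <- bilinear_sample(gy, sx, sy)
  ok <- gxs$valid & gys$valid
  if (mean(ok) < 0.5) return(NULL)
  # rotate gradients into the keypoint frame
  rx <- ct * gxs$values + st * gys$values
  ry <- -st * gxs$values + ct * gys$values
  mag <- sqrt(rx^2 + ry^2) * ok
  ang <- atan2(ry, rx) %% (2 * pi)
  wgt <- exp(-(u^2 + v^2) / (2 * (half + 0.5)^2))
  # cell coordinates in [0, n_cells), bilinear over cells, linear over bins
  cu <- (u + half + 0.5) / 4 - 0.5
  cv <- (v + half + 0.5) / 4 - 0.5
  ob <- ang / (2 * pi) * n_ori
  desc <- numeric(n_cells * n_cells * n_ori)
  cu0 <- floor(cu); cv0 <- floor(cv); ob0 <- floor(ob)
  fu <- cu - cu0; fv <- cv - cv0; fo <- ob - ob0
  wmag <- mag * wgt
  for (du in 0:1) for (dv in 0:1) for (do_ in 0:1) {
    cui <- cu0 + du; cvi <- cv0 + dv
    obi <- (ob0 + do_) %% n_ori
    wcontrib <- wmag *
      (du * fu + (1 - du) * (1 - fu)) *
      (dv * fv + (1 - dv) * (1 - fv)) *
      (do_ * fo + (1 - do_) * (1 - fo))
    keep <- cui >= 0 & cui < n_cells & cvi >= 0 & cvi < n_cells & wcontrib > 0
    if (!any(keep)) next
    idx <- (cvi[keep] * n_cells + cui[keep]) * n_ori + obi[keep] + 1
    acc <- tapply(wcontrib[keep], idx, sum)
    ii <- as.integer(names(acc))
    desc[ii] <- desc[ii] + acc
  }
  nrm <- sqrt(sum(desc^2))
  if (nrm < 1e-12) return(NULL)
  desc <- pmin(desc / nrm, 0.2)
  desc / max(sqrt(sum(desc^2)), 1e-12)
}

#' Detect and describe local features
#'
#' @param img numeric matrix (any intensity range; contrast-stretched
#'   internally)
#' @param max_features keep at most this many strongest keypoints
#' @param n_scales scales per octave
#' @param contrast_thresh DoG contrast threshold on the \[0, 1\] scale
#' @return list with `xy` (n x 2 full-resolution 0-based coordinates),
#'   `desc` (n x 128 matrix), `sigma`, `response`
#' @export
detect_features <- function(img, max_features = 500, n_scales = 3,
                            contrast_thresh = 0.01) {
  img <- contrast_stretch(img)
  if (min(dim(img)) < 64) stop("detect_features: image must be >= 64 px per side")
  n_octaves <- max(1, floor(log2(min(dim(img)) / 32)))
  feats <- list()
  cur <- img
  for (o in 0:(n_octaves - 1)) {
    oct_res <- detect_keypoints_octave(cur, o, n_scales, sigma0 = 1.6,
                                       contrast_thresh = contrast_thresh,
                                       edge_ratio = 10)
    kps <- oct_res$keypoints
    if (length(kps) > 0) {
      # order by response and cap per octave to bound descriptor work
      resp <- vapply(kps, function(k) k$response, numeric(1))
      kps <- kps[order(-resp)][seq_len(min(length(kps), max_features))]
      grad_cache <- vector("list", length(oct_res$gauss))
      for (kp in kps) {
        if (is.null(grad_cache[[kp$layer]])) {
          grad_cache[[kp$layer]] <- img_gradients(oct_res$gauss[[kp$layer]])
        }
        gr <- grad_cache[[kp$layer]]
        for (theta in keypoint_orientations(gr$gx, gr$gy, kp)) {
          d <- keypoint_descriptor(gr$gx, gr$gy, kp, theta)
          if (is.null(d)) next
          feats[[length(feats) + 1]] <- list(
            x = kp$x * 2^o, y = kp$y * 2^o,
            sigma = kp$sigma * 2^o, response = kp$response, desc = d
          )
        }
      }
    }
    cur <- half_sample(gauss_filter(cur, 5, 0.8))
    if (min(dim(cur)) < 32) break
  }
  if (length(feats) == 0) {
    return(list(xy = matrix(numeric(0), ncol = 2), desc = NULL,
                sigma = numeric(0), response = numeric(0)))
  }
  resp <- vapply(feats, function(f) f$response, numeric(1))
  ord <- order(-resp)[seq_len(min(length(feats), max_features))]
  feats <- feats[ord]
  list(
    xy = do.call(rbind, lapply(feats, function(f) c(f$x, f$y))),
    desc = do.call(rbind, lapply(feats, function(f) f$desc)),
    sigma = vapply(feats, function(f) f$sigma, numeric(1)),
    response = vapply(feats, function(f) f$response, numeric(1))
  )
}

#' Match features between two images
#'
#' Nearest-neighbour descriptor matching with the Lowe ratio test and a
#' mutual-best cross check. Deterministic given the inputs.
#'
#' @param img_a,img_b numeric matrices (>= 64 px per side)
#' @param ratio Lowe ratio threshold in (0, 1]
#' @param max_features per-image keypoint cap
#' @return a `feature_match_set`: list with `points_a`, `points_b`
#'   (n x 2, 0-based pixel coordinates) and `scores` in \[0, 1\]
#' @export
match_features <- function(img_a, img_b, ratio = 0.8, max_features = 500) {
  fa <- detect_features(img_a, max_features = max_features)
  fb <- detect_features(img_b, max_features = max_features)
  fail <- function() {
    stop("match_features: insufficient correspondence between images ",
         "(fewer than 3 surviving matches)")
  }
  if (nrow(fa$xy) < 3 || nrow(fb$xy) < 3) fail()
  # descriptors are unit norm: dist^2 = 2 - 2 * dot
  dots <- fa$desc %*% t(fb$desc)
  d2 <- pmax(2 - 2 * dots, 0)
  pick <- function(d2m) {
    t(apply(d2m, 1, function(row) {
      o <- order(row)
      c(best = o[1], d1 = row[o[1]], d2 = if (length(o) > 1) row[o[2]] else Inf)
    }))
  }
  ab <- pick(d2)
  ba_best <- apply(d2, 2, which.min)
  keep <- which(sqrt(ab[, "d1"]) < ratio * sqrt(ab[, "d2"]) &
                  ba_best[ab[, "best"]] == seq_len(nrow(d2)))
  if (length(keep) < 3) fail()
  scores <- 1 - sqrt(ab[keep, "d1"]) / pmax(sqrt(ab[keep, "d2"]), 1e-12)
  structure(
    list(
      points_a = fa$xy[keep, , drop = FALSE],
      points_b = fb$xy[ab[keep, "best"], , drop = FALSE],
      scores = pmin(pmax(scores, 0), 1)
    ),
    class = "feature_match_set"
  )
}
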