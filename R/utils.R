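# Low-level image helpers shared across modules.
#
# Conventions (asserted at module boundaries):
#   * 2D images are numeric matrices indexed [y + 1, x + 1]; pixel
#     coordinates are 0-based (x, y) with x rightward, y downward.
#   * 3D stacks are arrays indexed [z + 1, y + 1, x + 1].

#' Evaluate with a private RNG stream
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never perturb user-level randomness.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' 1D Gaussian kernel
#' @param size odd or even kernel width in pixels
#' @param sigma standard deviation in pixels
#' @return numeric vector summing to 1
#' @keywords internal
gaussian_kernel1d <- function(size, sigma) {
  stopifnot(size >= 1, sigma > 0)
  # centre an even-sized kernel on the half-pixel, like the usual box layout
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve rows of `img` with kernel `k`, replicate padding.
conv1d_rows <- function(img, k) {
  n <- length(k)
  half_l <- (n - 1) %/% 2
  half_r <- n - 1 - half_l
  nc <- ncol(img)
  pad <- cbind(
    img[, rep(1, half_l), drop = FALSE],
    img,
    img[, rep(nc, half_r), drop = FALSE]
  )
  out <- matrix(0, nrow(img), nc)
  for (i in seq_len(n)) {
    out <- out + k[i] * pad[, i:(i + nc - 1), drop = FALSE]
  }
  out
}

#' Separable Gaussian filter with replicate boundary
#'
#' The GF(size, sigma) smoothing operator used by the sensitivity-map and
#' inter-volume estimators.
#' @param img numeric matrix
#' @param size kernel width in pixels
#' @param sigma standard deviation in pixels
#' @return filtered matrix, same shape
#' @export
gauss_filter <- function(img, size, sigma) {
  stopifnot(is.matrix(img))
  k <- gaussian_kernel1d(size, sigma)
  t(conv1d_rows(t(conv1d_rows(img, k)), k))
}

#' Bilinear sampling of a 2D image at fractional pixel coordinates
#'
#' @param img numeric matrix indexed `[y + 1, x + 1]`
#' @param x,y numeric vectors of 0-based pixel coordinates
#' @param fill value used outside the image domain
#' @return list with `values` and logical `valid` (inside the domain)
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  valid <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  # clamp corner indices so arithmetic stays in-bounds; fill applied after
  xc0 <- pmin(pmax(x0, 0), w - 1)
  yc0 <- pmin(pmax(y0, 0), h - 1)
  xc1 <- pmin(xc0 + 1, w - 1)
  yc1 <- pmin(yc0 + 1, h - 1)
  i00 <- yc0 + 1 + h * xc0
  i10 <- yc1 + 1 + h * xc0
  i01 <- yc0 + 1 + h * xc1
  i11 <- yc1 + 1 + h * xc1
  v <- (1 - fx) * (1 - fy) * img[i00] + (1 - fx) * fy * img[i10] +
    fx * (1 - fy) * img[i01] + fx * fy * img[i11]
  v[!valid] <- fill
  list(values = v, valid = valid)
}

#' Bilinear resize of a 2D image
#' @param img numeric matrix
#' @param out_shape integer (rows, cols) of the output
#' @return resized matrix
#' @export
resize_image <- function(img, out_shape) {
  oh <- out_shape[1]
  ow <- out_shape[2]
  stopifnot(oh >= 1, ow >= 1)
  sy <- nrow(img) / oh
  sx <- ncol(img) / ow
  # align pixel centres of the two grids
  ys <- (seq_len(oh) - 0.5) * sy - 0.5
  xs <- (seq_len(ow) - 0.5) * sx - 0.5
  ys <- pmin(pmax(ys, 0), nrow(img) - 1)
  xs <- pmin(pmax(xs, 0), ncol(img) - 1)
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(img, g$x, g$y)$values, oh, ow)
}

#' Percentile contrast stretch to \[0, 1\]
#'
#' ET reconstructions and directly captured TEM images differ strongly in
#' contrast; all feature extraction runs on stretched images.
#' @param img numeric matrix
#' @param probs lower/upper percentiles
#' @return matrix with values in \[0, 1\]
#' @export
contrast_stretch <- function(img, probs = c(0.01, 0.99)) {
  q <- quantile(img, probs, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Translation estimate by phase correlation
#'
#' Independent of the feature-matching path; used as a cross-check and to
#' initialise optical flow. Returns the shift (dx, dy) such that
#' `mov(x + dx, y + dy) ~ ref(x, y)`.
#' @param ref,mov numeric matrices of identical shape
#' @param subpixel refine the integer peak with a parabolic fit
#' @return numeric `c(dx, dy)`
#' @export
phase_correlation <- function(ref, mov, subpixel = TRUE) {
  stopifnot(all(dim(ref) == dim(mov)))
  fa <- stats::fft(ref - mean(ref))
  fb <- stats::fft(mov - mean(mov))
  cp <- fa * Conj(fb)
  denom <- Mod(cp)
  denom[denom < 1e-12] <- 1e-12
  r <- Re(stats::fft(cp / denom, inverse = TRUE))
  pk <- which.max(r)
  py <- (pk - 1) %% nrow(r)
  px <- (pk - 1) %/% nrow(r)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  dy <- wrap(py, nrow(r))
  dx <- wrap(px, ncol(r))
  if (subpixel) {
    at <- function(y, x) r[(y %% nrow(r)) + 1, (x %% ncol(r)) + 1]
    fit1 <- function(m, c, p) {
      den <- m - 2 * c + p
      if (abs(den) < 1e-12) 0 else 0.5 * (m - p) / den
    }
    dx <- dx + fit1(at(py, px - 1), at(py, px), at(py, px + 1))
    dy <- dy + fit1(at(py - 1, px), at(py, px), at(py + 1, px))
  }
  c(dx = -dx, dy = -dy)
}

# Shift array contents by integer offsets, zero fill (test/oracle helper).
shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  h <- nrow(img)
  w <- ncol(img)
  src_x <- seq_len(w) - dx
  src_y <- seq_len(h) - dy
  ok_x <- src_x >= 1 & src_x <= w
  ok_y <- src_y >= 1 & src_y <= h
  out[which(ok_y), which(ok_x)] <- img[src_y[ok_y], src_x[ok_x]]
  out
}
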