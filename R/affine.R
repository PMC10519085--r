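# 2D affine maps in homogeneous form, used both for stage-coordinate ROI
# propagation (micrometres) and image alignment (pixels).

#' Construct a 2D affine model
#'
#' The model acts on column vectors `(x, y, 1)`; the last matrix row is
#' always `(0, 0, 1)`.
#'
#' @param matrix 3x3 numeric matrix
#' @param variant one of `"translation"`, `"similarity"`, `"affine"`
#' @return an `affine2d` object
#' @export
affine_model <- function(matrix, variant = c("affine", "translation", "similarity")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-12) {
    stop("affine_model: last row must be (0, 0, 1)")
  }
  if (variant == "translation" &&
      max(abs(matrix[1:2, 1:2] - diag(2))) > 1e-9) {
    stop("affine_model: translation variant requires identity linear part")
  }
  if (variant == "similarity") {
    a <- matrix[1, 1]; b <- matrix[1, 2]; c_ <- matrix[2, 1]; d <- matrix[2, 2]
    if (abs(a - d) > 1e-6 * max(1, abs(a)) || abs(b + c_) > 1e-6 * max(1, abs(b))) {
      stop("affine_model: similarity variant requires s*R(theta) linear part")
    }
  }
  structure(list(matrix = matrix, variant = variant), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d:", x$variant, ">\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Translation model
#' @param tx,ty translation components
#' @return `affine2d`
#' @export
affine_translation <- function(tx, ty) {
  m <- diag(3)
  m[1, 3] <- tx
  m[2, 3] <- ty
  affine_model(m, "translation")
}

#' Similarity model (uniform scale s, rotation theta, translation)
#' @param s positive scale
#' @param theta rotation angle in radians (counter-clockwise in (x, y))
#' @param tx,ty translation components
#' @return `affine2d`
#' @export
affine_similarity <- function(s, theta, tx = 0, ty = 0) {
  stopifnot(s > 0)
  m <- rbind(
    c(s * cos(theta), -s * sin(theta), tx),
    c(s * sin(theta), s * cos(theta), ty),
    c(0, 0, 1)
  )
  affine_model(m, "similarity")
}

#' Full affine model from the six free coefficients
#' @param a,b,c,d,e,f row-major coefficients of the upper 2x3 block
#' @return `affine2d`
#' @export
affine_full <- function(a, b, c, d, e, f) {
  affine_model(rbind(c(a, b, c), c(d, e, f), c(0, 0, 1)), "affine")
}

#' Apply an affine model to points
#' @param model `affine2d`
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) coordinates
#' @return n x 2 matrix of mapped coordinates
#' @export
apply_affine <- function(model, xy) {
  stopifnot(inherits(model, "affine2d"))
  xy <- rbind_points(xy)
  h <- cbind(xy, 1) %*% t(model$matrix)
  h[, 1:2, drop = FALSE]
}

rbind_points <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2, byrow = TRUE)
  stopifnot(ncol(xy) == 2)
  xy
}

#' Invert an affine model
#' @param model `affine2d`
#' @return `affine2d` with the inverse matrix
#' @export
affine_inverse <- function(model) {
  d <- det(model$matrix[1:2, 1:2])
  if (abs(d) < 1e-14) stop("affine_inverse: singular model")
  affine_model(solve(model$matrix), variant = model$variant)
}

#' Chain affine models in application order
#'
#' `chain_affine(list(A, B))` returns the model applying `A` first, then
#' `B` (matrix `B %*% A`).
#' @param models non-empty list of `affine2d`
#' @return combined `affine2d` (variant `"affine"` unless all inputs share
#'   a more restrictive variant)
#' @export
chain_affine <- function(models) {
  stopifnot(length(models) >= 1)
  m <- diag(3)
  variants <- character(0)
  for (mod in models) {
    stopifnot(inherits(mod, "affine2d"))
    m <- mod$matrix %*% m
    variants <- c(variants, mod$variant)
  }
  v <- if (all(variants == "translation")) {
    "translation"
  } else if (all(variants %in% c("translation", "similarity"))) {
    "similarity"
  } else {
    "affine"
  }
  affine_model(m, v)
}

# --- least-squares fits ------------------------------------------------

#' Fit a translation between paired points
#' @param src,dst n x 2 matrices of corresponding (x, y) points
#' @return `affine2d` translation
#' @export
fit_translation <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 1)
  t_ <- colMeans(dst - src)
  affine_translation(t_[1], t_[2])
}

#' Fit a similarity (scale + rotation + translation), closed form
#'
#' Least squares over all pairs via the usual centred cross-covariance
#' solution; exact when the pair count equals the degrees of freedom.
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 2
#' @return `affine2d` similarity
#' @export
fit_similarity <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == nrow(dst))
  if (nrow(src) < 2) stop("fit_similarity: need at least 2 pairs")
  ps <- colMeans(src); pd <- colMeans(dst)
  sc <- sweep(src, 2, ps); dc <- sweep(dst, 2, pd)
  denom <- sum(sc^2)
  if (denom < 1e-20) stop("fit_similarity: degenerate (coincident) source points")
  a <- sum(sc[, 1] * dc[, 1] + sc[, 2] * dc[, 2])
  b <- sum(sc[, 1] * dc[, 2] - sc[, 2] * dc[, 1])
  s <- sqrt(a^2 + b^2) / denom
  if (s <= 0) stop("fit_similarity: zero scale")
  theta <- atan2(b, a)
  rot <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  t_ <- pd - s * as.vector(rot %*% ps)
  affine_similarity(s, theta, t_[1], t_[2])
}

#' Fit a full affine map, least squares
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 3
#'   non-collinear
#' @return `affine2d`
#' @export
fit_affine <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == nrow(dst))
  if (nrow(src) < 3) stop("fit_affine: need at least 3 pairs")
  x <- cbind(src, 1)
  qx <- qr(x)
  if (qx$rank < 3) stop("fit_affine: degenerate (collinear) source points")
  coef <- qr.coef(qx, dst)
  affine_full(coef[1, 1], coef[2, 1], coef[3, 1],
              coef[1, 2], coef[2, 2], coef[3, 2])
}
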