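# Thin-plate-spline deformation fields: exact scattered-displacement
# interpolation at lambda = 0 (with an exact affine null space), smoothing
# spline for lambda > 0. Fields are dense backward-warp displacement grids.

#' Construct a deformation field
#' @param dx,dy numeric matrices (pixels) of identical shape; the warp
#'   samples the source image at `(x + dx, y + dy)`
#' @return a `deformation_field`
#' @export
deformation_field <- function(dx, dy) {
  stopifnot(is.matrix(dx), all(dim(dx) == dim(dy)),
            all(is.finite(dx)), all(is.finite(dy)))
  structure(list(dx = dx, dy = dy), class = "deformation_field")
}

tps_kernel <- function(r2) {
  # U(r) = r^2 log r = 0.5 * r^2 log r^2; U(0) = 0
  out <- 0.5 * r2 * log(r2)
  out[r2 <= 0] <- 0
  out
}

#' Fit and evaluate a thin-plate-spline deformation field
#'
#' Solves the standard TPS system for the x- and y-displacements of the
#' control points and evaluates the field densely. With `lambda_reg = 0`
#' the field interpolates the control displacements exactly and reproduces
#' any affine map with zero bending energy; `lambda_reg > 0` trades
#' fidelity for smoothness.
#'
#' @param src_pts n x 2 control points (0-based pixel coordinates in the
#'   target frame)
#' @param dst_pts n x 2 matched points in the source frame
#' @param shape `(y, x)` output field shape
#' @param lambda_reg regularisation weight (>= 0)
#' @return a `deformation_field` with the displacement `dst - src`
#'   interpolated over the grid
#' @export
tps_field <- function(src_pts, dst_pts, shape, lambda_reg = 0) {
  src_pts <- rbind_points(src_pts)
  dst_pts <- rbind_points(dst_pts)
  n <- nrow(src_pts)
  stopifnot(n == nrow(dst_pts), lambda_reg >= 0)
  if (n < 3) stop("tps_field: need at least 3 control points")
  if (qr(cbind(src_pts, 1))$rank < 3) {
    stop("tps_field: control points are collinear")
  }
  d2 <- as.matrix(dist(src_pts))^2
  K <- tps_kernel(d2) + diag(lambda_reg, n)
  P <- cbind(1, src_pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  disp <- dst_pts - src_pts
  rhs <- rbind(disp, matrix(0, 3, 2))
  coef <- tryCatch(solve(A, rhs), error = function(e) {
    stop("tps_field: singular TPS system (degenerate control points)")
  })
  w <- coef[seq_len(n), , drop = FALSE]
  a <- coef[n + 1:3, , drop = FALSE]
  oh <- shape[1]; ow <- shape[2]
  gx <- rep(seq_len(ow) - 1, each = oh)
  gy <- rep(seq_len(oh) - 1, times = ow)
  # r^2 between every grid point and every control point
  r2 <- outer(gx, src_pts[, 1], "-")^2 + outer(gy, src_pts[, 2], "-")^2
  U <- tps_kernel(r2)
  fx <- a[1, 1] + a[2, 1] * gx + a[3, 1] * gy + U %*% w[, 1]
  fy <- a[1, 2] + a[2, 2] * gx + a[3, 2] * gy + U %*% w[, 2]
  deformation_field(matrix(fx, oh, ow), matrix(fy, oh, ow))
}

#' Warp a volume with a dense 2D deformation field
#'
#' The same backward 2D warp is applied to every z-slice: output pixel
#' `(x, y)` samples the input at `(x + dx, y + dy)` bilinearly, zero fill
#' outside.
#'
#' @param vol an `image_stack`
#' @param field a `deformation_field` matching the slice shape
#' @return warped `image_stack` with a `validity` attribute
#' @export
apply_field <- function(vol, field) {
  stopifnot(inherits(vol, "image_stack"), inherits(field, "deformation_field"))
  d <- dim(vol$data)
  if (!all(dim(field$dx) == d[2:3])) {
    stop("apply_field: field shape ", paste(dim(field$dx), collapse = "x"),
         " does not match slice shape ", paste(d[2:3], collapse = "x"))
  }
  gx <- rep(seq_len(d[3]) - 1, each = d[2])
  gy <- rep(seq_len(d[2]) - 1, times = d[3])
  sx <- gx + as.vector(field$dx)
  sy <- gy + as.vector(field$dy)
  out <- array(0, dim = d)
  valid <- NULL
  for (z in seq_len(d[1])) {
    sm <- bilinear_sample(matrix(vol$data[z, , ], d[2], d[3]), sx, sy)
    out[z, , ] <- matrix(sm$values, d[2], d[3])
    if (is.null(valid)) valid <- matrix(sm$valid, d[2], d[3])
  }
  prev <- attr(vol, "validity") # compose through successive warps
  if (!is.null(prev)) {
    pv <- bilinear_sample(prev * 1, sx, sy)$values
    valid <- valid & matrix(pv > 0.999, d[2], d[3])
  }
  res <- image_stack(out, vol$voxel_size_nm, vol$origin_label)
  attr(res, "validity") <- valid
  res
}

#' Elastic fine alignment of one volume onto another
#'
#' Runs block matching between the two z-mean images, deactivates
#' texture-less blocks, resolves candidate ambiguity with [bp_refine()],
#' fits the TPS field through the surviving matches and warps `mov_vol`
#' into `ref_vol`'s frame.
#'
#' @param ref_vol,mov_vol aligned-scale `image_stack`s of identical slice
#'   shape
#' @param block_px,stride_px,search_px,k_candidates block-matching controls
#' @param C truncation threshold in squared pixels (default 8 px squared)
#' @param lambda_reg TPS regularisation
#' @param method solver selection passed to [bp_refine()]
#' @return list: `warped` (`image_stack`), `field` (`deformation_field`),
#'   `graph`, `refined` (the [bp_refine()] result)
#' @export
fine_align_pair <- function(ref_vol, mov_vol, block_px = 64, stride_px = 64,
                            search_px = 16, k_candidates = 3, C = 64,
                            lambda_reg = 0, method = "auto") {
  ref <- contrast_stretch(mean_image(ref_vol))
  mov <- contrast_stretch(mean_image(mov_vol))
  # small fields cannot host the default grid; shrink to keep >= 3x3 nodes
  max_block <- 2^floor(log2(min(dim(ref)) / 3))
  if (block_px > max_block) {
    stride_px <- max(16, round(stride_px * max_block / block_px))
    block_px <- max(16, max_block)
  }
  graph <- block_match(ref, mov, block_px = block_px, stride_px = stride_px,
                       search_px = search_px, k_candidates = k_candidates)
  graph <- prune_match_graph(graph)
  if (sum(graph$nodes$active) < 3) {
    stop("fine_align_pair: fewer than 3 textured blocks; cannot fit a field")
  }
  refined <- bp_refine(graph, C = C, method = method)
  act <- graph$nodes$active
  src <- cbind(graph$nodes$cx[act], graph$nodes$cy[act])
  dst <- cbind(refined$selected$px[act], refined$selected$py[act])
  field <- tps_field(src, dst, dim(ref), lambda_reg = lambda_reg)
  list(
    warped = apply_field(mov_vol, field),
    field = field,
    graph = graph,
    refined = refined
  )
}
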