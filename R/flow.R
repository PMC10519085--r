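# Dense optical flow by pyramidal, iteratively refined Lucas-Kanade.
# Convention: `lk_flow(ref, mov)` returns the backward field F with
# `mov(x + Fx, y + Fy) ~ ref(x, y)`, i.e. `apply (warp) F to mov` aligns it
# onto `ref`. Identical inputs yield an exactly zero field.

warp_image <- function(img, field) {
  h <- nrow(img); w <- ncol(img)
  gx <- rep(seq_len(w) - 1, each = h)
  gy <- rep(seq_len(h) - 1, times = w)
  sm <- bilinear_sample(img, gx + as.vector(field$dx), gy + as.vector(field$dy))
  v <- matrix(sm$values, h, w)
  # replicate outside content instead of zero to avoid spurious gradients
  inv <- !matrix(sm$valid, h, w)
  if (any(inv)) {
    cx <- pmin(pmax(gx + as.vector(field$dx), 0), w - 1)
    cy <- pmin(pmax(gy + as.vector(field$dy), 0), h - 1)
    vc <- matrix(bilinear_sample(img, cx, cy)$values, h, w)
    v[inv] <- vc[inv]
  }
  v
}

lk_refine <- function(ref, mov, field, n_iter, win_size, win_sigma) {
  for (it in seq_len(n_iter)) {
    movw <- warp_image(mov, field)
    gr <- img_gradients(movw)
    it_img <- movw - ref
    ixx <- gauss_filter(gr$gx^2, win_size, win_sigma)
    iyy <- gauss_filter(gr$gy^2, win_size, win_sigma)
    ixy <- gauss_filter(gr$gx * gr$gy, win_size, win_sigma)
    ixt <- gauss_filter(gr$gx * it_img, win_size, win_sigma)
    iyt <- gauss_filter(gr$gy * it_img, win_size, win_sigma)
    det <- ixx * iyy - ixy^2 + 1e-9
    du <- -(iyy * ixt - ixy * iyt) / det
    dv <- -(ixx * iyt - ixy * ixt) / det
    lim <- 2
    du <- pmin(pmax(du, -lim), lim)
    dv <- pmin(pmax(dv, -lim), lim)
    field <- deformation_field(field$dx + du, field$dy + dv)
  }
  field
}

#' Dense optical flow (pyramidal Lucas-Kanade)
#'
#' @param ref,mov numeric matrices of identical shape
#' @param n_levels pyramid depth (`NULL`: down to ~32 px)
#' @param n_iter refinement iterations per level
#' @param win_size,win_sigma Gaussian aggregation window
#' @return a `deformation_field` F with `warp(mov, F) ~ ref`
#' @export
lk_flow <- function(ref, mov, n_levels = NULL, n_iter = 4, win_size = 21,
                    win_sigma = 4) {
  stopifnot(all(dim(ref) == dim(mov)))
  if (is.null(n_levels)) {
    n_levels <- max(1, floor(log2(min(dim(ref)) / 32)) + 1)
  }
  pyr_ref <- list(ref)
  pyr_mov <- list(mov)
  for (l in seq_len(n_levels - 1)) {
    pyr_ref[[l + 1]] <- half_sample(gauss_filter(pyr_ref[[l]], 5, 1))
    pyr_mov[[l + 1]] <- half_sample(gauss_filter(pyr_mov[[l]], 5, 1))
  }
  field <- deformation_field(
    matrix(0, nrow(pyr_ref[[n_levels]]), ncol(pyr_ref[[n_levels]])),
    matrix(0, nrow(pyr_ref[[n_levels]]), ncol(pyr_ref[[n_levels]]))
  )
  for (l in n_levels:1) {
    if (l < n_levels) {
      sh <- dim(pyr_ref[[l]])
      field <- deformation_field(
        2 * resize_image(field$dx, sh),
        2 * resize_image(field$dy, sh)
      )
    }
    field <- lk_refine(pyr_ref[[l]], pyr_mov[[l]], field,
                       n_iter = n_iter, win_size = win_size,
                       win_sigma = win_sigma)
  }
  field
}
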