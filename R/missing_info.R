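# Missing-information estimation and generation.
#
# Between consecutive ET volumes, slices are lost to cutting damage, the
# missing wedge and beam-induced shrinkage. The lost counts are estimated
# from two complementary measurements and reconciled by a small quadratic
# program, then the missing slices are synthesised by frame interpolation:
#
#   intra (per volume):  L_top + L_bot = (L_cut - L_ET) / R_ET
#   inter (per pair)  :  L_bot_i + L_top_{i+1} from the gray-value change
#                        between the volumes' mean images, converted to a
#                        slice count by a per-pixel sensitivity map
#   distribution      :  minimise sum (L_top_i - L_bot_i)^2 +
#                        sum (L_top_{i+1} - L_bot_i)^2 under the equality
#                        constraints above.

#' Intra-volume lost-slice count from thickness bookkeeping
#'
#' `(cut thickness - ET thickness) / voxel size`, the total number of
#' slices lost at the top and bottom of one reconstructed volume.
#' A volume thicker than its cut returns the negative value with a
#' `negative` attribute (callers clip to zero for the solver).
#'
#' @param meta one row of a `section_meta` data frame (or a list with
#'   `cut_thickness_nm`, `et_slice_count`, `voxel_size_nm`)
#' @return numeric slice count (possibly negative, flagged)
#' @export
intra_loss <- function(meta) {
  if (is.data.frame(meta)) meta <- as.list(meta[1, ])
  if (meta$voxel_size_nm <= 0) stop("intra_loss: non-positive voxel size")
  v <- (meta$cut_thickness_nm - meta$et_slice_count * meta$voxel_size_nm) /
    meta$voxel_size_nm
  if (v < 0) {
    warning("intra_loss: ET volume thicker than its cut (", round(v, 2),
            " slices); clip to 0 before solving")
    attr(v, "negative") <- TRUE
  }
  v
}

#' Per-pixel z-sensitivity map of a volume
#'
#' The number of slices needed for one gray-value change along z at each
#' pixel: the reciprocal of the mean absolute slice-to-slice difference,
#' guarded on flat regions, capped, and smoothed with a Gaussian filter
#' (kernel 25, sigma 13) so the pixel-change correlation is smooth.
#'
#' @param vol an `image_stack` with z >= 2
#' @param size,sigma smoothing kernel controls
#' @param eps flat-region guard (default 1/255 of the dynamic range)
#' @param s_max cap (default 10x the raw map median)
#' @param z_trim fraction of slices dropped at each z end before the mean
#'   (default 0). The missing wedge obscures the reconstructed volume's
#'   extremes, so pipeline callers trim them to keep the gradient estimate
#'   representative of the interior.
#' @param mask optional logical matrix of measurable pixels (defaults to
#'   the volume's warp `validity` attribute when present). Fill regions
#'   have zero z-gradient and would saturate at the cap, then bleed into
#'   their surroundings through the smoothing; they are replaced by the
#'   in-mask median instead.
#' @return a `sensitivity_map`: list with `values` (smoothed, clipped) and
#'   `raw`
#' @export
sensitivity_map <- function(vol, size = 25, sigma = 13, eps = NULL,
                            s_max = NULL, z_trim = 0, mask = NULL) {
  stopifnot(inherits(vol, "image_stack"), z_trim >= 0, z_trim < 0.5)
  d <- dim(vol$data)
  if (d[1] < 2) stop("sensitivity_map: need at least 2 slices")
  keep <- seq_len(d[1])
  n_trim <- floor(z_trim * d[1])
  if (d[1] - 2 * n_trim >= 2) keep <- (1 + n_trim):(d[1] - n_trim)
  zz <- vol$data[keep, , , drop = FALSE]
  nk <- length(keep)
  dz <- abs(zz[2:nk, , , drop = FALSE] - zz[1:(nk - 1), , , drop = FALSE])
  mdz <- matrix(colMeans(matrix(dz, nk - 1, d[2] * d[3])), d[2], d[3])
  if (is.null(eps)) {
    # ~0.01 gray level on an 8-bit scale: only a blow-up guard, the s_max
    # cap handles genuinely flat regions
    rng <- diff(range(vol$data))
    eps <- max(rng, 1e-12) / 25500
  }
  raw <- 1 / pmax(mdz, eps)
  if (is.null(mask)) mask <- attr(vol, "validity")
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!any(mask)) stop("sensitivity_map: empty mask")
  if (is.null(s_max)) s_max <- 10 * median(raw[mask])
  clipped <- pmin(raw, s_max)
  clipped[!mask] <- median(clipped[mask])
  structure(
    list(values = gauss_filter(clipped, size, sigma), raw = raw,
         eps = eps, s_max = s_max),
    class = "sensitivity_map"
  )
}

#' Inter-volume lost-slice count from mean-image change
#'
#' Rescales both volumes' z-mean images (and sensitivity maps) to about
#' 256 x 256, forms the outlier-robust gray-change map
#' `D = GF(10, 3)(|mean_j - mean_i|)`, multiplies it pixelwise by the
#' average of the two smoothed sensitivity maps, and takes the spatial
#' maximum — the gray distance between the two volumes expressed in
#' slices. Under the uniform-change assumption that distance spans the two
#' volume centres, so the half thickness of each volume is subtracted to
#' leave the gap alone (`center_correction = FALSE` reproduces the
#' uncorrected reading).
#'
#' @param vol_i,vol_j spatially aligned `image_stack`s
#' @param smap_i,smap_j optional precomputed [sensitivity_map()]s
#' @param target_px working resolution (default 256)
#' @param center_correction subtract `(z_i + z_j) / 2` slices (default)
#' @param valid optional logical matrix of jointly valid pixels; defaults
#'   to the intersection of the volumes' warp `validity` attributes.
#'   Fill regions introduced by alignment warps would otherwise dominate
#'   the difference map, so aggregation runs over an eroded valid region
#'   only.
#' @param agg spatial aggregator over the product map. Under the
#'   uniform-change assumption the product is spatially constant, so its
#'   median and maximum coincide in theory; the median (default) is robust
#'   to the localized residual-misregistration spikes that survive
#'   alignment, while `"max"` is the literal reading of the formula and
#'   `"quantile"` (with `q`) sits in between.
#' @param q quantile used when `agg = "quantile"`
#' @return estimated `L_bot_i + L_top_{i+1}` in slices (>= 0)
#' @export
inter_loss <- function(vol_i, vol_j, smap_i = NULL, smap_j = NULL,
                       target_px = 256, center_correction = TRUE,
                       valid = NULL, agg = c("median", "max", "quantile"),
                       q = 0.9) {
  agg <- match.arg(agg)
  stopifnot(inherits(vol_i, "image_stack"), inherits(vol_j, "image_stack"))
  di <- dim(vol_i$data); dj <- dim(vol_j$data)
  if (!all(di[2:3] == dj[2:3])) {
    stop("inter_loss: volumes are not on a common grid (align them first)")
  }
  if (is.null(smap_i)) smap_i <- sensitivity_map(vol_i, z_trim = 0.2)
  if (is.null(smap_j)) smap_j <- sensitivity_map(vol_j, z_trim = 0.2)
  if (is.null(valid)) {
    vi <- attr(vol_i, "validity")
    vj <- attr(vol_j, "validity")
    valid <- matrix(TRUE, di[2], di[3])
    if (!is.null(vi)) valid <- valid & vi
    if (!is.null(vj)) valid <- valid & vj
  }
  mi <- mean_image(vol_i)
  mj <- mean_image(vol_j)
  f <- target_px / max(di[2:3])
  out_shape <- pmax(round(di[2:3] * f), 8)
  mi <- resize_image(mi, out_shape)
  mj <- resize_image(mj, out_shape)
  si <- resize_image(smap_i$values, out_shape)
  sj <- resize_image(smap_j$values, out_shape)
  # erode the valid region past the smoothing supports
  vm <- resize_image(valid * 1, out_shape)
  vm <- gauss_filter(vm, 31, 8) > 0.999
  if (!any(vm)) stop("inter_loss: no jointly valid pixels")
  d_map <- gauss_filter(abs(mj - mi), 10, 3)
  prod_map <- d_map * (si + sj) / 2
  est <- switch(agg,
    max = max(prod_map[vm]),
    median = median(prod_map[vm]),
    quantile = quantile(prod_map[vm], q, names = FALSE)
  )
  if (center_correction) est <- est - (di[1] + dj[1]) / 2
  max(est, 0)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Distribute lost slices over volume tops and bottoms
#'
#' Solves the equality-constrained quadratic program over
#' `(L_top_i, L_bot_i)`: the constraint chain leaves one degree of
#' freedom, resolved by minimising the symmetry objective
#' `sum (L_top_i - L_bot_i)^2 + sum (L_top_{i+1} - L_bot_i)^2` in closed
#' form. Negative continuous values are then projected to zero and counts
#' rounded (half away from zero) with a repair pass keeping each rounded
#' intra sum within 1 of its constraint.
#'
#' @param c_intra length-n per-volume totals (Eq.-7 style constants)
#' @param c_inter length-(n-1) per-pair totals (mean-image estimates)
#' @return a `gap_estimate`: list with `top`, `bot` (continuous),
#'   `rounded_top`, `rounded_bot`, `c_intra`, `c_inter`, `projected`
#' @export
solve_distribution <- function(c_intra, c_inter = numeric(0)) {
  n <- length(c_intra)
  stopifnot(n >= 1, length(c_inter) == n - 1,
            all(is.finite(c_intra)), all(is.finite(c_inter)))
  # every variable is affine in theta = L_top_1: accumulate (alpha, beta)
  alpha_t <- numeric(n); beta_t <- numeric(n)
  alpha_b <- numeric(n); beta_b <- numeric(n)
  alpha_t[1] <- 0; beta_t[1] <- 1
  for (i in seq_len(n)) {
    alpha_b[i] <- c_intra[i] - alpha_t[i]
    beta_b[i] <- -beta_t[i]
    if (i < n) {
      alpha_t[i + 1] <- c_inter[i] - alpha_b[i]
      beta_t[i + 1] <- -beta_b[i]
    }
  }
  # objective terms (a_k + b_k * theta)^2
  a_terms <- c(alpha_t - alpha_b, alpha_t[-1] - alpha_b[-n])
  b_terms <- c(beta_t - beta_b, beta_t[-1] - beta_b[-n])
  denom <- sum(b_terms^2)
  theta <- if (denom > 0) -sum(a_terms * b_terms) / denom else c_intra[1] / 2
  top <- alpha_t + beta_t * theta
  bot <- alpha_b + beta_b * theta
  projected <- any(top < 0) || any(bot < 0)
  top_p <- pmax(top, 0)
  bot_p <- pmax(bot, 0)
  rt <- as.integer(round_half_away(top_p))
  rb <- as.integer(round_half_away(bot_p))
  for (i in seq_len(n)) { # keep each rounded intra sum within 1
    target <- c_intra[i]
    while (rt[i] + rb[i] > target + 1) {
      # shrink whichever positive counter sits furthest above its
      # continuous value (projection can inflate the sum beyond rounding)
      if (rt[i] == 0L && rb[i] == 0L) break
      take_top <- rt[i] > 0L &&
        (rb[i] == 0L || rt[i] - top_p[i] >= rb[i] - bot_p[i])
      if (take_top) rt[i] <- rt[i] - 1L else rb[i] <- rb[i] - 1L
    }
    while (rt[i] + rb[i] < target - 1) {
      if (top_p[i] - rt[i] >= bot_p[i] - rb[i]) rt[i] <- rt[i] + 1L
      else rb[i] <- rb[i] + 1L
    }
  }
  structure(
    list(top = top, bot = bot, rounded_top = rt, rounded_bot = rb,
         c_intra = c_intra, c_inter = c_inter, projected = projected),
    class = "gap_estimate"
  )
}

#' Estimate all gaps of a section series (thickness + image evidence)
#'
#' Runs [intra_loss()] on each section's metadata, [inter_loss()] on each
#' aligned consecutive pair and reconciles both with
#' [solve_distribution()].
#'
#' @param volumes list of aligned `image_stack`s
#' @param meta `section_meta` data frame (one row per volume, in order)
#' @param ... passed to [inter_loss()]
#' @return a `gap_estimate`; the per-pair generated counts are
#'   `rounded_bot[i] + rounded_top[i + 1]`
#' @export
estimate_gaps <- function(volumes, meta, ...) {
  n <- length(volumes)
  stopifnot(n >= 1, nrow(meta) == n)
  c_intra <- vapply(seq_len(n), function(i) {
    v <- suppressWarnings(intra_loss(meta[i, ]))
    max(as.numeric(v), 0)
  }, numeric(1))
  smaps <- lapply(volumes, sensitivity_map, z_trim = 0.2)
  c_inter <- vapply(seq_len(max(n - 1, 0)), function(i) {
    inter_loss(volumes[[i]], volumes[[i + 1]], smaps[[i]], smaps[[i + 1]], ...)
  }, numeric(1))
  solve_distribution(c_intra, c_inter)
}

#' Interpolation time parameter for fine-tune sample i
#'
#' `t = i / (l1/2 + M + l2/2 - 1)` for the sample series running from the
#' middle image of volume 1 to the middle image of volume 2.
#'
#' @param i 0-based serial number of the image in the fine-tune data
#' @param l1,l2 slice counts of the two volumes
#' @param M number of images to be generated between them
#' @return t in `\[0, 1\]` (callers index within range)
#' @export
time_parameter <- function(i, l1, l2, M) {
  if (M < 0) stop("time_parameter: M must be nonnegative")
  den <- l1 / 2 + M + l2 / 2 - 1
  if (den <= 0) stop("time_parameter: non-positive denominator")
  i / den
}

#' Distillation configuration
#' @param T distillation temperature (> 0)
#' @param alpha weight of the distillation term in `\[0, 1\]`
#' @param epochs,lr,seed training controls
#' @return a `distillation_config`
#' @export
distillation_config <- function(T = 2, alpha = 0.2, epochs = 50, lr = 0.05,
                                seed = 1) {
  stopifnot(T > 0, alpha >= 0, alpha <= 1, epochs >= 1, lr > 0)
  structure(list(T = T, alpha = alpha, epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "distillation_config")
}

#' Distillation training loss
#'
#' `L = (1 - alpha) * L_rec + alpha * T^2 * L_dis` with
#' `L_rec = ||I_hat - I||_2` (root mean square over elements) and
#' `L_dis = 0.5 * L1(flow_s/T - flow_t/T) + 0.5 * L1(arb_s/T - arb_t/T)`
#' (elementwise-mean L1 terms).
#'
#' @param student_frame,true_frame generated and real image
#' @param student_flow,teacher_flow flow-part outputs (same shapes)
#' @param student_arb,teacher_arb interpolation-part outputs (same shapes)
#' @param cfg a [distillation_config()]
#' @return scalar loss; components in attributes `L_rec`, `L_dis`
#' @export
distillation_loss <- function(student_frame, true_frame, student_flow,
                              teacher_flow, student_arb, teacher_arb, cfg) {
  chk <- function(a, b, what) {
    if (!identical(dim2(a), dim2(b))) {
      stop("distillation_loss: shape mismatch in ", what)
    }
  }
  chk(student_frame, true_frame, "reconstruction pair")
  chk(student_flow, teacher_flow, "flow outputs")
  chk(student_arb, teacher_arb, "interpolation outputs")
  T <- cfg$T
  l_rec <- sqrt(mean((student_frame - true_frame)^2))
  l_dis <- 0.5 * mean(abs(student_flow / T - teacher_flow / T)) +
    0.5 * mean(abs(student_arb / T - teacher_arb / T))
  out <- (1 - cfg$alpha) * l_rec + cfg$alpha * T^2 * l_dis
  attr(out, "L_rec") <- l_rec
  attr(out, "L_dis") <- l_dis
  out
}

# ---- interpolator models ---------------------------------------------

#' Deterministic flow-blend interpolator (reference teacher)
#'
#' Bidirectional pyramidal Lucas-Kanade flow plus the symmetric blend
#' `I_t = (1 - t) * warp(I0, t * F01) + t * warp(I1, (1 - t) * F10)`.
#' Identical boundary frames produce exactly the boundary frame at any t.
#'
#' @return an `interpolator_model` with provenance `"baseline"`
#' @export
baseline_interpolator <- function() {
  flow_part <- function(i0, i1) {
    list(f01 = lk_flow(i1, i0), f10 = lk_flow(i0, i1))
  }
  arb_part <- function(i0, i1, t, flows) {
    w0 <- warp_image(i0, deformation_field(t * flows$f01$dx,
                                           t * flows$f01$dy))
    w1 <- warp_image(i1, deformation_field((1 - t) * flows$f10$dx,
                                           (1 - t) * flows$f10$dy))
    (1 - t) * w0 + t * w1
  }
  structure(
    list(flow_part = flow_part, arb_part = arb_part,
         final = function(i0, i1, t, flows, arb) arb,
         provenance = "baseline", params = NULL),
    class = "interpolator_model"
  )
}

#' Tiny trainable student interpolator
#'
#' A desk-scale parametric interpolator: each direction's flow is a global
#' (constant) field, and the blended frame receives a trainable gain/bias
#' correction. Six parameters in total, optimised by finite-difference
#' gradient descent on the distillation loss. Deliberately small — the
#' point is the distillation mechanics, not network capacity.
#'
#' @param seed initialisation seed (small random perturbation)
#' @return an `interpolator_model` with provenance `"student"`
#' @export
student_interpolator <- function(seed = 1) {
  params <- with_seed(seed, c(fx01 = rnorm(1, 0, 0.01),
                              fy01 = rnorm(1, 0, 0.01),
                              fx10 = rnorm(1, 0, 0.01),
                              fy10 = rnorm(1, 0, 0.01),
                              gain = 1, bias = 0))
  build <- function(params) {
    flow_part <- function(i0, i1) {
      sh <- dim(i0)
      list(
        f01 = deformation_field(matrix(params["fx01"], sh[1], sh[2]),
                                matrix(params["fy01"], sh[1], sh[2])),
        f10 = deformation_field(matrix(params["fx10"], sh[1], sh[2]),
                                matrix(params["fy10"], sh[1], sh[2]))
      )
    }
    arb_part <- function(i0, i1, t, flows) {
      w0 <- warp_image(i0, deformation_field(t * flows$f01$dx,
                                             t * flows$f01$dy))
      w1 <- warp_image(i1, deformation_field((1 - t) * flows$f10$dx,
                                             (1 - t) * flows$f10$dy))
      (1 - t) * w0 + t * w1
    }
    structure(
      list(flow_part = flow_part, arb_part = arb_part,
           final = function(i0, i1, t, flows, arb) {
             params["gain"] * arb + params["bias"]
           },
           provenance = "student", params = params, rebuild = build),
      class = "interpolator_model"
    )
  }
  build(params)
}

# Full forward pass: frame + intermediate outputs used by distillation.
interp_predict <- function(model, i0, i1, t) {
  flows <- model$flow_part(i0, i1)
  arb <- model$arb_part(i0, i1, t, flows)
  frame <- model$final(i0, i1, t, flows, arb)
  flow_stack <- array(c(flows$f01$dx, flows$f01$dy, flows$f10$dx,
                        flows$f10$dy), dim = c(dim(i0), 4))
  list(frame = frame, flow = flow_stack, arb = arb)
}

#' Generate the missing slices between two aligned volumes
#'
#' Interpolates `M` frames between the bottom slice of `vol_i` and the top
#' slice of `vol_j` at evenly spaced interior time points
#' `t = k / (M + 1)`, `k = 1..M`.
#'
#' @param vol_i,vol_j aligned `image_stack`s
#' @param M number of slices to generate (>= 0)
#' @param model an `interpolator_model` (default the flow-blend baseline)
#' @return list of `M` numeric matrices
#' @export
interpolate_gap <- function(vol_i, vol_j, M, model = baseline_interpolator()) {
  stopifnot(M >= 0)
  if (M == 0) return(list())
  di <- dim(vol_i$data); dj <- dim(vol_j$data)
  if (di[1] < 1 || dj[1] < 1) stop("interpolate_gap: empty volume")
  if (!all(di[2:3] == dj[2:3])) stop("interpolate_gap: shape mismatch")
  i0 <- matrix(vol_i$data[di[1], , ], di[2], di[3])
  i1 <- matrix(vol_j$data[1, , ], dj[2], dj[3])
  flows <- model$flow_part(i0, i1)
  lapply(seq_len(M), function(k) {
    t <- k / (M + 1)
    arb <- model$arb_part(i0, i1, t, flows)
    model$final(i0, i1, t, flows, arb)
  })
}

#' Fine-tune the student interpolator against a teacher on a volume pair
#'
#' Follows the small-sample strategy: the middle image of each volume is a
#' fixed boundary frame; every real slice between the two middles is a
#' training sample with its [time_parameter()] t; the student minimises
#' [distillation_loss()] against the teacher's flow and interpolation
#' outputs by finite-difference gradient descent. Deterministic for a
#' fixed config.
#'
#' @param student an `interpolator_model` from [student_interpolator()]
#' @param teacher an `interpolator_model` (e.g. the baseline)
#' @param vol_pair list of two `image_stack`s
#' @param M slice count of the gap between the volumes
#' @param cfg a [distillation_config()]
#' @param max_samples cap on training samples (evenly subsampled)
#' @return the trained student, with attribute `loss_trajectory`
#'   (per-epoch mean loss) and `l_dis_trajectory`
#' @export
fine_tune_student <- function(student, teacher, vol_pair, M = 0,
                              cfg = distillation_config(),
                              max_samples = 8) {
  v1 <- vol_pair[[1]]; v2 <- vol_pair[[2]]
  l1 <- dim(v1$data)[1]; l2 <- dim(v2$data)[1]
  if (l1 < 2 || l2 < 2) stop("fine_tune_student: need >= 2 slices per volume")
  m1 <- ceiling(l1 / 2); m2 <- ceiling(l2 / 2)
  i0 <- matrix(v1$data[m1, , ], dim(v1$data)[2], dim(v1$data)[3])
  i1 <- matrix(v2$data[m2, , ], dim(v2$data)[2], dim(v2$data)[3])
  # real samples: vol1 slices m1..l1 (serial 0..l1-m1), then after the gap
  # vol2 slices 1..m2 (serial l1-m1+M+1 .. l1-m1+M+m2)
  samples <- rbind(
    data.frame(vol = 1, z = m1:l1, i = (m1:l1) - m1),
    data.frame(vol = 2, z = 1:m2, i = (l1 - m1) + M + (1:m2))
  )
  if (nrow(samples) > max_samples) {
    samples <- samples[unique(round(seq(1, nrow(samples),
                                        length.out = max_samples))), ]
  }
  get_true <- function(s) {
    v <- if (s["vol"] == 1) v1 else v2
    matrix(v$data[s["z"], , ], dim(v$data)[2], dim(v$data)[3])
  }
  teach <- interp_predict(teacher, i0, i1, 0.5) # flow part is t-free
  t_of <- function(i) time_parameter(i, l1, l2, M)
  teacher_out <- lapply(seq_len(nrow(samples)), function(r) {
    t <- t_of(samples$i[r])
    arb <- teacher$arb_part(i0, i1, t, list(
      f01 = deformation_field(teach$flow[, , 1], teach$flow[, , 2]),
      f10 = deformation_field(teach$flow[, , 3], teach$flow[, , 4])
    ))
    list(flow = teach$flow, arb = arb, t = t,
         true = get_true(unlist(samples[r, ])))
  })
  loss_of <- function(params) {
    model <- student$rebuild(params)
    total <- 0
    dis <- 0
    for (s in teacher_out) {
      pr <- interp_predict(model, i0, i1, s$t)
      l <- distillation_loss(pr$frame, s$true, pr$flow, s$flow, pr$arb,
                             s$arb, cfg)
      total <- total + as.numeric(l)
      dis <- dis + attr(l, "L_dis")
    }
    c(total / length(teacher_out), dis / length(teacher_out))
  }
  params <- student$params
  h <- 1e-3
  traj <- numeric(cfg$epochs)
  traj_dis <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    base <- loss_of(params)
    if (!is.finite(base[1])) {
      stop("fine_tune_student: training diverged (non-finite loss) at epoch ",
           ep, "; params = ", paste(round(params, 4), collapse = ", "))
    }
    traj[ep] <- base[1]
    traj_dis[ep] <- base[2]
    grad <- vapply(seq_along(params), function(p) {
      up <- params; up[p] <- up[p] + h
      dn <- params; dn[p] <- dn[p] - h
      (loss_of(up)[1] - loss_of(dn)[1]) / (2 * h)
    }, numeric(1))
    step <- cfg$lr * grad
    cand <- params - step
    # backtracking keeps the trajectory non-increasing
    for (bt in 1:8) {
      if (loss_of(cand)[1] <= base[1]) break
      step <- step / 2
      cand <- params - step
    }
    if (loss_of(cand)[1] <= base[1]) params <- cand
  }
  out <- student$rebuild(params)
  attr(out, "loss_trajectory") <- traj
  attr(out, "l_dis_trajectory") <- traj_dis
  out
}

#' Assemble sections and generated gap slices into one continuous volume
#'
#' @param volumes list of `image_stack`s with identical (y, x) shape
#' @param gaps list (length `length(volumes) - 1`) of slice lists as
#'   returned by [interpolate_gap()]
#' @return the z-concatenated `image_stack` (voxel size of the first)
#' @export
assemble_volume <- function(volumes, gaps) {
  n <- length(volumes)
  stopifnot(n >= 1, length(gaps) == n - 1)
  shp <- dim(volumes[[1]]$data)[2:3]
  for (v in volumes) {
    if (!all(dim(v$data)[2:3] == shp)) stop("assemble_volume: shape mismatch")
  }
  total_z <- sum(vapply(volumes, function(v) dim(v$data)[1], numeric(1))) +
    sum(vapply(gaps, length, numeric(1)))
  out <- array(0, dim = c(total_z, shp[1], shp[2]))
  z <- 0
  for (i in seq_len(n)) {
    nz <- dim(volumes[[i]]$data)[1]
    out[z + seq_len(nz), , ] <- volumes[[i]]$data
    z <- z + nz
    if (i < n) {
      for (sl in gaps[[i]]) {
        if (!all(dim(sl) == shp)) stop("assemble_volume: gap slice shape mismatch")
        z <- z + 1
        out[z, , ] <- sl
      }
    }
  }
  image_stack(out, volumes[[1]]$voxel_size_nm, "assembled")
}
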