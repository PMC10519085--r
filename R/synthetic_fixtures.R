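# Phantom generators with exact ground truth for every pipeline stage:
# z-coherent textured volumes, serial "cutting" with known lost slices and
# known per-section deformations, and membrane/vesicle geometry with a
# reference affinity map.
#
# All generators are pure functions of their arguments and seed.

#' Phantom specification
#' @param shape integer `(z, y, x)` extents
#' @param texture `"blobs"`, `"filaments"`, `"ramp"` or `"checker"`
#' @param noise_sigma Gaussian noise level on the \[0, 1\] intensity scale
#' @param seed RNG seed (same seed, bit-identical phantom)
#' @param voxel_size_nm `(x, y, z)` voxel size in nm
#' @param ramp_rate intensity increase per slice for `"ramp"` (gray/slice
#'   on the \[0, 1\] scale)
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(shape, texture = c("blobs", "filaments", "ramp", "checker"),
                         noise_sigma = 0, seed = 1,
                         voxel_size_nm = c(0.664, 0.664, 0.664),
                         ramp_rate = 0.002) {
  texture <- match.arg(texture)
  stopifnot(length(shape) == 3, all(shape >= 1), noise_sigma >= 0)
  structure(
    list(shape = as.integer(shape), texture = texture,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         voxel_size_nm = voxel_size_nm, ramp_rate = ramp_rate),
    class = "phantom_spec"
  )
}

# Render a field of drifting 2D Gaussian blobs (shared by several textures).
render_blobs <- function(shape, n_blobs, drift_px, seed_offset = 0, seed) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  with_seed(seed + seed_offset, {
    k <- n_blobs
    cx <- runif(k, 0, nx - 1)
    cy <- runif(k, 0, ny - 1)
    sg <- runif(k, 2.5, max(4, min(ny, nx) / 12))
    amp <- runif(k, 0.25, 0.9) * sample(c(-1, 1), k, replace = TRUE)
    vx <- runif(k, -drift_px, drift_px)
    vy <- runif(k, -drift_px, drift_px)
    vol <- array(0, dim = shape)
    xs <- seq_len(nx) - 1
    ys <- seq_len(ny) - 1
    for (z in seq_len(nz)) {
      sl <- matrix(0, ny, nx)
      for (j in seq_len(k)) {
        bx <- cx[j] + vx[j] * (z - 1)
        by <- cy[j] + vy[j] * (z - 1)
        gx <- exp(-(xs - bx)^2 / (2 * sg[j]^2))
        gy <- exp(-(ys - by)^2 / (2 * sg[j]^2))
        sl <- sl + amp[j] * outer(gy, gx)
      }
      vol[z, , ] <- sl
    }
    vol
  })
}

#' Generate a textured phantom volume
#'
#' Structures drift slowly along z (the pixel change between consecutive
#' slices is small), mimicking the z-coherence of tomographic
#' reconstructions of tissue.
#'
#' @param spec a [phantom_spec()], or the shape if the remaining arguments
#'   are given directly
#' @param ... passed to [phantom_spec()] when `spec` is a shape
#' @return an `image_stack` with values in \[0, 1\]
#' @export
make_phantom <- function(spec, ...) {
  if (!inherits(spec, "phantom_spec")) spec <- phantom_spec(spec, ...)
  shape <- spec$shape
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (ny < 8 || nx < 8) stop("make_phantom: degenerate shape")
  n_blobs <- max(6, round(ny * nx / 1200))
  base <- switch(spec$texture,
    blobs = render_blobs(shape, n_blobs, drift_px = 0.15, seed = spec$seed),
    filaments = {
      # filaments = elongated blobs: stretched anisotropic bumps drifting in z
      v <- render_blobs(shape, n_blobs, drift_px = 0.2, seed = spec$seed)
      for (z in seq_len(nz)) {
        v[z, , ] <- gauss_filter(matrix(v[z, , ], ny, nx), 9, 1.2) +
          0.5 * t(gauss_filter(t(matrix(v[z, , ], ny, nx)), 15, 4))
      }
      v
    },
    ramp = {
      v <- render_blobs(c(1L, ny, nx), n_blobs, drift_px = 0, seed = spec$seed)
      sl <- matrix(v[1, , ], ny, nx)
      rng <- range(sl)
      # keep the textured base strictly positive so the added ramp is the
      # exact per-slice increment everywhere (no clipping)
      if (diff(rng) > 0) sl <- 0.05 + 0.45 * (sl - rng[1]) / diff(rng)
      out <- array(0, dim = shape)
      for (z in seq_len(nz)) out[z, , ] <- sl + (z - 1) * spec$ramp_rate
      out
    },
    checker = {
      tile <- 16
      sl <- outer(seq_len(ny) - 1, seq_len(nx) - 1,
                  function(y, x) ((y %/% tile + x %/% tile) %% 2))
      out <- array(0, dim = shape)
      for (z in seq_len(nz)) out[z, , ] <- sl
      out
    }
  )
  # normalise to [0.05, 0.95] (ramp keeps its exact per-slice increment)
  if (spec$texture != "ramp") {
    rng <- range(base)
    if (diff(rng) > 0) base <- 0.05 + 0.9 * (base - rng[1]) / diff(rng)
  }
  if (spec$noise_sigma > 0) {
    base <- base + with_seed(spec$seed + 7919L,
                             array(rnorm(length(base), 0, spec$noise_sigma),
                                   dim = shape))
  }
  base <- pmin(pmax(base, 0), if (spec$texture == "ramp") Inf else 1)
  image_stack(base, spec$voxel_size_nm,
              origin_label = paste0("phantom:", spec$texture))
}

#' Random smooth 2D deformation field
#'
#' Coarse-grid random displacements, bilinearly upsampled and smoothed;
#' used as ground-truth elastic warp in fixtures.
#' @param shape `(y, x)` field shape
#' @param max_disp_px peak displacement magnitude
#' @param grid_n control grid resolution per axis
#' @param seed RNG seed
#' @return a `deformation_field` (see [deformation_field()])
#' @export
random_smooth_field <- function(shape, max_disp_px = 4, grid_n = 4, seed = 1) {
  with_seed(seed, {
    mk <- function() {
      coarse <- matrix(runif(grid_n^2, -1, 1), grid_n, grid_n)
      f <- resize_image(coarse, shape)
      f <- gauss_filter(f, 2 * round(min(shape) / 8) + 1, min(shape) / 10)
      f / max(abs(f), 1e-9) * max_disp_px
    }
    deformation_field(mk(), mk())
  })
}

#' Cut a phantom volume into serial sections with known losses
#'
#' Partitions the z-extent into `n_sections` contiguous blocks (the
#' physical cuts). Within block i the first `delete_top[i]` and last
#' `delete_bot[i]` slices are discarded — the material lost to cutting,
#' missing wedge and shrinkage. Each surviving section volume is then
#' warped by its per-section affine and elastic field, optionally blurred
#' at its z-extremes (missing-wedge proxy: the reconstructed volume ends
#' are obscure) and corrupted with seeded noise.
#'
#' @param vol source `image_stack`
#' @param n_sections number of sections
#' @param delete_top,delete_bot integer vectors (length `n_sections`) of
#'   slices lost at each block's top/bottom
#' @param affines optional list of per-section `affine2d` (pixel coords)
#' @param elastic optional list of per-section `deformation_field`
#' @param noise_sigma per-section additive noise level
#' @param seed RNG seed
#' @param end_blur_frac fraction of slices at each section end receiving
#'   graded Gaussian blur (0 disables)
#' @return list with `sections` (list of `image_stack`), `meta` (a
#'   `section_meta` data frame) and `truth` (block ranges, deletions,
#'   transforms)
#' @export
slice_into_serial <- function(vol, n_sections, delete_top, delete_bot,
                              affines = NULL, elastic = NULL,
                              noise_sigma = 0, seed = 1,
                              end_blur_frac = 0.1) {
  stopifnot(inherits(vol, "image_stack"))
  nz <- dim(vol$data)[1]
  delete_top <- rep_len(as.integer(delete_top), n_sections)
  delete_bot <- rep_len(as.integer(delete_bot), n_sections)
  if (any(delete_top < 0) || any(delete_bot < 0)) {
    stop("slice_into_serial: deletions must be nonnegative")
  }
  block_len <- rep(nz %/% n_sections, n_sections)
  extra <- nz %% n_sections
  if (extra > 0) block_len[seq_len(extra)] <- block_len[seq_len(extra)] + 1
  if (any(block_len - delete_top - delete_bot < 1)) {
    stop("slice_into_serial: infeasible partition (section with no slices left)")
  }
  starts <- cumsum(c(1, head(block_len, -1)))
  vz <- vol$voxel_size_nm[3]
  sections <- vector("list", n_sections)
  meta <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    keep <- seq(starts[i] + delete_top[i],
                starts[i] + block_len[i] - 1 - delete_bot[i])
    sec <- vol$data[keep, , , drop = FALSE]
    sec_stack <- image_stack(sec, vol$voxel_size_nm,
                             origin_label = sprintf("section %d", i))
    if (!is.null(affines) && !is.null(affines[[i]])) {
      sec_stack <- apply_affine_to_volume(sec_stack, affines[[i]])
    }
    if (!is.null(elastic) && !is.null(elastic[[i]])) {
      sec_stack <- apply_field(sec_stack, elastic[[i]])
    }
    d <- sec_stack$data
    if (end_blur_frac > 0) {
      nzi <- dim(d)[1]
      n_blur <- max(1, round(end_blur_frac * nzi))
      for (k in seq_len(min(n_blur, nzi))) {
        s <- 1.5 * (n_blur - k + 1) / n_blur
        d[k, , ] <- gauss_filter(matrix(d[k, , ], dim(d)[2], dim(d)[3]), 9, s)
        zk <- nzi - k + 1
        d[zk, , ] <- gauss_filter(matrix(d[zk, , ], dim(d)[2], dim(d)[3]), 9, s)
      }
    }
    if (noise_sigma > 0) {
      d <- d + with_seed(seed + 101L * i,
                         array(rnorm(length(d), 0, noise_sigma), dim = dim(d)))
    }
    sections[[i]] <- image_stack(d, vol$voxel_size_nm,
                                 origin_label = sprintf("section %d", i))
    # keep the warp validity: fixture borders are fill, not tissue
    attr(sections[[i]], "validity") <- attr(sec_stack, "validity")
    meta[[i]] <- data.frame(
      section_index = i,
      cut_thickness_nm = block_len[i] * vz,
      et_slice_count = length(keep),
      voxel_size_nm = vz
    )
  }
  meta <- do.call(rbind, meta)
  class(meta) <- c("section_meta", "data.frame")
  list(
    sections = sections,
    meta = meta,
    truth = list(
      block_len = block_len,
      block_start = starts,
      deleted_top = delete_top,
      deleted_bot = delete_bot,
      c_inter = delete_bot[-n_sections] + delete_top[-1],
      affines = affines,
      elastic = elastic,
      source_z = nz
    )
  )
}

#' Membrane + vesicle phantom with reference affinity map
#'
#' Two compartments (pre- and postsynaptic) separated by a curved membrane
#' slab; spherical vesicles sit inside the presynaptic compartment. The
#' geometry follows the scale of a cortical synapse: the whole phantom
#' spans roughly a micrometre and vesicles default to 35 nm diameter.
#'
#' @param shape `(z, y, x)` extents
#' @param voxel_size_nm `(x, y, z)` voxel size in nm
#' @param n_vesicles number of vesicles to place
#' @param vesicle_diameter_nm vesicle diameter (30-40 nm is typical)
#' @param wall_nm total membrane slab thickness (both membranes + cleft)
#' @param noise_sigma image noise level
#' @param seed RNG seed
#' @return list with `volume` (`image_stack`), `affinity` (`affinity_map`),
#'   `labels` (compartment `label_volume`: 1 = presynaptic,
#'   2 = postsynaptic), `vesicles` (`label_volume`), `active_zone`
#'   (logical array), `centers_nm`, `radius_nm`
#' @export
make_membrane_vesicle_phantom <- function(shape = c(48, 96, 96),
                                          voxel_size_nm = c(4, 4, 4),
                                          n_vesicles = 10,
                                          vesicle_diameter_nm = 35,
                                          wall_nm = 16,
                                          noise_sigma = 0,
                                          seed = 1) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  vx <- voxel_size_nm[1]; vy <- voxel_size_nm[2]; vz <- voxel_size_nm[3]
  r_nm <- vesicle_diameter_nm / 2
  if (vesicle_diameter_nm / min(voxel_size_nm) < 4) {
    stop("make_membrane_vesicle_phantom: vesicles must span >= 4 voxels")
  }
  # membrane slab: y = f(x, z), gently curved
  xs <- (seq_len(nx) - 1)
  zs <- (seq_len(nz) - 1)
  f <- outer(zs, xs, function(z, x) {
    ny * 0.55 + 4 * sin(2 * pi * x / nx) + 3 * cos(2 * pi * z / nz)
  }) # [z, x]
  half_wall_vox <- (wall_nm / 2) / vy
  yy <- array(rep(seq_len(ny) - 1, each = nz), dim = c(nz, ny, nx))
  ff <- array(rep(f, times = ny), dim = c(nz, nx, ny)) # [z, x, y]
  ff <- aperm(ff, c(1, 3, 2))
  wall <- abs(yy - ff) <= half_wall_vox
  pre <- yy < ff - half_wall_vox
  post <- yy > ff + half_wall_vox

  labels <- array(0L, dim = shape)
  labels[pre] <- 1L
  labels[post] <- 2L

  # vesicles: rejection-sample non-overlapping centres inside presynaptic
  centers <- with_seed(seed, {
    out <- matrix(numeric(0), ncol = 3)
    margin_vox <- r_nm / c(vz, vy, vx) + 2
    tries <- 0
    while (nrow(out) < n_vesicles && tries < 20000) {
      tries <- tries + 1
      cz <- runif(1, margin_vox[1], nz - 1 - margin_vox[1])
      cx <- runif(1, margin_vox[3], nx - 1 - margin_vox[3])
      wall_y <- ny * 0.55 + 4 * sin(2 * pi * cx / nx) + 3 * cos(2 * pi * cz / nz)
      ymax <- wall_y - half_wall_vox - r_nm / vy - 2
      if (ymax < margin_vox[2]) next
      cy <- runif(1, margin_vox[2], ymax)
      if (nrow(out) > 0) {
        d2 <- ((out[, 1] - cz) * vz)^2 + ((out[, 2] - cy) * vy)^2 +
          ((out[, 3] - cx) * vx)^2
        if (min(d2) < (2.2 * r_nm)^2) next
      }
      out <- rbind(out, c(cz, cy, cx))
    }
    out
  })
  if (nrow(centers) < n_vesicles) {
    stop("make_membrane_vesicle_phantom: could not place ", n_vesicles,
         " non-overlapping vesicles in the presynaptic compartment")
  }

  vesicles <- array(0L, dim = shape)
  img <- array(0.75, dim = shape)
  img[wall] <- 0.15
  zz_nm <- (seq_len(nz) - 1) * vz
  yy_nm <- (seq_len(ny) - 1) * vy
  xx_nm <- (seq_len(nx) - 1) * vx
  for (v in seq_len(nrow(centers))) {
    c_nm <- centers[v, ] * c(vz, vy, vx)
    zr <- which(abs(zz_nm - c_nm[1]) <= r_nm)
    yr <- which(abs(yy_nm - c_nm[2]) <= r_nm)
    xr <- which(abs(xx_nm - c_nm[3]) <= r_nm)
    for (z in zr) for (y in yr) {
      d2 <- (zz_nm[z] - c_nm[1])^2 + (yy_nm[y] - c_nm[2])^2 +
        (xx_nm[xr] - c_nm[3])^2
      inside <- xr[d2 <= r_nm^2]
      vesicles[z, y, inside] <- as.integer(v)
      img[z, y, inside] <- 0.35
      rim <- xr[d2 <= r_nm^2 & d2 >= (0.7 * r_nm)^2]
      img[z, y, rim] <- 0.22
    }
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed + 31L,
                           array(rnorm(length(img), 0, noise_sigma),
                                 dim = shape))
    img <- pmin(pmax(img, 0), 1)
  }

  aff <- array(1, dim = c(shape, 3))
  for (ch in 1:3) aff[, , , ch][wall] <- 0

  # active zone: presynaptic-facing wall surface within the central apposition
  az <- array(FALSE, dim = shape)
  pre_face <- abs(yy - (ff - half_wall_vox)) <= 0.6
  central <- array(FALSE, dim = shape)
  central[, , seq(round(nx * 0.3), round(nx * 0.7))] <- TRUE
  central[seq_len(nz), , ] <- central[seq_len(nz), , ] # keep full z
  az[pre_face & central] <- TRUE

  list(
    volume = image_stack(img, voxel_size_nm, "phantom:synapse"),
    affinity = affinity_map(aff, voxel_size_nm),
    labels = label_volume(labels,
                          label_table = c(`1` = "presynaptic compartment",
                                          `2` = "postsynaptic compartment")),
    vesicles = label_volume(vesicles),
    active_zone = az,
    centers_nm = centers[, c(3, 2, 1), drop = FALSE] *
      rep(c(vx, vy, vz), each = nrow(centers)),
    radius_nm = r_nm
  )
}
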