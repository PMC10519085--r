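# Membrane segmentation from affinity maps (weight -> binarize -> watershed
# -> structure selection, with a scriptable proofreading log) and vesicle
# detection inside the presynaptic ROI, followed by morphometrics.

#' Construct an affinity map
#' @param values 4D array `(z, y, x, channel)` with 3 channels (z, y, x
#'   axis affinities), all values in \[0, 1\]
#' @param voxel_size_nm voxel size shared with the source volume
#' @return an `affinity_map`
#' @export
affinity_map <- function(values, voxel_size_nm = c(1, 1, 1)) {
  stopifnot(is.array(values), length(dim(values)) == 4, dim(values)[4] == 3)
  if (min(values) < 0 || max(values) > 1) {
    stop("affinity_map: values must lie in [0, 1]")
  }
  structure(list(values = values, voxel_size_nm = voxel_size_nm),
            class = "affinity_map")
}

#' Construct a label volume
#' @param labels nonnegative integer array `(z, y, x)`; 0 is background
#' @param label_table optional named character vector id -> name
#' @return a `label_volume`
#' @export
label_volume <- function(labels, label_table = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (min(labels) < 0) stop("label_volume: negative labels")
  structure(list(labels = labels, label_table = label_table),
            class = "label_volume")
}

#' Weighted binarization of an affinity map into a contour mask
#'
#' Channel-weighted mean affinity thresholded at `theta`; voxels below the
#' threshold (boundary-like) form the contour.
#'
#' @param aff an `affinity_map`
#' @param weights nonnegative per-channel weights, not all zero
#' @param theta threshold in (0, 1)
#' @return logical array `(z, y, x)`: TRUE on the contour
#' @export
affinity_to_contours <- function(aff, weights = c(1, 1, 1), theta = 0.5) {
  stopifnot(inherits(aff, "affinity_map"))
  if (theta <= 0 || theta >= 1) stop("affinity_to_contours: theta must be in (0, 1)")
  if (any(weights < 0) || sum(weights) == 0) {
    stop("affinity_to_contours: weights must be nonnegative, not all zero")
  }
  w <- weights / sum(weights)
  d <- dim(aff$values)[1:3]
  avg <- array(0, dim = d)
  for (ch in 1:3) avg <- avg + w[ch] * aff$values[, , , ch]
  avg < theta
}

#' Watershed labelling of the complement of a contour mask
#'
#' Unseeded mode: connected components (6-connected) of the non-contour
#' region become the basins. Contour voxels are then assigned to the
#' adjacent basin by breadth-first flooding in distance order, ties to the
#' smaller label id (deterministic). With `seeds`, basins grow from the
#' given labels instead.
#'
#' @param contour logical array `(z, y, x)`, TRUE on boundaries
#' @param seeds optional `label_volume` of nonzero seed markers
#' @param assign_contour flood contour voxels into basins (default TRUE;
#'   FALSE leaves them 0)
#' @return a `label_volume` with contiguous ids from 1
#' @export
watershed_labels <- function(contour, seeds = NULL, assign_contour = TRUE) {
  stopifnot(is.array(contour), length(dim(contour)) == 3)
  d <- dim(contour)
  if (all(contour)) stop("watershed_labels: all-contour input has no basins")
  if (is.null(seeds)) {
    lab <- .cc_label_3d(as.logical(!contour), as.integer(d), 6L)
  } else {
    stopifnot(all(dim(seeds$labels) == d))
    lab <- as.integer(seeds$labels)
    lab[as.logical(contour)] <- 0L
  }
  if (assign_contour) {
    lab <- .flood_assign(lab, as.integer(d))
  }
  lab <- array(lab, dim = d)
  # contiguous ids from 1 in first-appearance order
  ids <- sort(unique(as.integer(lab)))
  ids <- ids[ids != 0]
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    nz <- lab != 0
    lab[nz] <- remap[lab[nz]]
  }
  label_volume(lab)
}

#' Select and name structures by anchor points
#'
#' @param labels a `label_volume`
#' @param anchor_points matrix / list of voxel coordinates, rows `(z, y,
#'   x)` 1-based
#' @param name structure name given to the merged selection
#' @return a `label_volume` holding one label (id 1) covering the union of
#'   the anchored basins
#' @export
select_structure <- function(labels, anchor_points, name = "structure") {
  stopifnot(inherits(labels, "label_volume"))
  if (is.list(anchor_points)) anchor_points <- do.call(rbind, anchor_points)
  anchor_points <- matrix(as.integer(anchor_points), ncol = 3)
  d <- dim(labels$labels)
  ids <- integer(0)
  for (r in seq_len(nrow(anchor_points))) {
    p <- anchor_points[r, ]
    if (any(p < 1) || any(p > d)) {
      stop("select_structure: anchor ", paste(p, collapse = ","),
           " outside the volume")
    }
    id <- labels$labels[p[1], p[2], p[3]]
    if (id == 0) {
      stop("select_structure: anchor ", paste(p, collapse = ","),
           " lies on background")
    }
    ids <- union(ids, id)
  }
  mask <- array(0L, dim = d)
  mask[labels$labels %in% ids] <- 1L
  label_volume(mask, label_table = stats::setNames(name, "1"))
}

#' Replay a scripted edit log on a label volume
#'
#' A deterministic stand-in for interactive proofreading: each edit paints
#' or erases a set of voxels; later edits win on overlap. The applied log
#' is attached for provenance.
#'
#' @param labels a `label_volume`
#' @param edits list of edits, each `list(op = "paint"|"erase", voxels =
#'   n x 3 matrix of 1-based (z, y, x), label = id for paint)`
#' @return edited `label_volume` with attribute `edit_log`
#' @export
edit_labels <- function(labels, edits) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  for (k in seq_along(edits)) {
    e <- edits[[k]]
    v <- matrix(as.integer(e$voxels), ncol = 3)
    if (any(v < 1) || any(sweep(v, 2, d, ">") != 0)) {
      stop("edit_labels: edit ", k, " has out-of-bounds voxels")
    }
    idx <- cbind(v[, 1], v[, 2], v[, 3])
    if (e$op == "paint") {
      lab[idx] <- as.integer(e$label)
    } else if (e$op == "erase") {
      lab[idx] <- 0L
    } else {
      stop("edit_labels: unknown op '", e$op, "' in edit ", k)
    }
  }
  out <- label_volume(lab, labels$label_table)
  attr(out, "edit_log") <- edits
  out
}

#' Reference intensity-threshold vesicle predictor
#'
#' Scores dark voxels highly: `1 - stretched intensity`. Stands in for a
#' trained voxelwise model in tests and examples.
#' @param vol an `image_stack`
#' @param roi logical array restricting the scoring domain
#' @return array of scores in \[0, 1\] (0 outside the ROI)
#' @export
intensity_predictor <- function(vol, roi) {
  v <- vol$data
  rng <- range(v[roi])
  sc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  out <- 1 - pmin(pmax(sc, 0), 1)
  out[!roi] <- 0
  out
}

#' Segment vesicles inside a region of interest
#'
#' The presynaptic-membrane segmentation serves as the ROI so the
#' detector never sees the heavily imbalanced full volume. A pluggable
#' voxelwise predictor scores ROI voxels; connected components of the
#' thresholded score that match the expected vesicle size are labelled.
#' Components straddling the ROI boundary are clipped to it and counted
#' once.
#'
#' @param vol an `image_stack`
#' @param roi a `label_volume` mask (nonzero = ROI) or logical array
#' @param predictor `function(vol, roi_logical)` returning scores in
#'   \[0, 1\]
#' @param threshold score threshold
#' @param min_diameter_nm,max_diameter_nm admissible equivalent-sphere
#'   diameters
#' @return a `label_volume`, one id per vesicle
#' @export
segment_vesicles <- function(vol, roi, predictor = intensity_predictor,
                             threshold = 0.5, min_diameter_nm = 20,
                             max_diameter_nm = 60) {
  stopifnot(inherits(vol, "image_stack"))
  roi_log <- if (inherits(roi, "label_volume")) roi$labels > 0 else as.array(roi)
  d <- dim(vol$data)
  stopifnot(all(dim(roi_log) == d))
  if (!any(roi_log)) {
    return(label_volume(array(0L, dim = d)))
  }
  scores <- predictor(vol, roi_log)
  if (min(scores) < -1e-9 || max(scores) > 1 + 1e-9) {
    stop("segment_vesicles: predictor scores outside [0, 1]")
  }
  mask <- scores >= threshold & roi_log
  lab <- array(.cc_label_3d(as.logical(mask), as.integer(d), 26L), dim = d)
  voxel_vol <- prod(vol$voxel_size_nm)
  min_vol <- (4 / 3) * pi * (min_diameter_nm / 2)^3
  max_vol <- (4 / 3) * pi * (max_diameter_nm / 2)^3
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * voxel_vol >= min_vol & counts * voxel_vol <= max_vol)
  out <- array(0L, dim = d)
  for (i in seq_along(keep)) out[lab == keep[i]] <- as.integer(i)
  label_volume(out)
}

#' Vesicle morphometrics
#'
#' Volumes, centroid distances to the active zone, and nearest-neighbour
#' centre-to-centre distances, all in physical units and aware of
#' anisotropic voxel sizes.
#'
#' @param vesicles a `label_volume` of vesicles
#' @param active_zone logical array marking active-zone voxels (may be
#'   NULL: distance column omitted)
#' @param voxel_size_nm `(x, y, z)` voxel size in nm
#' @return data.frame (`vesicle_table`): `id`, `centroid_x/y/z_nm`,
#'   `volume_nm3`, `dist_active_zone_nm`, `nn_center_distance_nm`
#' @export
vesicle_morphometrics <- function(vesicles, active_zone = NULL,
                                  voxel_size_nm = c(1, 1, 1)) {
  stopifnot(inherits(vesicles, "label_volume"))
  lab <- vesicles$labels
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) stop("vesicle_morphometrics: no vesicles")
  d <- dim(lab)
  vx <- voxel_size_nm[1]; vy <- voxel_size_nm[2]; vz <- voxel_size_nm[3]
  idx <- which(lab > 0)
  zz <- ((idx - 1) %% d[1]) + 1
  yy <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  xx <- ((idx - 1) %/% (d[1] * d[2])) + 1
  lv <- lab[idx]
  cent <- t(vapply(ids, function(id) {
    s <- lv == id
    c(mean(xx[s] - 1) * vx, mean(yy[s] - 1) * vy, mean(zz[s] - 1) * vz,
      sum(s))
  }, numeric(4)))
  out <- data.frame(
    id = seq_along(ids),
    centroid_x_nm = cent[, 1], centroid_y_nm = cent[, 2],
    centroid_z_nm = cent[, 3],
    volume_nm3 = cent[, 4] * vx * vy * vz
  )
  if (!is.null(active_zone)) {
    az_idx <- which(active_zone)
    if (length(az_idx) == 0) stop("vesicle_morphometrics: empty active zone")
    az_z <- (((az_idx - 1) %% d[1])) * vz
    az_y <- ((((az_idx - 1) %/% d[1]) %% d[2])) * vy
    az_x <- (((az_idx - 1) %/% (d[1] * d[2]))) * vx
    out$dist_active_zone_nm <- vapply(seq_len(nrow(out)), function(r) {
      sqrt(min((az_x - out$centroid_x_nm[r])^2 +
                 (az_y - out$centroid_y_nm[r])^2 +
                 (az_z - out$centroid_z_nm[r])^2))
    }, numeric(1))
  }
  if (nrow(out) >= 2) {
    dm <- as.matrix(dist(out[, c("centroid_x_nm", "centroid_y_nm",
                                 "centroid_z_nm")]))
    diag(dm) <- Inf
    out$nn_center_distance_nm <- apply(dm, 1, min)
  } else {
    out$nn_center_distance_nm <- NA_real_
    attr(out, "single_vesicle") <- TRUE
  }
  class(out) <- c("vesicle_table", "data.frame")
  out
}
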