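# Rough ROI localisation across serial sections.
#
# Sections are placed side by side on the support grid, so the stage
# coordinates of one structure in consecutive sections are related by a
# low-order 2D map. With one confirmed pair of consecutive positions the
# map is a translation; with two, a similarity; with three or more, a full
# affine. Each newly confirmed (exact) position triggers a refit, and the
# next section's rough position is predicted from the latest exact one.

#' Construct an ROI position record
#' @param section_index section number (>= 1)
#' @param xy_um numeric `(x, y)` stage coordinates in micrometres
#' @param status `"exact"` (operator-confirmed) or `"rough"` (predicted)
#' @return a one-row `data.frame` with class `roi_position`
#' @export
roi_position <- function(section_index, xy_um, status = c("exact", "rough")) {
  status <- match.arg(status)
  stopifnot(section_index >= 1, length(xy_um) == 2, all(is.finite(xy_um)))
  structure(
    data.frame(
      section = as.integer(section_index),
      x_um = xy_um[1], y_um = xy_um[2],
      status = status, stringsAsFactors = FALSE
    ),
    class = c("roi_position", "data.frame")
  )
}

#' Fit the stage-appropriate inter-section model from confirmed pairs
#'
#' `prior_pairs` holds correspondences between an exact position in section
#' n and the exact position of the same structure in section n + 1. The
#' model family escalates with the evidence: one pair fits a translation,
#' two a similarity, three or more (non-collinear) a full affine; all
#' overdetermined cases are least squares.
#'
#' @param src n x 2 matrix of (x, y) positions in the earlier sections (um)
#' @param dst n x 2 matrix of the corresponding positions one section later
#' @param variant `"auto"` (pair-count rule above) or an explicit variant
#' @return an `affine2d` model mapping section-n coordinates to n + 1
#' @export
fit_stage_model <- function(src, dst,
                            variant = c("auto", "translation", "similarity", "affine")) {
  variant <- match.arg(variant)
  src <- rbind_points(src)
  dst <- rbind_points(dst)
  if (nrow(src) != nrow(dst) || nrow(src) < 1) {
    stop("fit_stage_model: need matched, non-empty pair lists")
  }
  n <- nrow(src)
  if (variant == "auto") {
    variant <- if (n == 1) "translation" else if (n == 2) "similarity" else "affine"
    if (variant != "translation") {
      sv <- svd(scale(src, scale = FALSE))$d
      if (sv[1] < 1e-9) {
        # coincident sources (e.g. identically placed sections): only the
        # translation is identifiable
        variant <- "translation"
      } else if (variant == "affine" && sv[2] / sv[1] < 0.02) {
        # sections are usually collected along a line; a near-collinear
        # cloud makes the 6-parameter fit ill-conditioned and amplifies
        # the placement jitter, so fall back to the similarity family
        variant <- "similarity"
      }
    }
  }
  need <- c(translation = 1, similarity = 2, affine = 3)[[variant]]
  if (n < need) {
    stop("fit_stage_model: ", variant, " fit needs >= ", need,
         " pair(s), got ", n)
  }
  switch(variant,
    translation = fit_translation(src, dst),
    similarity = fit_similarity(src, dst),
    affine = fit_affine(src, dst)
  )
}

#' Predict the rough ROI position in the next section
#' @param model `affine2d` from [fit_stage_model()]
#' @param loc_exact `roi_position` with status `"exact"`
#' @return `roi_position` for the following section with status `"rough"`
#' @export
predict_rough <- function(model, loc_exact) {
  stopifnot(inherits(loc_exact, "roi_position"))
  if (loc_exact$status != "exact") {
    stop("predict_rough: prediction must start from an exact position")
  }
  xy <- apply_affine(model, c(loc_exact$x_um, loc_exact$y_um))
  roi_position(loc_exact$section + 1L, as.numeric(xy), "rough")
}

#' Propagate ROI positions across a section series
#'
#' Sections `1..k` (k >= 2) must carry exact positions. For each later
#' section the model is refit from all consecutive exact pairs available so
#' far, the rough position is predicted from the latest exact position,
#' and — when a `confirm` callback is supplied, standing in for the
#' operator precisely relocating the structure at high magnification — the
#' confirmed position joins the exact set before the next prediction.
#' Without `confirm`, predictions chain on themselves.
#'
#' @param exact `data.frame` with columns `section`, `x_um`, `y_um` for the
#'   initially confirmed sections (must cover 1..k, k >= 2)
#' @param n_sections total number of sections
#' @param confirm optional `function(section, rough_xy)` returning the
#'   confirmed `(x, y)` position
#' @return `data.frame` with columns `section`, `x_um`, `y_um`, `status`;
#'   `status` is `"exact"` for inputs/confirmed entries, `"rough"` for
#'   predictions
#' @export
propagate_sequence <- function(exact, n_sections, confirm = NULL) {
  stopifnot(is.data.frame(exact),
            all(c("section", "x_um", "y_um") %in% names(exact)))
  exact <- exact[order(exact$section), , drop = FALSE]
  k <- nrow(exact)
  if (k < 2 || !identical(as.integer(exact$section), seq_len(k))) {
    stop("propagate_sequence: need exact positions for sections 1..k, k >= 2 ",
         "(check the candidate structure in the adjacent section first)")
  }
  stopifnot(n_sections >= k)
  pos <- data.frame(
    section = seq_len(n_sections),
    x_um = NA_real_, y_um = NA_real_,
    status = NA_character_, stringsAsFactors = FALSE
  )
  pos$x_um[seq_len(k)] <- exact$x_um
  pos$y_um[seq_len(k)] <- exact$y_um
  pos$status[seq_len(k)] <- "exact"
  for (s in seq(k + 1, length.out = n_sections - k)) {
    usable <- which(pos$status[seq_len(s - 1)] == "exact")
    # consecutive exact pairs (j, j + 1) observed so far
    pair_src <- usable[(usable + 1) %in% usable]
    src <- cbind(pos$x_um[pair_src], pos$y_um[pair_src])
    dst <- cbind(pos$x_um[pair_src + 1], pos$y_um[pair_src + 1])
    model <- fit_stage_model(src, dst)
    from <- roi_position(s - 1L, c(pos$x_um[s - 1], pos$y_um[s - 1]), "exact")
    rough <- predict_rough(model, from)
    pos$x_um[s] <- rough$x_um
    pos$y_um[s] <- rough$y_um
    pos$status[s] <- "rough"
    if (!is.null(confirm)) {
      conf <- confirm(s, c(rough$x_um, rough$y_um))
      pos$x_um[s] <- conf[1]
      pos$y_um[s] <- conf[2]
      pos$status[s] <- "exact"
    } else {
      # chain forward: treat the prediction as the best available anchor
      pos$status[s] <- "exact"
      attr(pos, "chained") <- c(attr(pos, "chained"), s)
    }
  }
  if (!is.null(attr(pos, "chained"))) {
    pos$status[attr(pos, "chained")] <- "rough"
  }
  pos
}
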