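# End-to-end reconstruction: coarse affine chaining, elastic refinement,
# gap estimation, gap generation and assembly.

#' Reconstruct a continuous volume from serial section volumes
#'
#' Aligns every section into the first section's frame (feature-based
#' affine between consecutive z-mean images, optionally polished; then
#' elastic block-matching/consistency/TPS refinement), estimates the
#' slices lost inside and between sections, generates them with the given
#' interpolator and concatenates everything.
#'
#' @param sections list of `image_stack`s in z order
#' @param meta `section_meta` data frame (one row per section)
#' @param fine run the elastic refinement stage (default TRUE)
#' @param model interpolator for gap generation
#' @param block_px,stride_px,search_px,C fine-alignment controls
#' @param seed RANSAC seed
#' @param gap_override optional integer vector of per-pair gap counts,
#'   bypassing estimation
#' @return list: `volume` (assembled `image_stack`), `aligned` (list of
#'   aligned sections), `coarse_models`, `fields`, `gaps`
#'   (`gap_estimate` or NULL), `gap_counts`
#' @export
reconstruct_series <- function(sections, meta, fine = TRUE,
                               model = baseline_interpolator(),
                               block_px = 64, stride_px = 64,
                               search_px = 16, C = 64, seed = 1,
                               gap_override = NULL) {
  n <- length(sections)
  stopifnot(n >= 2, nrow(meta) == n)
  means <- lapply(sections, mean_image)
  pair_models <- coarse_align_sections(means, seed = seed, refine = TRUE)
  aligned <- vector("list", n)
  aligned[[1]] <- sections[[1]]
  cum <- affine_model(diag(3)) # maps section-1 frame into section-i coords
  coarse_models <- vector("list", n - 1)
  fields <- vector("list", n - 1)
  for (i in 2:n) {
    # pair_models[[i-1]] maps section-i coords into section-(i-1) coords
    cum <- chain_affine(list(cum, affine_inverse(pair_models[[i - 1]])))
    coarse_models[[i - 1]] <- cum
    warped <- apply_affine_to_volume(sections[[i]], cum)
    if (fine) {
      fa <- fine_align_pair(aligned[[i - 1]], warped, block_px = block_px,
                            stride_px = stride_px, search_px = search_px,
                            C = C)
      aligned[[i]] <- fa$warped
      fields[[i - 1]] <- fa$field
    } else {
      aligned[[i]] <- warped
    }
  }
  gaps_est <- NULL
  if (is.null(gap_override)) {
    gaps_est <- estimate_gaps(aligned, meta)
    gap_counts <- gaps_est$rounded_bot[-n] + gaps_est$rounded_top[-1]
  } else {
    gap_counts <- rep_len(as.integer(gap_override), n - 1)
  }
  gap_slices <- lapply(seq_len(n - 1), function(i) {
    interpolate_gap(aligned[[i]], aligned[[i + 1]], gap_counts[i], model)
  })
  list(
    volume = assemble_volume(aligned, gap_slices),
    aligned = aligned,
    coarse_models = coarse_models,
    fields = fields,
    gaps = gaps_est,
    gap_counts = gap_counts
  )
}
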