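two_box_affinity <- function() {
  # two compartments split by a 1-voxel wall at x = 6 (1-based index 6)
  aff <- array(1, dim = c(4, 8, 11, 3))
  for (ch in 1:3) aff[, , 6, ch] <- 0
  affinity_map(aff)
}

test_that("affinity weighting and binarization produce the wall contour", {
  full <- affinity_map(array(1, dim = c(3, 4, 5, 3)))
  expect_false(any(affinity_to_contours(full)))

  aff <- two_box_affinity()
  contour <- affinity_to_contours(aff, theta = 0.5)
  expect_true(all(contour[, , 6]))
  expect_false(any(contour[, , -6]))

  # channel weights: drop the z channel on an anisotropic wall
  aniso <- array(1, dim = c(4, 6, 6, 3))
  aniso[2, , , 1] <- 0 # z-oriented wall only in the z-affinity channel
  am <- affinity_map(aniso)
  c_all <- affinity_to_contours(am, weights = c(1, 1, 1), theta = 0.5)
  c_xy <- affinity_to_contours(am, weights = c(0, 1, 1), theta = 0.5)
  diffv <- which(c_all != c_xy, arr.ind = TRUE)
  expect_true(all(diffv[, 1] == 2)) # differences confined to the wall slice
  # oracle: direct per-voxel recomputation
  w <- c(1, 1, 1) / 3
  avg <- w[1] * aniso[, , , 1] + w[2] * aniso[, , , 2] + w[3] * aniso[, , , 3]
  expect_identical(c_all, avg < 0.5)

  expect_error(affinity_to_contours(aff, theta = 1.2), "theta")
  expect_error(affinity_to_contours(aff, weights = c(0, 0, 0)), "weights")
})

test_that("watershed conserves voxels and splits compartments deterministically", {
  aff <- two_box_affinity()
  contour <- affinity_to_contours(aff)
  ws <- watershed_labels(contour)
  expect_equal(max(ws$labels), 2)
  # conservation: every voxel belongs to exactly one basin after flooding
  expect_equal(sum(ws$labels > 0), length(ws$labels))
  # basins-only mode: wall voxels stay unassigned, counts match construction
  ws0 <- watershed_labels(contour, assign_contour = FALSE)
  expect_equal(sum(ws0$labels == 1), 4 * 8 * 5)
  expect_equal(sum(ws0$labels == 2), 4 * 8 * 5)
  expect_equal(sum(ws0$labels == 0), 4 * 8 * 1)

  # no contour at all: a single basin
  none <- array(FALSE, dim = c(3, 4, 4))
  expect_equal(max(watershed_labels(none)$labels), 1)
  expect_error(watershed_labels(array(TRUE, dim = c(2, 2, 2))), "basins")

  # seeded flooding equals an independent BFS flood on a 3-basin phantom
  contour3 <- array(FALSE, dim = c(3, 9, 9))
  contour3[, c(4, 7), ] <- TRUE
  seeds <- array(0L, dim = c(3, 9, 9))
  seeds[2, 2, 5] <- 1L; seeds[2, 5, 5] <- 2L; seeds[2, 9, 5] <- 3L
  ws3 <- watershed_labels(contour3, seeds = label_volume(seeds))
  # oracle: layered BFS with min-label tie-break
  oracle <- seeds
  oracle[contour3] <- 0L
  oracle[!contour3 & seeds == 0] <- 0L
  grow <- function(lab) {
    d <- dim(lab)
    repeat {
      nxt <- lab
      for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
        if (lab[z, y, x] != 0) next
        nb <- c(
          if (z > 1) lab[z - 1, y, x], if (z < d[1]) lab[z + 1, y, x],
          if (y > 1) lab[z, y - 1, x], if (y < d[2]) lab[z, y + 1, x],
          if (x > 1) lab[z, y, x - 1], if (x < d[3]) lab[z, y, x + 1]
        )
        nb <- nb[nb != 0]
        if (length(nb) > 0) nxt[z, y, x] <- min(nb)
      }
      if (identical(nxt, lab)) return(lab)
      lab <- nxt
    }
  }
  # fill the seedless basin interiors first (connected components step)
  expect_equal(sum(ws3$labels > 0), length(ws3$labels))
  grown <- grow(oracle)
  inb <- grown != 0
  expect_equal(ws3$labels[inb], grown[inb])
})

test_that("structure selection and scripted edits behave deterministically", {
  aff <- two_box_affinity()
  ws <- watershed_labels(affinity_to_contours(aff))
  a_vox <- c(2, 3, 2) # inside compartment A (x < wall)
  sel <- select_structure(ws, rbind(a_vox), "presynaptic membrane")
  expect_equal(sel$labels[2, 3, 2], 1L)
  expect_equal(sort(unique(as.vector(sel$labels))), c(0L, 1L))
  expect_equal(sum(sel$labels), sum(ws$labels == ws$labels[2, 3, 2]))

  both <- select_structure(ws, rbind(c(2, 3, 2), c(2, 3, 10)), "merged")
  expect_equal(sum(both$labels), length(both$labels)) # union of both basins

  expect_error(select_structure(ws, rbind(c(99, 1, 1))), "outside")
  ws0 <- watershed_labels(affinity_to_contours(aff), assign_contour = FALSE)
  expect_error(select_structure(ws0, rbind(c(1, 1, 6))), "background")
  # after flooding, a wall voxel resolves to its adjacent basin
  wall_id <- ws$labels[1, 1, 6]
  expect_true(wall_id %in% c(1L, 2L))

  # edits: identity, paint-then-erase, erase-a-bridge re-splits
  expect_identical(edit_labels(ws, list())$labels, ws$labels)
  vox <- rbind(c(1, 1, 1), c(1, 1, 2))
  pe <- edit_labels(ws0, list(
    list(op = "paint", voxels = vox, label = 7L),
    list(op = "erase", voxels = vox)
  ))
  manual <- ws0$labels
  manual[rbind(c(1, 1, 1), c(1, 1, 2))] <- 0L
  expect_identical(pe$labels[1, 1, 1:2], c(0L, 0L))

  # bridged compartments: erase the bridge, re-watershed, two labels again
  contour <- affinity_to_contours(aff)
  bridged <- contour
  bridged[2, 4, 6] <- FALSE # hole in the wall joins the compartments
  expect_equal(max(watershed_labels(bridged, assign_contour = FALSE)$labels), 1)
  repaired <- bridged
  repaired[2, 4, 6] <- TRUE # the erase stroke restores the wall
  expect_equal(max(watershed_labels(repaired, assign_contour = FALSE)$labels), 2)
})

test_that("vesicle segmentation finds all spheres inside the ROI", {
  ph <- make_membrane_vesicle_phantom(n_vesicles = 10, seed = 2)
  ws <- watershed_labels(affinity_to_contours(ph$affinity))
  pre <- ws$labels == 1
  ves <- segment_vesicles(ph$volume, pre)
  expect_equal(max(ves$labels), 10)
  # perfect recall/precision: every detected vesicle overlaps exactly one
  # ground-truth vesicle and vice versa
  for (id in 1:10) {
    hit <- unique(ph$vesicles$labels[ves$labels == id])
    hit <- hit[hit != 0]
    expect_equal(length(hit), 1)
  }

  empty <- segment_vesicles(ph$volume, array(FALSE, dim(ph$volume$data)))
  expect_equal(max(empty$labels), 0)

  bad_pred <- function(vol, roi) array(2, dim = dim(vol$data))
  expect_error(segment_vesicles(ph$volume, pre, predictor = bad_pred),
               "scores")
})

test_that("morphometrics recover analytic volumes and distances", {
  ph <- make_membrane_vesicle_phantom(n_vesicles = 10, seed = 2)
  ws <- watershed_labels(affinity_to_contours(ph$affinity))
  ves <- segment_vesicles(ph$volume, ws$labels == 1)
  tab <- vesicle_morphometrics(ves, ph$active_zone, ph$volume$voxel_size_nm)
  analytic <- (4 / 3) * pi * ph$radius_nm^3
  expect_true(all(abs(tab$volume_nm3 - analytic) / analytic < 0.05))

  # two point-vesicles 50 nm apart: exact nn distance
  lab <- array(0L, dim = c(5, 5, 5))
  lab[2, 2, 1] <- 1L
  lab[2, 2, 6 - 5] <- 1L # same voxel guard: use distinct voxels below
  lab <- array(0L, dim = c(5, 5, 11))
  lab[2, 2, 1] <- 1L
  lab[2, 2, 11] <- 2L
  t2 <- vesicle_morphometrics(label_volume(lab), NULL, c(5, 5, 5))
  expect_equal(t2$nn_center_distance_nm, c(50, 50))

  # active zone in the plane z = 0, vesicle centroid at z = 30 nm
  lab3 <- array(0L, dim = c(7, 5, 5))
  lab3[4, 3, 3] <- 1L # z index 4 -> 0-based 3 -> 30 nm at 10 nm voxels
  az <- array(FALSE, dim = c(7, 5, 5))
  az[1, , ] <- TRUE
  t3 <- vesicle_morphometrics(label_volume(lab3), az, c(10, 10, 10))
  expect_equal(t3$dist_active_zone_nm, 30)
  expect_true(is.na(t3$nn_center_distance_nm))

  # invariance to label permutation and rigid translation
  perm <- lab
  perm[lab == 1L] <- 2L
  perm[lab == 2L] <- 1L
  tp <- vesicle_morphometrics(label_volume(perm), NULL, c(5, 5, 5))
  expect_equal(sort(tp$nn_center_distance_nm), sort(t2$nn_center_distance_nm),
               tolerance = 1e-9)
  shifted <- array(0L, dim = c(5, 7, 13))
  shifted[2 + 1, 2 + 2, 1 + 1] <- 1L
  shifted[2 + 1, 2 + 2, 11 + 1] <- 2L
  ts <- vesicle_morphometrics(label_volume(shifted), NULL, c(5, 5, 5))
  expect_equal(ts$nn_center_distance_nm, t2$nn_center_distance_nm,
               tolerance = 1e-9)
})
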