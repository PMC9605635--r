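# 3D geometric metrics: volumes, triangulated-isosurface area, sphericity,
# maximum diameter, centroid, the peak-to-centroid distance family
# (SmCD, SpCD, MSR, nSpCD) and the spherical rim width.

#' Active, inner and total lesion volumes
#'
#' `active = N * Vv`, `inner = N' * Vv`, `total = (N + N') * Vv`, returned
#' in cubic millimetres (use [geom_features()] for clinical units).
#'
#' @param ls A `lesion_set`.
#' @param lesion_id Lesion label.
#' @return A list: `volume_active`, `volume_inner`, `volume_total` (mm^3).
#' @export
lesion_volumes <- function(ls, lesion_id) {
  stopifnot(inherits(ls, "lesion_set"),
            lesion_id >= 1, lesion_id <= length(ls$N))
  va <- ls$N[lesion_id] * ls$voxel_volume
  vi <- ls$N_inner[lesion_id] * ls$voxel_volume
  list(volume_active = va, volume_inner = vi, volume_total = va + vi)
}

# --- triangulated isosurface -------------------------------------------------

# Decomposition of the unit cube (corners in offset order below) into six
# tetrahedra sharing the main diagonal 1-8.
.cube_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                       c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
.cube_tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(3, 7, 8, 1),
                    c(7, 5, 8, 1), c(5, 6, 8, 1), c(6, 2, 8, 1))

# Total area (mm^2) of the level-`level` isosurface of scalar field `u`
# (3D array, voxel-centre samples on a grid with physical `spacing`),
# triangulated by marching tetrahedra. The field is zero-padded by one
# layer so surfaces touching the array edge close properly.
isosurface_area <- function(u, spacing, level = 0.5) {
  d0 <- dim(u)
  p <- array(0, d0 + 2L)
  p[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <- u
  d <- dim(p)
  nc <- d - 1L
  corner_vals <- lapply(seq_len(8L), function(m) {
    o <- .cube_offsets[m, ]
    as.vector(p[o[1] + seq_len(nc[1]), o[2] + seq_len(nc[2]),
                o[3] + seq_len(nc[3])])
  })
  above <- lapply(corner_vals, function(v) v > level)
  keep <- which(Reduce(`|`, above) & !Reduce(`&`, above))
  if (!length(keep)) return(0)
  ijk <- arrayInd(keep, .dim = nc)
  base <- cbind((ijk[, 1] - 1) * spacing[1],
                (ijk[, 2] - 1) * spacing[2],
                (ijk[, 3] - 1) * spacing[3])
  vals <- lapply(corner_vals, function(v) v[keep])
  pos <- lapply(seq_len(8L), function(m) {
    sweep(base, 2L, .cube_offsets[m, ] * spacing, `+`)
  })
  interp <- function(i, j, sel) {
    vi <- vals[[i]][sel]; vj <- vals[[j]][sel]
    t <- (level - vi) / (vj - vi)
    pos[[i]][sel, , drop = FALSE] +
      t * (pos[[j]][sel, , drop = FALSE] - pos[[i]][sel, , drop = FALSE])
  }
  tri_area <- function(a, b, c) {
    u1 <- b - a; u2 <- c - a
    cx <- u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2]
    cy <- u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3]
    cz <- u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total <- 0
  for (tt in seq_len(nrow(.cube_tets))) {
    ci <- .cube_tets[tt, ]
    b <- vapply(ci, function(m) above[[m]][keep], logical(length(keep)))
    if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
    nab <- rowSums(b)
    for (target in c(1L, 3L)) {
      sel <- which(nab == target)
      if (!length(sel)) next
      bm <- b[sel, , drop = FALSE]
      lone <- if (target == 1L) bm else !bm
      sidx <- max.col(lone)
      for (s in 1:4) {
        ss <- sel[sidx == s]
        if (!length(ss)) next
        oth <- setdiff(1:4, s)
        total <- total + sum(tri_area(interp(ci[s], ci[oth[1]], ss),
                                      interp(ci[s], ci[oth[2]], ss),
                                      interp(ci[s], ci[oth[3]], ss)))
      }
    }
    sel <- which(nab == 2L)
    if (length(sel)) {
      bm <- b[sel, , drop = FALSE]
      for (pt in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
        ss <- sel[bm[, pt[1]] & bm[, pt[2]]]
        if (!length(ss)) next
        lo <- setdiff(1:4, pt)
        e1 <- interp(ci[pt[1]], ci[lo[1]], ss)
        e2 <- interp(ci[pt[1]], ci[lo[2]], ss)
        e3 <- interp(ci[pt[2]], ci[lo[2]], ss)
        e4 <- interp(ci[pt[2]], ci[lo[1]], ss)
        total <- total + sum(tri_area(e1, e2, e3)) + sum(tri_area(e1, e3, e4))
      }
    }
  }
  total
}

#' Surface area of a binary lesion mask
#'
#' Area of the triangulated isosurface of the filled lesion mask
#' (active plus inner voxels) at level 0.5, in square millimetres. The
#' binary mask is first smoothed with a 3x3x3 box filter so the extracted
#' level set tracks the underlying smooth boundary instead of the voxel
#' staircase; meshing the raw binary mask overestimates a sphere's area by
#' roughly 28%, the smoothed mesh is within 1% at 1 mm spacing.
#'
#' @param filled_mask Logical 3D array (active and inner voxels).
#' @param spacing Voxel spacing, mm.
#' @param smooth Apply the box pre-smoothing (default `TRUE`).
#' @return Surface area in mm^2.
#' @export
surface_area <- function(filled_mask, spacing, smooth = TRUE) {
  assert_mask(filled_mask, "filled_mask")
  if (!any(filled_mask)) stop("empty mask", call. = FALSE)
  u <- array(as.numeric(filled_mask), dim(filled_mask))
  if (smooth) {
    sm <- mean_filter3(u)
    # lesions only a few voxels wide never reach 0.5 after smoothing;
    # fall back to meshing the raw mask so the area stays defined
    if (max(sm) > 0.5) u <- sm
  }
  isosurface_area(u, spacing, level = 0.5)
}

#' Sphericity of a lesion
#'
#' `Sg = pi^(1/3) * (6 V)^(2/3) / S` with total volume `V` and surface `S`
#' in consistent units: 1 for a perfect sphere, approaching 0 for very
#' irregular shapes.
#'
#' @param volume_total Total (filled) volume.
#' @param surface Surface area, same length unit.
#' @return Dimensionless sphericity.
#' @export
sphericity <- function(volume_total, surface) {
  if (any(volume_total <= 0) || any(surface <= 0)) {
    stop("volume and surface must be positive", call. = FALSE)
  }
  pi^(1 / 3) * (6 * volume_total)^(2 / 3) / surface
}

# Surface voxels: mask voxels with at least one face-adjacent background
# neighbour (array boundary counts as background).
surface_voxels <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  mask & !core
}

#' Maximum 3D diameter of a lesion
#'
#' Maximal Euclidean distance (mm) between the world coordinates of any two
#' surface voxel centres of the filled mask. Computed exactly by a chunked
#' scan over surface-voxel pairs. A single-voxel mask has diameter 0.
#'
#' @inheritParams surface_area
#' @param origin World position of the first voxel centre, mm.
#' @return Maximum diameter in mm.
#' @export
max_diameter <- function(filled_mask, spacing, origin = c(0, 0, 0)) {
  assert_mask(filled_mask, "filled_mask")
  idx <- which(surface_voxels(filled_mask))
  if (!length(idx)) stop("empty mask", call. = FALSE)
  if (length(idx) == 1L) return(0)
  pts <- world_coords(arrayInd(idx, dim(filled_mask)), spacing, origin)
  n <- nrow(pts)
  best <- 0
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(pts[rows, 1], pts[, 1], `-`)^2 +
      outer(pts[rows, 2], pts[, 2], `-`)^2 +
      outer(pts[rows, 3], pts[, 3], `-`)^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

#' Geometric centroid of the active lesion voxels
#'
#' Unweighted mean of the world coordinates of the N active (segmented)
#' voxel centres, per axis; necrotic voxels are excluded.
#'
#' @param active_mask Logical 3D array of active voxels.
#' @param spacing Voxel spacing, mm.
#' @param origin World position of the first voxel centre, mm.
#' @return World coordinate (mm) of the centroid, length 3.
#' @export
lesion_centroid <- function(active_mask, spacing, origin = c(0, 0, 0)) {
  assert_mask(active_mask, "active_mask")
  idx <- which(active_mask)
  if (!length(idx)) stop("empty active mask", call. = FALSE)
  colMeans(world_coords(arrayInd(idx, dim(active_mask)), spacing, origin))
}

#' SUVmax- and SUVpeak-to-centroid distances
#'
#' `SmCD` is the Euclidean distance from the SUVmax voxel centre to the
#' lesion centroid; `SpCD` the distance from the SUVpeak cube centre to the
#' centroid, both in millimetres and in the same world frame.
#'
#' @param centroid,suv_max_location,suv_peak_location World mm coordinates.
#' @return A list: `smcd`, `spcd` (mm).
#' @export
centroid_distances <- function(centroid, suv_max_location,
                               suv_peak_location) {
  stopifnot(length(centroid) == 3, length(suv_max_location) == 3,
            length(suv_peak_location) == 3)
  list(smcd = sqrt(sum((suv_max_location - centroid)^2)),
       spcd = sqrt(sum((suv_peak_location - centroid)^2)))
}

#' Mean spherical radius and normalized peak-to-centroid distance
#'
#' `MSR = (3 V / (4 pi))^(1/3)` is the radius of the sphere with the
#' lesion's total (filled) volume; `nSpCD = SpCD / MSR` is the
#' size-normalized peak-to-centroid distance: values near 0 put the SUVpeak
#' at the lesion centre, values near 1 at the boundary. Lesions with
#' `nSpCD >= cut` (default 0.66, a cohort mean that new datasets should
#' recompute) are classed peripheral, otherwise central.
#'
#' @param spcd SUVpeak-to-centroid distance, mm.
#' @param volume_total Total lesion volume, mm^3.
#' @param cut Peripheral/central classification cut on nSpCD.
#' @return A list: `msr` (mm), `nspcd`, `nspcd_class`.
#' @export
normalized_scd <- function(spcd, volume_total, cut = 0.66) {
  if (volume_total <= 0) stop("volume_total must be positive", call. = FALSE)
  stopifnot(spcd >= 0)
  msr <- (3 * volume_total / (4 * pi))^(1 / 3)
  nspcd <- spcd / msr
  list(msr = msr, nspcd = nspcd,
       nspcd_class = if (nspcd >= cut) "peripheral" else "central")
}

#' Spherical rim width
#'
#' Spherical approximation of the average thickness of the enhancing rim:
#' the difference between the equivalent spherical radii of the total and
#' inner volumes, `(3 V_total / 4 pi)^(1/3) - (3 V_inner / 4 pi)^(1/3)`.
#' With no inner volume this equals the mean spherical radius.
#'
#' @param volume_total Total (filled) volume, mm^3.
#' @param volume_inner Inner (necrotic/non-enhancing) volume, mm^3.
#' @return Rim width in mm.
#' @export
rim_width <- function(volume_total, volume_inner) {
  if (volume_inner > volume_total) {
    stop("volume_inner cannot exceed volume_total", call. = FALSE)
  }
  stopifnot(volume_inner >= 0)
  (3 * volume_total / (4 * pi))^(1 / 3) -
    (3 * volume_inner / (4 * pi))^(1 / 3)
}

#' All geometric features of one lesion
#'
#' Combines volumes, surface, sphericity, maximum diameter, centroid and
#' the centroid-distance family into a one-row tibble, converted to the
#' conventional clinical reporting units (volumes mL, surface cm^2,
#' diameters and rim width cm, distances mm). For PET volumes the SUVmax
#' and SUVpeak locations are found on the grid; for MRI, SmCD/SpCD/nSpCD
#' are not defined and returned as `NA`.
#'
#' @param grid A [voxel_grid].
#' @param ls A `lesion_set` from [segment_threshold()].
#' @param lesion_id Lesion label; default the measurement (largest) lesion.
#' @param nspcd_cut Peripheral/central cut on nSpCD, default 0.66.
#' @return A one-row tibble of geometric features.
#' @export
geom_features <- function(grid, ls, lesion_id = NULL, nspcd_cut = 0.66) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(ls, "lesion_set"))
  lesion_id <- lesion_id %||% select_measurement_lesion(ls)
  mk <- lesion_masks(ls, lesion_id)
  vol <- lesion_volumes(ls, lesion_id)
  surf <- surface_area(mk$filled, ls$spacing)
  sph <- sphericity(vol$volume_total, surf)
  maxd <- max_diameter(mk$filled, ls$spacing, ls$origin)
  ctr <- lesion_centroid(mk$active, ls$spacing, ls$origin)
  rimw <- rim_width(vol$volume_total, vol$volume_inner)

  if (grid$modality == "PET") {
    st <- suv_statistics(grid, mk$active)
    pk <- suv_peak(grid, mk$active)
    cd <- centroid_distances(ctr, st$suv_max_location, pk$suv_peak_location)
    ns <- normalized_scd(cd$spcd, vol$volume_total, cut = nspcd_cut)
    smcd <- cd$smcd; spcd <- cd$spcd
    msr <- ns$msr; nspcd <- ns$nspcd; nspcd_class <- ns$nspcd_class
  } else {
    msr <- (3 * vol$volume_total / (4 * pi))^(1 / 3)
    smcd <- NA_real_; spcd <- NA_real_
    nspcd <- NA_real_; nspcd_class <- NA_character_
  }

  tibble::tibble(
    lesion = as.integer(lesion_id),
    volume_active_ml = mm3_to_ml(vol$volume_active),
    volume_inner_ml = mm3_to_ml(vol$volume_inner),
    volume_total_ml = mm3_to_ml(vol$volume_total),
    surface_cm2 = mm2_to_cm2(surf),
    sphericity = sph,
    max_diameter_cm = mm_to_cm(maxd),
    rim_width_cm = mm_to_cm(rimw),
    centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
    msr_mm = msr, smcd_mm = smcd, spcd_mm = spcd,
    nspcd = nspcd, nspcd_class = nspcd_class
  )
}

#' Combined PET and geometric features of one lesion
#'
#' @inheritParams geom_features
#' @param cov_cut Heterogeneity cut on COV, default 0.30.
#' @return A one-row tibble joining [pet_features()] and [geom_features()]
#'   (PET), or the geometric block alone (MRI).
#' @export
extract_lesion_features <- function(grid, ls, lesion_id = NULL,
                                    cov_cut = 0.30, nspcd_cut = 0.66) {
  lesion_id <- lesion_id %||% select_measurement_lesion(ls)
  geo <- geom_features(grid, ls, lesion_id, nspcd_cut = nspcd_cut)
  if (grid$modality == "PET") {
    pet <- pet_features(grid, ls, lesion_id, cov_cut = cov_cut)
    dplyr::bind_cols(pet, geo[setdiff(names(geo), "lesion")])
  } else {
    geo
  }
}
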