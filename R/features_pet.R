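# SUV-based intensity metrics on the measurement lesion: SUVmax, SUVmean,
# population SD, SUVpeak (3x3x3 neighbourhood average), MTV, TLA, COV.

# 3x3x3 uniform mean filter (weights 1/27) with zero padding at the image
# border, applied to the whole grid: neighbours outside the segmentation but
# inside the image contribute to the average.
mean_filter3 <- function(a) {
  d <- dim(a)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  out <- array(0, d)
  for (di in 0:2) for (dj in 0:2) for (dk in 0:2) {
    out <- out + padded[di + seq_len(d[1]), dj + seq_len(d[2]),
                        dk + seq_len(d[3])]
  }
  out / 27
}

#' SUV statistics over the active lesion voxels
#'
#' Maximum, mean and standard deviation of the SUV over the active
#' (metabolically active, non-necrotic) voxels, plus the world coordinate of
#' the SUVmax voxel centre. The standard deviation uses the population
#' convention (divide by N): COV is a descriptor of the voxel intensity
#' distribution, not an estimate from a sample. Arg-max ties break to the
#' first voxel in array (column-major) order.
#'
#' @param grid A [voxel_grid].
#' @param active_mask Logical 3D array of active lesion voxels.
#' @return A list: `suv_max`, `suv_mean`, `sd`, `suv_max_location` (mm).
#' @export
suv_statistics <- function(grid, active_mask) {
  stopifnot(inherits(grid, "voxel_grid"))
  assert_mask(active_mask, "active_mask")
  idx <- which(active_mask)
  if (!length(idx)) stop("empty active mask", call. = FALSE)
  v <- grid$values[idx]
  m <- mean(v)
  sd_pop <- sqrt(mean((v - m)^2))
  at <- idx[which.max(v)]
  loc <- drop(world_coords(arrayInd(at, dim(grid$values)),
                           grid$spacing, grid$origin))
  list(suv_max = max(v), suv_mean = m, sd = sd_pop, suv_max_location = loc)
}

#' SUVpeak: maximum of the 27-voxel neighbourhood average
#'
#' Every voxel's SUV is averaged with its 26 neighbours (3x3x3 kernel, all
#' weights 1/27, defined on voxel indices) over the whole grid with zero
#' padding at the image border; SUVpeak is the maximum of this filtered
#' field over the lesion voxels, and its location — the cube centre used for
#' the SUVpeak calculation — is the reference point for SpCD.
#'
#' @inheritParams suv_statistics
#' @return A list: `suv_peak`, `suv_peak_location` (world mm of the arg-max
#'   of the filtered field over the mask; ties break to array order).
#' @export
suv_peak <- function(grid, active_mask) {
  stopifnot(inherits(grid, "voxel_grid"))
  assert_mask(active_mask, "active_mask")
  idx <- which(active_mask)
  if (!length(idx)) stop("empty active mask", call. = FALSE)
  f <- mean_filter3(grid$values)
  fi <- f[idx]
  at <- idx[which.max(fi)]
  loc <- drop(world_coords(arrayInd(at, dim(grid$values)),
                           grid$spacing, grid$origin))
  list(suv_peak = max(fi), suv_peak_location = loc)
}

#' Coefficient of variation and heterogeneity class
#'
#' `COV = sigma_SUV / SUVmean` over the lesion voxels; lesions with
#' `COV >= cut` (default 0.30) are classified heterogeneous, below it
#' homogeneous.
#'
#' @param sd Population standard deviation of the lesion SUVs.
#' @param suv_mean Mean lesion SUV; must be positive.
#' @param cut Heterogeneity cut, default 0.30.
#' @return A list: `cov`, `heterogeneity` (`"homogeneous"`/`"heterogeneous"`).
#' @export
suv_cov <- function(sd, suv_mean, cut = 0.30) {
  if (!is.finite(suv_mean) || suv_mean <= 0) {
    stop("suv_mean must be positive to form a coefficient of variation",
         call. = FALSE)
  }
  stopifnot(sd >= 0)
  cv <- sd / suv_mean
  list(cov = cv,
       heterogeneity = if (cv >= cut) "heterogeneous" else "homogeneous")
}

#' Metabolic tumor volume and total lesion activity
#'
#' `MTV = N * Vv` (active voxels only) converted to millilitres;
#' `TLA = SUVmean * MTV`.
#'
#' @param ls A `lesion_set`.
#' @param lesion_id Lesion label.
#' @param suv_mean Mean SUV of the lesion's active voxels.
#' @return A list: `mtv` (mL), `tla` (SUV * mL).
#' @export
mtv_tla <- function(ls, lesion_id, suv_mean) {
  stopifnot(inherits(ls, "lesion_set"),
            lesion_id >= 1, lesion_id <= length(ls$N))
  mtv <- mm3_to_ml(ls$N[lesion_id] * ls$voxel_volume)
  list(mtv = mtv, tla = suv_mean * mtv)
}

#' All SUV-based features of one lesion
#'
#' Convenience wrapper combining [suv_statistics()], [suv_peak()],
#' [suv_cov()] and [mtv_tla()] into a one-row tibble.
#'
#' @param grid A [voxel_grid] (PET).
#' @param ls A `lesion_set` from [segment_threshold()].
#' @param lesion_id Lesion label; default the measurement (largest) lesion.
#' @param cov_cut Heterogeneity cut for COV, default 0.30.
#' @return A one-row tibble: `suv_max`, `suv_mean`, `suv_peak`, `mtv` (mL),
#'   `tla`, `cov`, `heterogeneity`, and the world coordinates of the SUVmax
#'   voxel and SUVpeak cube centre.
#' @export
pet_features <- function(grid, ls, lesion_id = NULL, cov_cut = 0.30) {
  stopifnot(inherits(ls, "lesion_set"))
  lesion_id <- lesion_id %||% select_measurement_lesion(ls)
  active <- ls$label_map == lesion_id
  st <- suv_statistics(grid, active)
  pk <- suv_peak(grid, active)
  cv <- suv_cov(st$sd, st$suv_mean, cut = cov_cut)
  mt <- mtv_tla(ls, lesion_id, st$suv_mean)
  tibble::tibble(
    lesion = as.integer(lesion_id),
    suv_max = st$suv_max, suv_mean = st$suv_mean, suv_sd = st$sd,
    suv_peak = pk$suv_peak,
    mtv_ml = mt$mtv, tla = mt$tla,
    cov = cv$cov, heterogeneity = cv$heterogeneity,
    suv_max_x = st$suv_max_location[1], suv_max_y = st$suv_max_location[2],
    suv_max_z = st$suv_max_location[3],
    suv_peak_x = pk$suv_peak_location[1], suv_peak_y = pk$suv_peak_location[2],
    suv_peak_z = pk$suv_peak_location[3]
  )
}
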