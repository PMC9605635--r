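#' Specify a synthetic lesion
#'
#' Describes one hypermetabolic (PET) or contrast-enhancing (MRI) lesion for
#' the phantom generator. A lesion is a radially perturbed sphere: the
#' surface radius along direction u is `base_radius * (1 + bumpiness * g(u))`
#' where `g` is a smooth band-limited angular function with `max |g| = 1`
#' drawn from the phantom seed. `bumpiness = 0` gives an exact discretised
#' sphere. An optional central necrotic core (low uptake / hypointense) and
#' an off-centre hotspot (Gaussian bump peaking at `hotspot_suv`, placed at
#' `hotspot_radial_fraction` of the base radius along a seeded random
#' direction) provide ground truth for the necrosis and nSpCD recovery
#' checks.
#'
#' @param center World position of the lesion centre, mm (length 3).
#' @param base_radius Base sphere radius, mm.
#' @param bumpiness Amplitude of the radial perturbation, dimensionless
#'   `>= 0`; fractional deviation from the base radius.
#' @param necrotic_core_radius Radius of the central low-uptake core, mm;
#'   `0` means none. Must be `< base_radius`.
#' @param hotspot_radial_fraction Radial position of the hotspot centre as a
#'   fraction of `base_radius`, in `[0, 1]`; this is the intended nSpCD
#'   ground truth.
#' @param hotspot_suv Peak intensity of the hotspot (the bump is added on
#'   top of `rim_suv` so the voxel at the hotspot centre reaches about this
#'   value). Set equal to `rim_suv` for no hotspot.
#' @param rim_suv Uptake of the metabolically active lesion tissue.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, base_radius, bumpiness = 0,
                        necrotic_core_radius = 0,
                        hotspot_radial_fraction = 0,
                        hotspot_suv = 3, rim_suv = 3) {
  stopifnot(length(center) == 3, base_radius > 0, bumpiness >= 0)
  if (necrotic_core_radius >= base_radius) {
    stop("necrotic_core_radius must be smaller than base_radius", call. = FALSE)
  }
  if (hotspot_radial_fraction < 0 || hotspot_radial_fraction > 1) {
    stop("hotspot_radial_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(center = as.numeric(center), base_radius = base_radius,
                 bumpiness = bumpiness,
                 necrotic_core_radius = necrotic_core_radius,
                 hotspot_radial_fraction = hotspot_radial_fraction,
                 hotspot_suv = hotspot_suv, rim_suv = rim_suv),
            class = "lesion_spec")
}

#' Specify a synthetic volume phantom
#'
#' @param grid_shape Voxel counts per axis (length 3).
#' @param spacing Voxel size per axis, mm.
#' @param lesions List of [lesion_spec()] objects.
#' @param background_suv Background uptake level (`>= 0`).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   intensities, truncated at 0 (`>= 0`).
#' @param seed Integer seed; fully determines the phantom.
#' @param modality `"PET"` or `"MRI"`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         lesions, background_suv = 0.3, noise_sd = 0,
                         seed = 1L, modality = c("PET", "MRI")) {
  modality <- match.arg(modality)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(spacing) == 3, all(spacing > 0),
            background_suv >= 0, noise_sd >= 0)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  stopifnot(length(lesions) >= 1,
            all(vapply(lesions, inherits, logical(1), "lesion_spec")))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), lesions = lesions,
                 background_suv = background_suv, noise_sd = noise_sd,
                 seed = as.integer(seed), modality = modality),
            class = "phantom_spec")
}

# Band-limited random angular function on the unit sphere, normalised to
# max |g| ~ 1 (by sampling); smooth, so the perturbed radius is smooth.
random_angular_fn <- function(n_modes = 6L, wavenumber = 3) {
  dirs <- matrix(stats::rnorm(3L * n_modes), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coef <- stats::rnorm(n_modes)
  phase <- stats::runif(n_modes, 0, 2 * pi)
  raw <- function(u) {
    # u: n x 3 unit vectors
    s <- u %*% t(dirs) * wavenumber
    drop(cos(sweep(s, 2L, phase, `+`)) %*% coef)
  }
  probe <- matrix(stats::rnorm(3 * 2000), ncol = 3L)
  probe <- probe / sqrt(rowSums(probe^2))
  amp <- max(abs(raw(probe)))
  if (amp < 1e-12) amp <- 1
  function(u) raw(u) / amp
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic PET/MRI phantom with known ground truth
#'
#' Renders the lesions of a [phantom_spec()] onto a background volume and
#' returns both the [voxel_grid] and a ground-truth record: analytic lesion
#' volume (`(4/3) pi r^3` when `bumpiness = 0`, voxel-counted otherwise),
#' true centre, true hotspot world position, necrotic core volume and lesion
#' count. Deterministic for a fixed seed. Lesions must fit inside the grid
#' with at least a 2-voxel margin.
#'
#' The hotspot is an isotropic Gaussian bump (sigma = 2 voxels) added to the
#' rim uptake inside the active lesion tissue only, so segmentation ground
#' truth is unchanged by the hotspot.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `grid` (a [voxel_grid]) and `truth` (a
#'   tibble with one row per lesion) plus `lesion_count`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  d <- spec$grid_shape
  h <- spec$spacing
  extent <- (d - 1) * h
  vals <- array(spec$background_suv, d)
  axes <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * h[a])

  truth <- vector("list", length(spec$lesions))
  for (li in seq_along(spec$lesions)) {
    ls <- spec$lesions[[li]]
    rmax <- ls$base_radius * (1 + ls$bumpiness)
    lo <- ls$center - rmax
    hi <- ls$center + rmax
    if (any(lo < 2 * h) || any(hi > extent - 2 * h)) {
      stop("lesion ", li, " does not fit in the grid with a 2-voxel margin",
           call. = FALSE)
    }
    gfun <- random_angular_fn()
    hdir <- random_unit_vector()
    hotspot_pos <- ls$center +
      ls$hotspot_radial_fraction * ls$base_radius * hdir

    # bounding box in voxel indices
    bb_lo <- pmax(1L, floor(lo / h) + 1L)
    bb_hi <- pmin(d, ceiling(hi / h) + 1L)
    ii <- bb_lo[1]:bb_hi[1]; jj <- bb_lo[2]:bb_hi[2]; kk <- bb_lo[3]:bb_hi[3]
    gx <- axes[[1]][ii] - ls$center[1]
    gy <- axes[[2]][jj] - ls$center[2]
    gz <- axes[[3]][kk] - ls$center[3]
    nb <- c(length(ii), length(jj), length(kk))
    rel <- cbind(rep(gx, times = nb[2] * nb[3]),
                 rep(rep(gy, each = nb[1]), times = nb[3]),
                 rep(gz, each = nb[1] * nb[2]))
    dist <- sqrt(rowSums(rel^2))
    if (ls$bumpiness > 0) {
      u <- rel / pmax(dist, 1e-12)
      radius_u <- ls$base_radius * (1 + ls$bumpiness * gfun(u))
    } else {
      radius_u <- ls$base_radius
    }
    inside <- dist <= radius_u
    core <- if (ls$necrotic_core_radius > 0) {
      inside & dist <= ls$necrotic_core_radius
    } else {
      rep(FALSE, length(dist))
    }
    active <- inside & !core

    sub <- vals[ii, jj, kk]
    sub_v <- as.vector(sub)
    sub_v[active] <- ls$rim_suv
    # necrotic core stays at background level (low uptake / hypointense)
    if (ls$hotspot_suv > ls$rim_suv && any(active)) {
      sigma <- 2 * min(h)
      hd2 <- rowSums(sweep(rel, 2L, hotspot_pos - ls$center, `-`)^2)
      bump <- (ls$hotspot_suv - ls$rim_suv) * exp(-hd2 / (2 * sigma^2))
      sub_v[active] <- sub_v[active] + bump[active]
    }
    vals[ii, jj, kk] <- array(sub_v, nb)

    vol_true <- if (ls$bumpiness == 0) {
      4 / 3 * pi * ls$base_radius^3
    } else {
      sum(inside) * prod(h)
    }
    truth[[li]] <- tibble::tibble(
      lesion = li,
      true_volume_mm3 = vol_true,
      core_volume_mm3 = if (ls$necrotic_core_radius > 0)
        4 / 3 * pi * ls$necrotic_core_radius^3 else 0,
      center_x = ls$center[1], center_y = ls$center[2], center_z = ls$center[3],
      hotspot_x = hotspot_pos[1], hotspot_y = hotspot_pos[2],
      hotspot_z = hotspot_pos[3],
      hotspot_radial_fraction = ls$hotspot_radial_fraction,
      base_radius = ls$base_radius,
      bumpiness = ls$bumpiness
    )
  }

  if (spec$noise_sd > 0) {
    vals <- vals + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    vals[vals < 0] <- 0
  }

  list(grid = voxel_grid(vals, spacing = h, modality = spec$modality),
       truth = dplyr::bind_rows(truth),
       lesion_count = length(spec$lesions))
}

#' Generate a two-lesion phantom bridged by faint background uptake
#'
#' Builds the phantom of `spec` (which must contain exactly two lesions) and
#' adds a thin corridor of intensity `bridge_suv` joining the two lesion
#' centres, emulating multiple hypermetabolic foci connected by a faint
#' increased metabolic background uptake. `bridge_suv` must lie strictly
#' between the background level and the lower rim uptake, so the foci are
#' separate at a high threshold but connected at a low one (the multifocal
#' signature); without the bridge two foci are multicentric.
#'
#' @param spec A [phantom_spec()] with exactly two lesions.
#' @param bridge_suv Corridor intensity; must satisfy
#'   `background_suv < bridge_suv < min(rim_suv)`.
#' @return Same structure as [make_phantom()].
#' @export
make_bridged_phantom <- function(spec, bridge_suv) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$lesions) != 2L) {
    stop("bridged phantom requires exactly two lesions", call. = FALSE)
  }
  rims <- vapply(spec$lesions, `[[`, numeric(1), "rim_suv")
  if (!(bridge_suv > spec$background_suv && bridge_suv < min(rims))) {
    stop("bridge_suv must lie strictly between background_suv and the ",
         "smallest rim_suv", call. = FALSE)
  }
  out <- make_phantom(spec)
  g <- out$grid
  d <- dim(g$values)
  h <- g$spacing
  a <- spec$lesions[[1]]$center
  b <- spec$lesions[[2]]$center
  axes <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * h[ax])
  # distance from each voxel centre to segment a-b, vectorised on the
  # bounding box of the segment padded by the corridor radius
  rad <- 1.5 * max(h)
  lo <- pmax(1L, floor((pmin(a, b) - rad) / h) + 1L)
  hi <- pmin(d, ceiling((pmax(a, b) + rad) / h) + 1L)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  nb <- c(length(ii), length(jj), length(kk))
  px <- rep(axes[[1]][ii], times = nb[2] * nb[3])
  py <- rep(rep(axes[[2]][jj], each = nb[1]), times = nb[3])
  pz <- rep(axes[[3]][kk], each = nb[1] * nb[2])
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- px - (a[1] + t * ab[1])
  dy <- py - (a[2] + t * ab[2])
  dz <- pz - (a[3] + t * ab[3])
  near <- sqrt(dx^2 + dy^2 + dz^2) <= rad
  sub <- g$values[ii, jj, kk]
  sub_v <- as.vector(sub)
  sub_v[near & sub_v < bridge_suv] <- bridge_suv
  g$values[ii, jj, kk] <- array(sub_v, nb)
  out$grid <- g
  out
}
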