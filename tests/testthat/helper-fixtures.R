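# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# Binary sphere indicator sampled on voxel centres; centre defaults to the
# grid middle (on the voxel lattice for even symmetry).
sphere_mask <- function(r, h, pad = 4, center = NULL) {
  n <- ceiling(2 * (r + pad) / h)
  x <- (0:(n - 1)) * h
  center <- center %||% rep((n - 1) / 2 * h, 3)
  dx2 <- outer((x - center[1])^2, (x - center[2])^2, `+`)
  arr <- array(FALSE, c(n, n, n))
  for (k in 1:n) arr[, , k] <- dx2 + (x[k] - center[3])^2 <= r^2
  arr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A uniform-uptake sphere phantom as a voxel_grid (no noise, no hotspot).
sphere_grid <- function(r = 10, h = 1, inside = 3, outside = 0.3,
                        core_r = 0, pad = 4, modality = "PET") {
  m <- sphere_mask(r, h, pad = pad)
  vals <- array(outside, dim(m))
  vals[m] <- inside
  if (core_r > 0) {
    core <- sphere_mask(core_r, h, pad = pad + (r - core_r) / 1)
    # rebuild with same grid dims
    n <- dim(m)[1]
    x <- (0:(n - 1)) * h
    ctr <- rep((n - 1) / 2 * h, 3)
    dx2 <- outer((x - ctr[1])^2, (x - ctr[2])^2, `+`)
    core <- array(FALSE, dim(m))
    for (k in 1:n) core[, , k] <- dx2 + (x[k] - ctr[3])^2 <= core_r^2
    vals[core] <- outside
  }
  voxel_grid(vals, spacing = rep(h, 3), modality = modality)
}

# Independent brute-force oracle for SUVpeak: triple-loop 27-neighbourhood
# average with zero padding, maximised over `mask` voxels.
brute_force_peak <- function(vals, mask = NULL) {
  d <- dim(vals)
  if (is.null(mask)) mask <- array(TRUE, d)
  best <- -Inf
  best_idx <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    s <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3]) {
        s <- s + vals[ii, jj, kk]
      }
    }
    if (s / 27 > best) {
      best <- s / 27
      best_idx <- c(i, j, k)
    }
  }
  list(peak = best, idx = best_idx)
}

# Independent AUC oracle: Mann-Whitney U / (n1 n2), higher value = positive.
mann_whitney_auc <- function(x_pos, x_neg) {
  cmp <- outer(x_pos, x_neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(x_pos) * length(x_neg))
}

# Minimal hand-built lesion_set for unit tests of selection logic.
fake_lesion_set <- function(N, N_inner = rep(0L, length(N)), vv = 1) {
  structure(list(label_map = NULL, inner_map = NULL,
                 N = as.integer(N), N_inner = as.integer(N_inner),
                 spacing = rep(vv^(1 / 3), 3), origin = c(0, 0, 0),
                 voxel_volume = vv, threshold = 1, modality = "PET",
                 classification = NA_character_),
            class = "lesion_set")
}

# Two-lesion phantom spec used by the multilesionality tests.
two_focus_spec <- function(seed, noise_sd = 0.02) {
  phantom_spec(
    grid_shape = c(64, 40, 40), spacing = c(1, 1, 1),
    lesions = list(
      lesion_spec(center = c(18, 20, 20), base_radius = 7,
                  rim_suv = 3, hotspot_suv = 3),
      lesion_spec(center = c(46, 20, 20), base_radius = 6,
                  rim_suv = 3, hotspot_suv = 3)),
    background_suv = 0.3, noise_sd = noise_sd, seed = seed)
}
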