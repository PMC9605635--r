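# Threshold-based semiautomatic segmentation: connected-component labelling
# (26-connectivity for lesions, 6-connectivity for hole filling), necrotic
# inner-region extraction, and multifocal/multicentric classification.

neighbor_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  storage.mode(offs) <- "integer"
  offs
}

# Label connected components of a logical 3D array. Frontier-vectorised BFS:
# each sweep expands the whole frontier by all offsets at once.
label_components <- function(mask, connectivity = 26L) {
  assert_mask(mask)
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  visited <- array(FALSE, d)
  lab <- 0L
  ptr <- 1L
  nfg <- length(fg)
  while (ptr <= nfg) {
    s <- fg[ptr]
    ptr <- ptr + 1L
    if (visited[s]) next
    lab <- lab + 1L
    visited[s] <- TRUE
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      ijk <- arrayInd(frontier, d)
      cand <- vector("list", nrow(offs))
      for (r in seq_len(nrow(offs))) {
        ni <- ijk[, 1L] + offs[r, 1L]
        nj <- ijk[, 2L] + offs[r, 2L]
        nk <- ijk[, 3L] + offs[r, 3L]
        ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
          nk >= 1L & nk <= d[3L]
        if (!any(ok)) next
        cand[[r]] <- ni[ok] + (nj[ok] - 1L) * d[1L] +
          (nk[ok] - 1L) * d[1L] * d[2L]
      }
      nbrs <- unique(unlist(cand, use.names = FALSE))
      if (is.null(nbrs)) break
      nbrs <- nbrs[mask[nbrs] & !visited[nbrs]]
      if (!length(nbrs)) break
      visited[nbrs] <- TRUE
      labels[nbrs] <- lab
      frontier <- nbrs
    }
  }
  labels
}

# Fill interior holes of a logical 3D mask: flood the complement from the
# array border using 6-connectivity; anything unreachable is a hole.
fill_holes <- function(mask) {
  assert_mask(mask)
  d <- dim(mask)
  outside <- array(FALSE, d)
  border <- unique(c(
    which(slice.index(mask, 1L) %in% c(1L, d[1L])),
    which(slice.index(mask, 2L) %in% c(1L, d[2L])),
    which(slice.index(mask, 3L) %in% c(1L, d[3L]))
  ))
  seeds <- border[!mask[border]]
  if (!length(seeds)) return(array(TRUE, d))
  outside[seeds] <- TRUE
  offs <- neighbor_offsets(6L)
  frontier <- seeds
  while (length(frontier)) {
    ijk <- arrayInd(frontier, d)
    cand <- vector("list", nrow(offs))
    for (r in seq_len(nrow(offs))) {
      ni <- ijk[, 1L] + offs[r, 1L]
      nj <- ijk[, 2L] + offs[r, 2L]
      nk <- ijk[, 3L] + offs[r, 3L]
      ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
        nk >= 1L & nk <= d[3L]
      if (!any(ok)) next
      cand[[r]] <- ni[ok] + (nj[ok] - 1L) * d[1L] +
        (nk[ok] - 1L) * d[1L] * d[2L]
    }
    nbrs <- unique(unlist(cand, use.names = FALSE))
    if (is.null(nbrs)) break
    nbrs <- nbrs[!mask[nbrs] & !outside[nbrs]]
    if (!length(nbrs)) break
    outside[nbrs] <- TRUE
    frontier <- nbrs
  }
  mask | !outside
}

resolve_threshold <- function(grid, rule) {
  vals <- grid$values
  if (!is.list(rule) || length(rule) != 1L ||
      !names(rule) %in% c("absolute", "fraction_of_max")) {
    stop("`rule` must be list(absolute = ) or list(fraction_of_max = )",
         call. = FALSE)
  }
  thr <- if (names(rule) == "absolute") {
    rule$absolute
  } else {
    stopifnot(rule$fraction_of_max > 0, rule$fraction_of_max <= 1)
    rule$fraction_of_max * max(vals)
  }
  if (thr > max(vals)) {
    stop("no lesion above threshold: threshold ", signif(thr, 4),
         " exceeds the volume maximum ", signif(max(vals), 4), call. = FALSE)
  }
  if (thr < min(vals)) {
    stop("threshold ", signif(thr, 4), " is below the volume minimum; ",
         "the whole volume would be foreground", call. = FALSE)
  }
  thr
}

#' Threshold-based lesion segmentation
#'
#' Segments a volume into lesions: voxels at or above the threshold form the
#' foreground, which is split into 26-connected components; components
#' smaller than `min_voxels` are discarded. Each lesion's interior holes
#' (enclosed sub-threshold voxels, 6-connectivity hole filling) form its
#' inner (necrotic) mask — hypointense/low-uptake regions fully inside the
#' lesion. Labels are assigned in decreasing order of active voxel count, so
#' label 1 is the largest component.
#'
#' @param grid A [voxel_grid].
#' @param rule Threshold rule: `list(absolute = s)` for an absolute
#'   intensity threshold, or `list(fraction_of_max = f)` for a fraction of
#'   the volume maximum (PET default practice: `f = 0.40`).
#' @param min_voxels Minimum component size retained (default 10).
#' @return A `lesion_set`: label maps for active and inner voxels, per-lesion
#'   counts `N` and `N_inner`, voxel volume, threshold used, and modality.
#' @export
segment_threshold <- function(grid, rule = list(fraction_of_max = 0.40),
                              min_voxels = 10L) {
  stopifnot(inherits(grid, "voxel_grid"))
  thr <- resolve_threshold(grid, rule)
  fg <- grid$values >= thr
  labels <- label_components(fg, connectivity = 26L)
  nlab <- max(labels)
  if (nlab == 0L) stop("no lesion above threshold", call. = FALSE)
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) {
    stop("no lesion above threshold after the min_voxels filter", call. = FALSE)
  }
  # relabel by decreasing size; ties keep original discovery order
  keep <- keep[order(-sizes[keep], keep)]
  d <- dim(grid$values)
  label_map <- array(0L, d)
  inner_map <- array(0L, d)
  N <- integer(length(keep))
  N_inner <- integer(length(keep))
  for (new_id in seq_along(keep)) {
    comp <- labels == keep[new_id]
    label_map[comp] <- new_id
    # hole filling on the padded bounding box only
    idx <- which(comp)
    ijk <- arrayInd(idx, d)
    lo <- pmax(1L, apply(ijk, 2L, min) - 1L)
    hi <- pmin(d, apply(ijk, 2L, max) + 1L)
    sub <- comp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    filled <- fill_holes(sub)
    inner <- filled & !sub
    if (any(inner)) {
      inner_full <- array(FALSE, d)
      inner_full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inner
      inner_map[inner_full] <- new_id
    }
    N[new_id] <- sum(comp)
    N_inner[new_id] <- sum(inner)
  }
  structure(
    list(label_map = label_map, inner_map = inner_map,
         N = N, N_inner = N_inner,
         spacing = grid$spacing, origin = grid$origin,
         voxel_volume = prod(grid$spacing),
         threshold = thr, modality = grid$modality,
         classification = if (length(keep) == 1L) "unifocal" else NA_character_),
    class = "lesion_set"
  )
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set %s> %d lesion(s), threshold %.4g\n",
              x$modality, length(x$N), x$threshold))
  print(tidy.lesion_set(x))
  invisible(x)
}

#' Tidy a lesion set into a per-lesion tibble
#'
#' @param x A `lesion_set`.
#' @param ... Unused.
#' @return A tibble with one row per lesion: voxel counts and volumes (mL).
#' @export
tidy.lesion_set <- function(x, ...) {
  tibble::tibble(
    lesion = seq_along(x$N),
    n_active = x$N,
    n_inner = x$N_inner,
    volume_active_ml = mm3_to_ml(x$N * x$voxel_volume),
    volume_inner_ml = mm3_to_ml(x$N_inner * x$voxel_volume),
    volume_total_ml = mm3_to_ml((x$N + x$N_inner) * x$voxel_volume)
  )
}

#' @export
glance.lesion_set <- function(x, ...) {
  tibble::tibble(
    n_lesions = length(x$N),
    classification = x$classification,
    threshold = x$threshold,
    largest_lesion = select_measurement_lesion(x),
    total_volume_ml = mm3_to_ml(sum(x$N + x$N_inner) * x$voxel_volume)
  )
}

lesion_masks <- function(ls, id) {
  list(active = ls$label_map == id,
       inner = ls$inner_map == id,
       filled = ls$label_map == id | ls$inner_map == id)
}

#' Select the measurement lesion (largest filled volume)
#'
#' With multiple lesions, all per-lesion measures are computed on the
#' largest one: the lesion maximising the filled volume
#' `(N + N_inner) * Vv`. Exact ties break to the lowest label.
#'
#' @param ls A `lesion_set`.
#' @return Integer lesion id.
#' @export
select_measurement_lesion <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  if (!length(ls$N)) stop("empty lesion set", call. = FALSE)
  vol <- (ls$N + ls$N_inner) * ls$voxel_volume
  which.max(vol) # first maximum = lowest label on ties
}

# Default "faint elevated background" threshold: mean + 2 SD of the border
# shell (outermost voxel layer), an operational stand-in for visually faint
# uptake above background.
default_low_threshold <- function(grid, shell = 1L) {
  d <- dim(grid$values)
  m <- array(FALSE, d)
  m[c(seq_len(shell), d[1L] - seq_len(shell) + 1L), , ] <- TRUE
  m[, c(seq_len(shell), d[2L] - seq_len(shell) + 1L), ] <- TRUE
  m[, , c(seq_len(shell), d[3L] - seq_len(shell) + 1L)] <- TRUE
  vals <- grid$values[m]
  mean(vals) + 2 * stats::sd(vals)
}

#' Classify unifocal / multifocal / multicentric disease
#'
#' Foci are the 26-connected components at the high threshold. One focus is
#' unifocal disease. With two or more foci, the volume is re-thresholded at
#' a low ("faint background uptake") level: if any two foci fall in a common
#' low-threshold component they are connected by faint uptake and the tumor
#' is multifocal; otherwise multicentric. Both multifocal and multicentric
#' map to `multilesional = TRUE` for statistics.
#'
#' @param grid A [voxel_grid].
#' @param high_rule Threshold rule for foci (see [segment_threshold()]).
#' @param low_rule Threshold rule for the faint-bridge test, or `NULL` to
#'   use the border-shell estimate mean + 2 SD of the background.
#' @param min_voxels Minimum focus size at the high threshold.
#' @return A one-row tibble: `classification` (`"unifocal"`, `"multifocal"`
#'   or `"multicentric"`), `multilesional` (logical), `n_foci`, and the two
#'   thresholds used.
#' @export
classify_multilesionality <- function(grid,
                                      high_rule = list(fraction_of_max = 0.40),
                                      low_rule = NULL,
                                      min_voxels = 10L) {
  stopifnot(inherits(grid, "voxel_grid"))
  high <- segment_threshold(grid, high_rule, min_voxels = min_voxels)
  n_foci <- length(high$N)
  low_thr <- if (is.null(low_rule)) {
    default_low_threshold(grid)
  } else {
    resolve_threshold(grid, low_rule)
  }
  if (low_thr >= high$threshold) {
    stop("low threshold (", signif(low_thr, 4),
         ") must lie below the high threshold (", signif(high$threshold, 4),
         ")", call. = FALSE)
  }
  if (n_foci == 1L) {
    cls <- "unifocal"
  } else {
    low_labels <- label_components(grid$values >= low_thr, connectivity = 26L)
    # each high focus inherits the low-threshold component of its voxels
    focus_low <- vapply(seq_len(n_foci), function(id) {
      low_labels[which(high$label_map == id)[1L]]
    }, integer(1))
    cls <- if (anyDuplicated(focus_low)) "multifocal" else "multicentric"
  }
  tibble::tibble(
    classification = cls,
    multilesional = cls != "unifocal",
    n_foci = n_foci,
    high_threshold = high$threshold,
    low_threshold = low_thr
  )
}
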