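# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal by inversion; vectorised, deterministic under set.seed().
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Unit conversions: everything internal is mm / mm^2 / mm^3; reporting uses
# the conventional clinical units (cm, cm^2, mL).
mm3_to_ml <- function(x) x / 1000
mm2_to_cm2 <- function(x) x / 100
mm_to_cm <- function(x) x / 10

assert_mask <- function(mask, what = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop(what, " must be a 3D array", call. = FALSE)
  }
  invisible(mask)
}

# Linear index <-> (i,j,k) helpers on a 3D array of dim d (1-based).
lin_index <- function(ijk, d) {
  ijk[, 1L] + (ijk[, 2L] - 1L) * d[1L] + (ijk[, 3L] - 1L) * d[1L] * d[2L]
}
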