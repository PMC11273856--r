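#' @keywords internal
#' @useDynLib choromet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic generators in the package
# go through this so that (config, seed) fully determines their output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear interpolation of a matrix at fractional indices
#'
#' Interpolates `m[i, j]` at fractional 1-based positions, clamping queries to
#' the matrix borders (nearest-edge extrapolation).
#'
#' @param m numeric matrix.
#' @param i,j numeric vectors of fractional row/column positions (1-based).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_interp <- function(m, i, j) {
  nr <- nrow(m); nc <- ncol(m)
  i <- clamp(i, 1, nr); j <- clamp(j, 1, nc)
  i0 <- clamp(floor(i), 1, nr - 1L); j0 <- clamp(floor(j), 1, nc - 1L)
  if (nr == 1L) i0 <- rep(1L, length(i))
  if (nc == 1L) j0 <- rep(1L, length(j))
  fi <- i - i0; fj <- j - j0
  i1 <- pmin(i0 + 1, nr); j1 <- pmin(j0 + 1, nc)
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j1)] * (1 - fi) * fj +
    m[cbind(i1, j1)] * fi * fj
}

# Trilinear interpolation of a 3D array at fractional 1-based positions.
# Out-of-bounds queries return `fill`.
trilinear_interp <- function(arr, x, y, z, fill = NA_real_) {
  d <- dim(arr)
  inb <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(inb)) return(out)
  x <- x[inb]; y <- y[inb]; z <- z[inb]
  x0 <- clamp(floor(x), 1, d[1] - 1L)
  y0 <- clamp(floor(y), 1, d[2] - 1L)
  z0 <- clamp(floor(z), 1, d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1L, length(x))
  if (d[2] == 1L) y0 <- rep(1L, length(y))
  if (d[3] == 1L) z0 <- rep(1L, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  # linear index helper (1-based)
  lin <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  v <- arr[lin(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    arr[lin(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    arr[lin(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    arr[lin(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    arr[lin(x1, y1, z0)] * fx * fy * (1 - fz) +
    arr[lin(x1, y0, z1)] * fx * (1 - fy) * fz +
    arr[lin(x0, y1, z1)] * (1 - fx) * fy * fz +
    arr[lin(x1, y1, z1)] * fx * fy * fz
  out[inb] <- v
  out
}

# Smooth a matrix with a small separable moving-average kernel (width must be
# odd); borders handled by edge replication. Used for texture fields and for
# pre-smoothing gradient images.
smooth_matrix <- function(m, width = 3L) {
  stopifnot(width %% 2L == 1L)
  if (width == 1L) return(m)
  box_smooth_cpp(m, as.integer(width), as.integer(width))
}

# Horizontal-only (across columns) moving average, edge-replicated.
hsmooth <- function(m, width = 5L) {
  stopifnot(width %% 2L == 1L)
  if (width == 1L) return(m)
  box_smooth_cpp(m, 1L, as.integer(width))
}

# Vertical-only (down columns) moving average, edge-replicated.
vsmooth <- function(m, width = 3L) {
  stopifnot(width %% 2L == 1L)
  if (width == 1L) return(m)
  box_smooth_cpp(m, as.integer(width), 1L)
}
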