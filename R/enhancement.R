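#' Perona-Malik anisotropic diffusion of a B-scan
#'
#' Classic edge-preserving denoising: explicit 4-neighbour diffusion with
#' conduction `c(g) = exp(-(g / kappa)^2)` and reflective borders. With
#' `lambda <= 0.25` the scheme obeys the discrete maximum principle, and the
#' symmetric edge fluxes make it conservative, so the image mean is
#' preserved to rounding error.
#'
#' @param img numeric matrix `[depth x n_ascans]` (or any 2D image).
#' @param n_iter number of explicit steps (>= 0).
#' @param kappa gradient scale of the conduction function (> 0), in
#'   intensity units.
#' @param lambda step size in `(0, 0.25]`.
#' @return the diffused matrix.
#' @export
anisotropic_diffusion <- function(img, n_iter = 20L, kappa = 0.07, lambda = 0.2) {
  stopifnot(is.matrix(img), n_iter >= 0, kappa > 0, lambda > 0, lambda <= 0.25)
  if (n_iter == 0L) return(img)
  pm_diffusion_cpp(img, as.integer(n_iter), kappa, lambda)
}

#' Adaptive attenuation compensation of a B-scan
#'
#' Column-wise compensation of depth-dependent signal loss: for each A-scan
#' the compensated value at depth `z` is
#' `I(z)^n / (2 * sum_{z' >= z} I(z')^n)`; with `take_root` a final `1/n`
#' power restores the intensity scale (contrast exponent `n >= 1`). The
#' deepest non-zero sample of any column maps to 0.5 (before the root);
#' all-zero columns map to zero.
#'
#' @param img numeric matrix `[depth x n_ascans]`, non-negative.
#' @param n contrast exponent (>= 1).
#' @param take_root apply the final `1/n` root.
#' @return the compensated matrix.
#' @export
adaptive_compensation <- function(img, n = 2, take_root = TRUE) {
  stopifnot(is.matrix(img), n >= 1)
  if (any(img < 0)) stop("adaptive compensation requires non-negative intensities")
  nr <- nrow(img)
  En <- img^n
  # suffix sums down each column: sum_{z' >= z} I(z')^n
  suf <- apply(En[nr:1, , drop = FALSE], 2, cumsum)[nr:1, , drop = FALSE]
  out <- En / (2 * suf)
  out[suf == 0] <- 0
  if (take_root) out <- out^(1 / n)
  out
}

#' Enhance a whole OCT volume
#'
#' Applies the per-B-scan enhancement chain in the fixed order denoising
#' (anisotropic diffusion) then adaptive compensation.
#'
#' @param volume an [oct_volume()].
#' @param n_iter,kappa,lambda diffusion parameters
#'   (see [anisotropic_diffusion()]).
#' @param n,take_root compensation parameters
#'   (see [adaptive_compensation()]).
#' @return an enhanced [oct_volume()].
#' @export
enhance_volume <- function(volume, n_iter = 20L, kappa = 0.07, lambda = 0.2,
                           n = 2, take_root = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  out <- volume
  for (b in seq_len(dim(volume$data)[3])) {
    img <- anisotropic_diffusion(volume$data[, , b], n_iter = n_iter,
                                 kappa = kappa, lambda = lambda)
    out$data[, , b] <- adaptive_compensation(img, n = n, take_root = take_root)
  }
  out
}
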