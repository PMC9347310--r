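#' Generate a pair of mean-fluorescence field-of-view images
#'
#' Places `n_neurons` Gaussian cell bodies at non-overlapping positions in a
#' 256 x 256 field. The second image is the same layout translated by
#' `shift_px` with per-cell brightness and shape perturbations of relative
#' scale `morph_noise`; the true correspondence is the identity pairing.
#'
#' @param seed integer seed.
#' @param n_neurons number of cells; rejected if they cannot be placed
#'   without overlap.
#' @param shift_px integer translation `c(dy, dx)` applied to image B.
#' @param morph_noise relative SD of per-cell brightness/size perturbation
#'   in image B (0 = exact copy).
#' @param image_size field size in pixels (default 256).
#' @return list with `imageA`, `imageB` (matrices), `centers` (n x 2 matrix
#'   of day-1 centers, rows = (y, x)), and `correspondence` (identity
#'   integer vector).
#' @export
make_fov_pair <- function(seed = 1L, n_neurons = 30L, shift_px = c(0L, 0L),
                          morph_noise = 0, image_size = 256L) {
  stopifnot(n_neurons >= 1, length(shift_px) == 2, morph_noise >= 0)
  min_dist <- 16
  margin <- 24
  with_rng_seed(seed, {
    centers <- matrix(NA_real_, n_neurons, 2)
    placed <- 0L
    for (attempt in seq_len(20000L)) {
      cand <- runif(2, margin, image_size - margin)
      if (placed == 0 ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_dist) {
        placed <- placed + 1L
        centers[placed, ] <- cand
        if (placed == n_neurons) break
      }
    }
    if (placed < n_neurons)
      stop("field overcrowded: placed only ", placed, " of ", n_neurons,
           " cells without overlap")
    bright <- runif(n_neurons, 0.5, 1)
    sigma_y <- runif(n_neurons, 2.5, 4.5)
    sigma_x <- runif(n_neurons, 2.5, 4.5)
    theta <- runif(n_neurons, 0, pi)
    # smooth neuropil-like background texture, identical across days up to
    # the translation (it is what anchors patch identity in real data)
    texture <- smooth_texture(image_size)
    imageA <- 0.05 + 0.1 * texture +
      render_fov(centers, bright, sigma_y, sigma_x, theta, image_size)
    pert <- function(v) v * exp(rnorm(n_neurons, 0, morph_noise))
    centersB <- sweep(centers, 2, shift_px, "+")
    textureB <- circ_shift(texture, shift_px[1], shift_px[2])
    imageB <- 0.05 + 0.1 * textureB +
      render_fov(centersB, pert(bright), pert(sigma_y), pert(sigma_x),
                 theta + rnorm(n_neurons, 0, morph_noise), image_size)
  })
  list(imageA = imageA, imageB = imageB, centers = centers,
       correspondence = seq_len(n_neurons))
}

# Anisotropic Gaussian cell bodies with per-cell orientation.
render_fov <- function(centers, bright, sigma_y, sigma_x, theta, image_size) {
  img <- matrix(0, image_size, image_size)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    s <- max(sigma_y[i], sigma_x[i])
    r <- ceiling(3 * s)
    ys <- max(1, floor(cy - r)):min(image_size, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(image_size, ceiling(cx + r))
    if (!length(ys) || !length(xs)) next
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    u <- cos(theta[i]) * dy + sin(theta[i]) * dx
    v <- -sin(theta[i]) * dy + cos(theta[i]) * dx
    blob <- bright[i] *
      exp(-(u^2 / (2 * sigma_y[i]^2) + v^2 / (2 * sigma_x[i]^2)))
    img[ys, xs] <- img[ys, xs] + blob
  }
  img
}

# Low-pass-filtered white noise (unit SD), generated in the Fourier domain.
smooth_texture <- function(n, cutoff = 0.08) {
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) / n
  radial <- sqrt(outer(f^2, f^2, "+"))
  sp <- fft(matrix(rnorm(n * n), n)) * exp(-(radial / cutoff)^2)
  x <- Re(fft(sp, inverse = TRUE)) / (n * n)
  (x - mean(x)) / sd(x)
}

circ_shift <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(p) - 1 - dx) %% p) + 1]
}
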