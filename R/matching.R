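#' Rigid translation registration by cross-correlation
#'
#' Finds the integer shift `(dy, dx)` maximizing the circular
#' cross-correlation (computed in the Fourier domain) between two
#' equal-sized images, such that `B` approximately equals `A` translated by
#' `(dy, dx)`. Peaks past the half-size are wrapped to negative shifts.
#'
#' @param imageA,imageB numeric matrices of identical dimensions.
#' @return integer vector `c(dy, dx)`.
#' @export
register_translation <- function(imageA, imageB) {
  stopifnot(is.matrix(imageA), is.matrix(imageB),
            identical(dim(imageA), dim(imageB)))
  a <- imageA - mean(imageA)
  b <- imageB - mean(imageB)
  if (all(a == 0) || all(b == 0)) {
    warning("flat image: returning zero shift")
    return(c(dy = 0L, dx = 0L))
  }
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) { s <- i - 1L; if (s > n / 2) s - n else s }
  c(dy = wrap(peak[1], nrow(cc)), dx = wrap(peak[2], ncol(cc)))
}

#' Structural similarity (SSIM) between two image patches
#'
#' Standard structural similarity index: sliding Gaussian-weighted
#' (11 x 11, sigma 1.5) local means, variances and covariance combined into
#' the luminance-contrast-structure product with the default stabilizing
#' constants K1 = 0.01, K2 = 0.03, averaged over the valid region of the
#' SSIM map. Identical patches score exactly 1; a patch against its
#' negative scores below 0 through the structure term.
#'
#' @param patchA,patchB numeric matrices of identical size (at least the
#'   window size, default 11).
#' @param dynamic_range value range `L` of the data; defaults to the
#'   observed range across both patches.
#' @param window_size,sigma Gaussian window parameters.
#' @return scalar in \[-1, 1\].
#' @export
patch_similarity <- function(patchA, patchB, dynamic_range = NULL,
                             window_size = 11L, sigma = 1.5) {
  stopifnot(is.matrix(patchA), is.matrix(patchB),
            identical(dim(patchA), dim(patchB)))
  if (any(dim(patchA) < window_size))
    stop("patch smaller than SSIM window (", window_size, ")")
  L <- if (is.null(dynamic_range)) diff(range(c(patchA, patchB))) else
    dynamic_range
  if (L == 0) return(if (identical(patchA, patchB)) 1 else 0)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- exp(-((seq_len(window_size) - (window_size + 1) / 2)^2) /
             (2 * sigma^2))
  g <- g / sum(g)
  filt <- function(x) gauss_filter_valid(x, g)
  mu_a <- filt(patchA); mu_b <- filt(patchB)
  var_a <- filt(patchA^2) - mu_a^2
  var_b <- filt(patchB^2) - mu_b^2
  cov_ab <- filt(patchA * patchB) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(ssim_map)
}

# Separable "valid" Gaussian filtering via banded matrix products:
# returns an (r-w+1) x (c-w+1) matrix of local weighted sums.
gauss_filter_valid <- function(x, g) {
  w <- length(g)
  band <- function(n) {
    m <- matrix(0, n - w + 1L, n)
    for (i in seq_len(n - w + 1L)) m[i, i:(i + w - 1L)] <- g
    m
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Match neurons across two sessions and score against a reference pairing
#'
#' Registers the day-2 mean-fluorescence image to day 1, extracts a square
#' patch (default 39 x 39 pixels) around every ROI center on each day
#' (day-2 centers corrected by the recovered shift; out-of-bounds patches
#' are zero-padded and flagged), fills the day1 x day2 structural-
#' similarity matrix, normalizes each row by its maximum, assigns each
#' day-1 cell its argmax day-2 match, and reports the percentage of cells
#' whose top-ranked match equals the reference pairing. Assignment is
#' per-row (not one-to-one); `one_to_one = TRUE` instead takes a greedy
#' mutual-best assignment.
#'
#' @param day1_image,day2_image mean-fluorescence images (matrices).
#' @param roi_centers_1,roi_centers_2 n x 2 matrices of (y, x) centers;
#'   both are expressed in the day-1 reference frame (day-2 extraction
#'   positions are obtained by applying the recovered shift).
#' @param reference_pairing integer vector: for day-1 cell i, the index of
#'   its true day-2 partner.
#' @param patch_size square patch side in pixels (default 39).
#' @param one_to_one use a greedy one-to-one assignment instead of
#'   independent row argmax.
#' @return list of class `match_result`: `similarity`,
#'   `normalized_similarity`, `assignment`, `agreement_pct`, `shift`,
#'   `padded` (logical per day-1 cell).
#' @export
match_and_score <- function(day1_image, day2_image, roi_centers_1,
                            roi_centers_2, reference_pairing,
                            patch_size = 39L, one_to_one = FALSE) {
  stopifnot(nrow(roi_centers_1) == length(reference_pairing))
  shift <- register_translation(day1_image, day2_image)
  # day-2 centers are given in the day-1 reference frame; the recovered
  # shift maps them into day-2 image coordinates
  centers_2 <- sweep(roi_centers_2, 2, shift, "+")
  p1 <- lapply(seq_len(nrow(roi_centers_1)), function(i)
    extract_patch(day1_image, roi_centers_1[i, ], patch_size))
  p2 <- lapply(seq_len(nrow(centers_2)), function(i)
    extract_patch(day2_image, centers_2[i, ], patch_size))
  L <- diff(range(day1_image, day2_image))
  sim <- matrix(NA_real_, length(p1), length(p2))
  for (i in seq_along(p1)) for (j in seq_along(p2))
    sim[i, j] <- patch_similarity(p1[[i]]$patch, p2[[j]]$patch,
                                  dynamic_range = L)
  norm_sim <- sim / apply(sim, 1, max)
  assignment <- if (one_to_one) greedy_assignment(sim) else
    apply(sim, 1, which.max)
  structure(list(
    similarity = sim, normalized_similarity = norm_sim,
    assignment = assignment,
    agreement_pct = 100 * mean(assignment == reference_pairing),
    shift = shift,
    padded_1 = vapply(p1, `[[`, logical(1), "padded"),
    padded_2 = vapply(p2, `[[`, logical(1), "padded")
  ), class = "match_result")
}

extract_patch <- function(image, center, patch_size) {
  half <- (patch_size - 1L) %/% 2L
  cy <- round(center[1]); cx <- round(center[2])
  ys <- (cy - half):(cy - half + patch_size - 1L)
  xs <- (cx - half):(cx - half + patch_size - 1L)
  padded <- min(ys) < 1 || min(xs) < 1 ||
    max(ys) > nrow(image) || max(xs) > ncol(image)
  patch <- matrix(0, patch_size, patch_size)
  yin <- ys >= 1 & ys <= nrow(image)
  xin <- xs >= 1 & xs <= ncol(image)
  patch[yin, xin] <- image[ys[yin], xs[xin]]
  list(patch = patch, padded = padded)
}

greedy_assignment <- function(sim) {
  n1 <- nrow(sim); n2 <- ncol(sim)
  assignment <- integer(n1)
  s <- sim
  for (k in seq_len(min(n1, n2))) {
    ij <- arrayInd(which.max(s), dim(s))
    assignment[ij[1]] <- ij[2]
    s[ij[1], ] <- -Inf
    s[, ij[2]] <- -Inf
  }
  assignment
}

#' Read a grayscale image from TIFF or CSV
#'
#' Convenience loader for mean-fluorescence field-of-view images. TIFF
#' reading requires the `tiff` package; multi-channel images are averaged.
#'
#' @param path file ending in `.tif`/`.tiff` or `.csv`.
#' @return numeric matrix.
#' @export
read_fov_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}
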