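#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the weighted average `Y = 0.299 R + 0.587 G + 0.114 B`, the standard
#' luma weighting that tracks the human eye's sensitivity to the three
#' channels. The result is rounded half-up and clamped to `[0, 255]`, so an
#' image with `R = G = B` maps exactly to its common channel value.
#'
#' @param img an `H x W x 3` numeric array of R, G, B intensities in
#'   `[0, 255]`, or an `H x W` matrix (already gray, returned validated).
#' @return an `H x W` numeric matrix of intensities in `[0, 255]`.
#' @examples
#' arr <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' rgb_to_gray(arr)   # 141
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(as_gray_image(img))
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("`img` must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 1 || dim(img)[2] < 1)
    stop("`img` must be non-empty", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("channel values must be in [0, 255]", call. = FALSE)
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  y <- floor(y + 0.5)            # round half up
  matrix(pmin(pmax(y, 0), 255), nrow = dim(img)[1])
}

#' Corrupt a grayscale image with seeded noise
#'
#' Fixture generator for exercising the denoising filters. `salt_pepper`
#' picks exactly `round(amount * H * W)` distinct pixel positions and sets
#' each to 0 or 255 with equal probability; `gaussian` adds i.i.d. zero-mean
#' noise with standard deviation `amount` (intensity units), then rounds and
#' clamps. The realization is fully determined by `seed`.
#'
#' @param img grayscale image matrix.
#' @param kind `"salt_pepper"` or `"gaussian"`.
#' @param amount corrupted-pixel fraction in `[0, 1]` (salt_pepper) or noise
#'   sigma in intensity units (gaussian).
#' @param seed integer seed fixing the noise realization.
#' @return the corrupted image, same dimensions.
#' @export
add_noise <- function(img, kind = c("salt_pepper", "gaussian"),
                      amount, seed = 1L) {
  img <- as_gray_image(img)
  kind <- match.arg(kind)
  if (!is.numeric(amount) || length(amount) != 1 || amount < 0)
    stop("`amount` must be a non-negative scalar", call. = FALSE)
  if (kind == "salt_pepper" && amount > 1)
    stop("salt_pepper `amount` is a fraction in [0, 1]", call. = FALSE)
  if (amount == 0) return(img)
  with_seed(seed, {
    if (kind == "salt_pepper") {
      n <- round(amount * length(img))
      pos <- sample.int(length(img), n)
      img[pos] <- ifelse(runif(n) < 0.5, 0, 255)
    } else {
      img[] <- pmin(pmax(floor(img + rnorm(length(img), sd = amount) + 0.5),
                         0), 255)
    }
    img
  })
}

check_window <- function(window, img) {
  if (!is.numeric(window) || length(window) != 1 || window %% 2 != 1 ||
      window < 3)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (window > min(dim(img)))
    stop("`window` exceeds the image extent", call. = FALSE)
  as.integer(window)
}

#' Median filter
#'
#' Replaces each pixel with the median of its `window x window` neighborhood.
#' Nonlinear, so isolated salt-and-pepper impulses are removed without the
#' edge blurring of linear smoothing. Borders are handled by edge
#' replication, so dimensions are preserved and borders are not darkened.
#'
#' @param img grayscale image matrix.
#' @param window odd integer window side, `>= 3` and at most `min(dim(img))`.
#' @return the filtered image, same dimensions.
#' @seealso [mean_filter()], [gaussian_filter()] for the linear alternatives.
#' @export
median_filter <- function(img, window = 3L) {
  img <- as_gray_image(img)
  window <- check_window(window, img)
  .spatial_filter_cpp(img, window, 0L, 0)
}

#' Mean (box) filter
#'
#' Linear smoothing alternative to [median_filter()]; blurs edges, kept for
#' comparison. Edge-replicated borders; result rounded half-up.
#' @inheritParams median_filter
#' @export
mean_filter <- function(img, window = 3L) {
  img <- as_gray_image(img)
  window <- check_window(window, img)
  .spatial_filter_cpp(img, window, 1L, 0)
}

#' Gaussian filter
#'
#' Linear low-pass alternative to [median_filter()], kept for comparison.
#' @inheritParams median_filter
#' @param sigma Gaussian kernel standard deviation in pixels.
#' @export
gaussian_filter <- function(img, window = 3L, sigma = window / 3) {
  img <- as_gray_image(img)
  window <- check_window(window, img)
  stopifnot(sigma > 0)
  .spatial_filter_cpp(img, window, 2L, sigma)
}

#' Apply the configured denoising filter
#'
#' Dispatch helper used by the pipeline and the command-line tool; median is
#' the default (and recommended) filter.
#' @inheritParams median_filter
#' @param filter one of `"median"`, `"mean"`, `"gaussian"`.
#' @export
preprocess <- function(img, window = 3L,
                       filter = c("median", "mean", "gaussian")) {
  filter <- match.arg(filter)
  switch(filter,
         median   = median_filter(img, window),
         mean     = mean_filter(img, window),
         gaussian = gaussian_filter(img, window))
}

#' Read a raster image as a grayscale matrix
#'
#' Reads an 8-bit PNG; RGB(A) input is converted with [rgb_to_gray()] (alpha
#' is ignored).
#' @param path path to a PNG file.
#' @return grayscale image matrix with intensities in `[0, 255]`.
#' @export
read_gray <- function(path) {
  a <- png::readPNG(path)
  a <- a * 255
  if (length(dim(a)) == 2) return(as_gray_image(floor(a + 0.5)))
  rgb_to_gray(a[, , 1:3, drop = FALSE])
}

#' Write a grayscale matrix as an 8-bit PNG
#' @param img grayscale image matrix.
#' @param path output path.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
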