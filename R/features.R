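#' Rotate and scale a template with a validity mask
#'
#' Resamples the template at the given angle (degrees, counter-clockwise) and
#' isotropic scale with bilinear interpolation. The output canvas is the
#' rotated bounding box; pixels that fall outside the source template are
#' marked invalid in the mask and excluded from match scoring.
#'
#' @param tpl template image matrix.
#' @param angle rotation in degrees, counter-clockwise.
#' @param scale isotropic scale ratio (> 0).
#' @return list with `pixels` (matrix) and `mask` (logical matrix).
#' @keywords internal
transform_template <- function(tpl, angle = 0, scale = 1) {
  tpl <- as_gray_image(tpl, "tpl")
  stopifnot(scale > 0)
  h <- nrow(tpl); w <- ncol(tpl)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  oh <- max(1L, ceiling(scale * (h * abs(ct) + w * abs(st))))
  ow <- max(1L, ceiling(scale * (w * abs(ct) + h * abs(st))))
  # inverse map: output center coords -> source coords
  oc_i <- (oh + 1) / 2; oc_j <- (ow + 1) / 2
  sc_i <- (h + 1) / 2;  sc_j <- (w + 1) / 2
  jo <- matrix(rep(seq_len(ow), each = oh), nrow = oh) - oc_j
  io <- matrix(rep(seq_len(oh), times = ow), nrow = oh) - oc_i
  # undo rotation (x right, y down; CCW visual rotation) then scale
  xs <- ( jo * ct - io * st) / scale + sc_j
  ys <- ( jo * st + io * ct) / scale + sc_i
  eps <- 1e-9
  ok <- ys >= 1 - eps & ys <= h + eps & xs >= 1 - eps & xs <= w + eps
  i0 <- pmin(pmax(floor(ys), 1), h); j0 <- pmin(pmax(floor(xs), 1), w)
  fi <- pmin(pmax(ys - i0, 0), 1);   fj <- pmin(pmax(xs - j0, 0), 1)
  px <- matrix(0, oh, ow)
  idx <- which(ok)
  if (length(idx)) {
    ii <- i0[idx]; jj <- j0[idx]
    i1 <- pmin(ii + 1, h); j1 <- pmin(jj + 1, w)  # clamp at the far edge
    px[idx] <- (1 - fi[idx]) * ((1 - fj[idx]) * tpl[cbind(ii, jj)] +
                                     fj[idx]  * tpl[cbind(ii, j1)]) +
                    fi[idx]  * ((1 - fj[idx]) * tpl[cbind(i1, jj)] +
                                     fj[idx]  * tpl[cbind(i1, j1)])
  }
  list(pixels = px, mask = ok)
}

#' Match a template against an image over a rotation/scale grid
#'
#' Slides the template over every placement in the image for every pose in
#' the angle/scale grid and scores each with zero-mean normalized
#' cross-correlation (NCC), mapped to `[0, 1]` as `max(0, ncc)`. NCC is
#' invariant to gain/offset changes of the image intensities, which is what
#' makes a fixed decision threshold (see [classify_gender()]) meaningful.
#' Placements with (near-)zero intensity variance score 0.
#'
#' @param img grayscale search image.
#' @param tpl grayscale template (the pointed male umbilicus region).
#' @param angles rotation grid in degrees.
#' @param scales scale-ratio grid.
#' @return list of class `crab_match` with `score` in `[0, 1]`, `row`, `col`
#'   (1-based top-left of the best placement), `angle` and `scale`.
#' @export
match_template <- function(img, tpl,
                           angles = seq(-180, 180, by = 10),
                           scales = seq(0.8, 1.2, by = 0.1)) {
  img <- as_gray_image(img)
  tpl <- as_gray_image(tpl, "tpl")
  if (nrow(tpl) > nrow(img) || ncol(tpl) > ncol(img))
    stop("template larger than image", call. = FALSE)
  best <- list(score = 0, row = 1L, col = 1L, angle = angles[1],
               scale = scales[1])
  for (sc in scales) {
    for (an in angles) {
      tr <- transform_template(tpl, an, sc)
      if (nrow(tr$pixels) > nrow(img) || ncol(tr$pixels) > ncol(img)) next
      hit <- .ncc_scan_cpp(img, tr$pixels, tr$mask)
      if (hit$score > best$score)
        best <- list(score = hit$score, row = hit$row, col = hit$col,
                     angle = an, scale = sc)
    }
  }
  structure(best, class = "crab_match")
}

#' Classify gender from a match score
#'
#' The abdominal umbilicus is pointed in males and rounded in females; a
#' normalized match score against the pointed-umbilicus template at or above
#' the threshold (default 0.7) calls the specimen male, below calls female.
#' The boundary is inclusive for male.
#'
#' @param match a `crab_match` result or a bare score in `[0, 1]`.
#' @param threshold decision threshold in (0, 1).
#' @return `"male"` or `"female"`.
#' @export
classify_gender <- function(match, threshold = 0.7) {
  score <- if (inherits(match, "crab_match")) match$score else match
  stopifnot(is.numeric(score), length(score) == 1,
            threshold > 0, threshold < 1)
  if (score >= threshold) "male" else "female"
}

#' Hough-gradient circle detection
#'
#' Two-stage circle detection: edge pixels (Sobel gradient magnitude at or
#' above `canny_high`) vote along their gradient directions for candidate
#' centers in a 2-D accumulator, collapsing the classical 3-D parameter
#' space; radii are then estimated per center from the histogram of
#' supporting edge-pixel distances in `[r_min, r_max]`. Returned circles have
#' at least `param2` center votes, are mutually separated by at least
#' `min_dist`, and are sorted by descending votes. Too-small `min_dist` or
#' `param2` over-detects (many spurious circles); too-large values miss the
#' carapace — both ends are worth checking when tuning.
#'
#' @param img preprocessed (median-filtered) grayscale image.
#' @param min_dist minimum separation between returned centers (pixels).
#' @param param2 minimum accumulator votes for a center.
#' @param canny_high gradient-magnitude edge threshold.
#' @param r_min,r_max radius search range (pixels).
#' @param max_circles cap on the number of returned circles.
#' @return data.frame with columns `cx`, `cy` (pixel-center coordinates,
#'   `x = col`, `y = row`), `r` (pixels) and `votes`; zero rows if nothing
#'   is found.
#' @export
detect_circles <- function(img, min_dist = 15, param2 = 30,
                           canny_high = 100, r_min = 10, r_max = 80,
                           max_circles = 32L) {
  img <- as_gray_image(img)
  stopifnot(min_dist > 0, param2 >= 1, r_min >= 1, r_min < r_max)
  .hough_circles_cpp(img, min_dist, as.integer(param2), canny_high,
                     as.integer(r_min), as.integer(r_max),
                     as.integer(max_circles))
}

#' Pick the carapace circle from detection results
#'
#' The back view contains one dominant disc (the carapace); among the
#' detected circles the one with most votes wins, ties go to the larger
#' radius, remaining ties to the center closest to the image center.
#'
#' @param circles data.frame from [detect_circles()].
#' @param img the image the circles came from (for the center tie-break).
#' @return a one-row data.frame (`cx`, `cy`, `r`, `votes`).
#' @export
pick_carapace <- function(circles, img) {
  if (is.null(circles) || nrow(circles) == 0)
    stop("no carapace detected", call. = FALSE)
  ctr_x <- (ncol(img) + 1) / 2; ctr_y <- (nrow(img) + 1) / 2
  d2 <- (circles$cx - ctr_x)^2 + (circles$cy - ctr_y)^2
  ord <- order(-circles$votes, -circles$r, d2)
  circles[ord[1], , drop = FALSE]
}

#' Pixel-size calibration from a reference object
#'
#' A reference crab of known carapace length is photographed once with the
#' camera fixed; the ratio of physical to pixel size converts subsequent
#' Hough radii to centimeters.
#'
#' @param reference_len_cm known physical length (cm).
#' @param reference_len_px its measured length in the image (pixels).
#' @return cm-per-pixel scale factor.
#' @export
calibrate <- function(reference_len_cm, reference_len_px) {
  if (!is.numeric(reference_len_cm) || !is.numeric(reference_len_px) ||
      reference_len_cm <= 0 || reference_len_px <= 0)
    stop("calibration lengths must be positive", call. = FALSE)
  reference_len_cm / reference_len_px
}

#' Condition-factor fatness
#'
#' `K = 100 * W / L^3` with body weight `W` in grams and carapace length `L`
#' in centimeters — the standard condition factor relating weight to the
#' cube of a linear body measure. Higher K means a plumper crab.
#'
#' @param weight_g body weight (g), positive.
#' @param carapace_cm carapace length (cm), positive.
#' @return fatness in percent.
#' @export
fatness <- function(weight_g, carapace_cm) {
  if (any(!is.finite(weight_g)) || any(!is.finite(carapace_cm)) ||
      any(weight_g <= 0) || any(carapace_cm <= 0))
    stop("weight and carapace length must be positive", call. = FALSE)
  100 * weight_g / carapace_cm^3
}

#' Mean shell gray inside the carapace circle
#'
#' Averages the intensities of all pixels whose centers lie strictly inside
#' the circle, clipped to image bounds. Darker (cyan-black) shells indicate
#' better quality in practice; the raw mean gray is passed to the model,
#' which learns the direction of the effect.
#'
#' @param img grayscale image.
#' @param carapace one-row data.frame (or list) with `cx`, `cy`, `r`.
#' @return mean intensity in `[0, 255]`.
#' @export
shell_gray <- function(img, carapace) {
  img <- as_gray_image(img)
  cx <- carapace$cx; cy <- carapace$cy; r <- carapace$r
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(r), r > 0)
  ji <- max(1L, ceiling(cx - r)); jf <- min(ncol(img), floor(cx + r))
  ii <- max(1L, ceiling(cy - r)); if_ <- min(nrow(img), floor(cy + r))
  if (ji > jf || ii > if_)
    stop("circle lies entirely outside the image", call. = FALSE)
  js <- ji:jf; is <- ii:if_
  dx2 <- (js - cx)^2; dy2 <- (is - cy)^2
  inside <- outer(dy2, dx2, `+`) < r^2
  if (!any(inside))
    stop("circle contains no pixel centers", call. = FALSE)
  mean(img[is, js, drop = FALSE][inside])
}

#' Extract the four grading features for one specimen
#'
#' Composes the full feature path: both views are median-filtered, the
#' abdomen view is matched against the pointed-umbilicus template to call
#' gender, the back view goes through Hough circle detection to get the
#' carapace (length = circle diameter converted by the calibration), and
#' fatness and mean shell gray are derived. Intermediate results are kept
#' for audit.
#'
#' @param back_img back-view grayscale image (carapace visible).
#' @param abdomen_img abdomen-view grayscale image (umbilicus visible).
#' @param tpl pointed-umbilicus template.
#' @param weight_g measured body weight (g).
#' @param cm_per_px calibration from [calibrate()].
#' @param hough named list of arguments for [detect_circles()].
#' @param angles,scales pose grid for [match_template()].
#' @param window,filter preprocessing settings (see [preprocess()]).
#' @param threshold gender decision threshold.
#' @return list of class `crab_features` with `gender`, `weight_g`,
#'   `carapace_cm`, `fatness_pct`, `shell_gray`, and an `audit` list
#'   (match result, picked circle, calibration).
#' @export
extract_features <- function(back_img, abdomen_img, tpl, weight_g,
                             cm_per_px, hough = list(),
                             angles = seq(-20, 20, by = 10),
                             scales = c(0.9, 1.0, 1.1),
                             window = 3L, filter = "median",
                             threshold = 0.7) {
  stopifnot(weight_g > 0, cm_per_px > 0)
  back <- preprocess(back_img, window, filter)
  abdo <- preprocess(abdomen_img, window, filter)

  m <- match_template(abdo, tpl, angles = angles, scales = scales)
  gender <- classify_gender(m, threshold)

  circles <- do.call(detect_circles, c(list(back), hough))
  cara <- tryCatch(pick_carapace(circles, back),
                   error = function(e) stop("back view: ", conditionMessage(e),
                                            call. = FALSE))
  carapace_cm <- 2 * cara$r * cm_per_px
  structure(list(
    gender      = gender,
    weight_g    = weight_g,
    carapace_cm = carapace_cm,
    fatness_pct = fatness(weight_g, carapace_cm),
    shell_gray  = shell_gray(back, cara),
    audit = list(match = m, carapace = cara, cm_per_px = cm_per_px)
  ), class = "crab_features")
}

#' Numeric model-input vector for one specimen
#'
#' Encodes gender as male = 1, female = 0 and returns the 4-vector in the
#' canonical order (gender, weight, fatness, shell gray).
#' @param feats a `crab_features` object (or compatible list).
#' @return named numeric vector of length 4.
#' @export
feature_vector <- function(feats) {
  c(gender = if (identical(feats$gender, "male")) 1 else 0,
    weight_g = feats$weight_g, fatness_pct = feats$fatness_pct,
    shell_gray = feats$shell_gray)
}
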