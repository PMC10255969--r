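#' Render the canonical umbilicus glyph
#'
#' The male abdominal umbilicus is rendered as a narrow downward-pointing
#' triangle, the female one as a wide half-ellipse bulging downward; the
#' shapes are deliberately distinct so that the normalized match score of a
#' rounded glyph against the pointed template falls well below the 0.7
#' gender threshold while a pointed glyph self-matches near 1.
#'
#' @param shape `"pointed"` (male) or `"rounded"` (female).
#' @param size glyph canvas side in pixels (odd recommended).
#' @param fg,bg glyph and background intensities.
#' @return grayscale image matrix.
#' @export
umbilicus_glyph <- function(shape = c("pointed", "rounded"), size = 33L,
                            fg = 200, bg = 30) {
  shape <- match.arg(shape)
  g <- as.integer(size)
  img <- matrix(bg, g, g)
  cj <- (g + 1) / 2
  i <- matrix(rep(seq_len(g), times = g), g)      # row index
  j <- matrix(rep(seq_len(g), each = g), g)       # col index
  if (shape == "pointed") {
    halfw <- 0.225 * g * (1 - (i - 1) / (g - 1))  # tapers to the apex
    fill <- abs(j - cj) <= halfw
  } else {
    fill <- ((j - cj) / (0.45 * g))^2 + ((i - 1) / (0.55 * g))^2 <= 1
  }
  img[fill] <- fg
  img
}

#' Synthesize a back-view image with a known carapace
#'
#' Draws a filled disc (the carapace seen from above) at a known center and
#' radius on a darker background, then adds seeded Gaussian speckle and
#' optional salt-and-pepper corruption. The ground-truth circle is returned
#' alongside the image so detector recovery can be asserted exactly.
#'
#' @param r_px carapace radius in pixels.
#' @param cx,cy disc center (pixel-center coordinates; default canvas
#'   center).
#' @param canvas canvas side in pixels.
#' @param shell_gray_base disc intensity before noise.
#' @param bg_gray background intensity.
#' @param speckle_sd Gaussian speckle standard deviation (0 disables).
#' @param sp_amount salt-and-pepper corrupted fraction (0 disables).
#' @param seed noise seed.
#' @return list with `image` and `circle` (data.frame `cx`, `cy`, `r`).
#' @export
make_back_image <- function(r_px, cx = NULL, cy = NULL, canvas = 256L,
                            shell_gray_base = 140, bg_gray = 30,
                            speckle_sd = 5, sp_amount = 0, seed = 1L) {
  canvas <- as.integer(canvas)
  if (is.null(cx)) cx <- (canvas + 1) / 2
  if (is.null(cy)) cy <- (canvas + 1) / 2
  margin <- 3
  if (r_px <= 0 || cx - r_px < margin || cx + r_px > canvas - margin + 1 ||
      cy - r_px < margin || cy + r_px > canvas - margin + 1)
    stop("carapace disc does not fit in the canvas with margin",
         call. = FALSE)
  i <- matrix(rep(seq_len(canvas), times = canvas), canvas)
  j <- matrix(rep(seq_len(canvas), each = canvas), canvas)
  img <- matrix(bg_gray, canvas, canvas)
  img[(i - cy)^2 + (j - cx)^2 <= r_px^2] <- shell_gray_base
  if (speckle_sd > 0)
    img <- add_noise(img, "gaussian", speckle_sd,
                     seed = child_seed(seed, "speckle"))
  if (sp_amount > 0)
    img <- add_noise(img, "salt_pepper", sp_amount,
                     seed = child_seed(seed, "sp"))
  list(image = img, circle = data.frame(cx = cx, cy = cy, r = r_px))
}

#' Synthesize an abdomen-view image with a posed umbilicus glyph
#'
#' Places the pointed (male) or rounded (female) glyph at a pose drawn from
#' the configured angle/scale grid and a random in-bounds position, then
#' adds seeded speckle. The conveyor constrains how far a live crab can
#' rotate between the guide baffles, so the default pose grid is modest
#' (-20..20 degrees, scales 0.9-1.1); it must match the grid the matcher
#' searches.
#'
#' @param shape `"pointed"` or `"rounded"`.
#' @param canvas canvas side in pixels.
#' @param glyph_size glyph canvas side passed to [umbilicus_glyph()].
#' @param angles,scales pose grid the pose is drawn from.
#' @param speckle_sd Gaussian speckle standard deviation.
#' @param bg_gray background intensity (matches the glyph background).
#' @param seed pose and noise seed.
#' @return list with `image` and `truth` (shape, angle, scale, row, col).
#' @export
make_abdomen_image <- function(shape = c("pointed", "rounded"),
                               canvas = 128L, glyph_size = 33L,
                               angles = seq(-20, 20, by = 10),
                               scales = c(0.9, 1.0, 1.1),
                               speckle_sd = 5, bg_gray = 30, seed = 1L) {
  shape <- match.arg(shape)
  canvas <- as.integer(canvas)
  glyph <- umbilicus_glyph(shape, glyph_size, bg = bg_gray)
  pose <- with_seed(child_seed(seed, "pose"), {
    list(angle = sample(angles, 1), scale = sample(scales, 1))
  })
  tr <- transform_template(glyph, pose$angle, pose$scale)
  ph <- nrow(tr$pixels); pw <- ncol(tr$pixels)
  if (ph > canvas || pw > canvas)
    stop("posed glyph does not fit in the canvas", call. = FALSE)
  at <- with_seed(child_seed(seed, "place"), {
    c(sample.int(canvas - ph + 1, 1), sample.int(canvas - pw + 1, 1))
  })
  img <- matrix(bg_gray, canvas, canvas)
  patch <- img[at[1]:(at[1] + ph - 1), at[2]:(at[2] + pw - 1)]
  patch[tr$mask] <- tr$pixels[tr$mask]
  img[at[1]:(at[1] + ph - 1), at[2]:(at[2] + pw - 1)] <- patch
  img <- matrix(pmin(pmax(floor(img + 0.5), 0), 255), canvas, canvas)
  if (speckle_sd > 0)
    img <- add_noise(img, "gaussian", speckle_sd,
                     seed = child_seed(seed, "speckle"))
  list(image = img,
       truth = list(shape = shape, angle = pose$angle, scale = pose$scale,
                    row = at[1], col = at[2]))
}

#' Grade-labelling rule for synthetic specimens
#'
#' The real quality label comes from cooking each crab and weighing its
#' edible fraction; the synthetic stand-in is a linear score over the four
#' features scaled by fixed design ranges, with positive weight on fatness
#' and weight, negative weight on shell gray (darker cyan-black shells
#' grade better), and a small additive gender term. Fixed cutpoints on the
#' score split the population into `G = length(cutpoints) + 1` grades
#' (grade G = best); the default cutpoints are the terciles of the score
#' under the generator's design distributions. When `margin > 0` the
#' generator draws a balanced grade target per specimen and redraws its
#' continuous features until the score lands in that grade's band at
#' least `margin` clear of the cutpoints — without a boundary margin the
#' grade of near-cutpoint specimens is not recoverable from finite data
#' and recovery tests would measure sampling luck, not the model. Labels
#' are misrated to an adjacent grade with probability `label_noise`,
#' emulating marginal errors of the edible-proportion rating protocol (a
#' rater may confuse neighboring grades but will not rate a top specimen
#' as bottom grade).
#'
#' @param coefs named coefficients over
#'   `(gender, weight_g, fatness_pct, shell_gray)`.
#' @param cutpoints strictly increasing score cutpoints.
#' @param ranges named list of `(lo, hi)` fixed scaling ranges per feature.
#' @param margin half-width of the score exclusion band around each
#'   cutpoint.
#' @param label_noise label-flip probability in `[0, 0.5)`.
#' @return list of class `grade_rule` (with `G` derived from `cutpoints`).
#' @export
grade_rule <- function(coefs = c(gender = 0.1, weight_g = 0.35,
                                 fatness_pct = 0.35, shell_gray = -0.2),
                       cutpoints = c(0.21, 0.37),
                       ranges = list(gender = c(0, 1),
                                     weight_g = c(40, 420),
                                     fatness_pct = c(35, 95),
                                     shell_gray = c(90, 200)),
                       margin = 0.05, label_noise = 0.1) {
  if (length(coefs) != 4 || length(ranges) != 4)
    stop("rule needs 4 coefficients and 4 ranges", call. = FALSE)
  if (length(cutpoints) < 1 || is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)", call. = FALSE)
  stopifnot(margin >= 0)
  if (length(cutpoints) > 1 && 2 * margin >= min(diff(cutpoints)))
    stop("margin too wide: an intermediate grade band would be empty",
         call. = FALSE)
  structure(list(coefs = coefs, cutpoints = cutpoints, ranges = ranges,
                 margin = margin, G = length(cutpoints) + 1L,
                 label_noise = label_noise), class = "grade_rule")
}

#' Quality score of specimens under a grade rule
#' @param features data.frame with columns `gender` (0/1 or male/female),
#'   `weight_g`, `fatness_pct`, `shell_gray`.
#' @param rule a [grade_rule()].
#' @return numeric score vector.
#' @export
grade_score <- function(features, rule) {
  gd <- features$gender
  if (!is.numeric(gd)) gd <- as.numeric(gd == "male")
  vals <- list(gender = gd, weight_g = features$weight_g,
               fatness_pct = features$fatness_pct,
               shell_gray = features$shell_gray)
  Z <- vapply(names(vals), function(nm) {
    r <- rule$ranges[[nm]]
    (vals[[nm]] - r[1]) / (r[2] - r[1])
  }, numeric(length(gd)))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  drop(Z %*% rule$coefs)
}

#' Apply a grade rule to a feature table (no label noise)
#'
#' Deterministic part of the labelling: the linear score of
#' [grade_score()] cut at the rule's fixed cutpoints.
#' @inheritParams grade_score
#' @return integer grades in `1..G`.
#' @export
apply_grade_rule <- function(features, rule) {
  findInterval(grade_score(features, rule), rule$cutpoints,
               left.open = TRUE) + 1L
}

#' Generate a synthetic graded crab dataset
#'
#' Desk-scale replica of an 80-specimen study: genders exactly balanced,
#' carapace length and condition factor drawn from realistic river-crab
#' distributions (weight follows as `W = K L^3 / 100`), shell gray uniform
#' over the photographed range. Each specimen gets a back image (disc of
#' the true radius) and an abdomen image (glyph matching the true gender),
#' and the feature table is labelled by the grade rule with optional label
#' noise. Everything is reproducible from `seed`.
#'
#' @param n number of specimens (>= 10).
#' @param rule a [grade_rule()].
#' @param seed master seed.
#' @param cm_per_px pixel calibration used to size the back-image discs.
#' @param canvas_back,canvas_abdomen canvas sides in pixels.
#' @param with_images set `FALSE` to skip image synthesis (feature table
#'   only).
#' @param dir optional directory; when given, images (`PNG`), the manifest,
#'   the feature table (`CSV`) and the ground truth (`JSON`) are written.
#' @return list of class `crab_dataset`: `features` (data.frame with `id`,
#'   the four features, `grade` — noisy label — and `grade_true`),
#'   `manifest`, `specimens` (per-specimen images + truth when
#'   `with_images`), `template` (pointed-umbilicus template), `rule`,
#'   `cm_per_px`, `seed`.
#' @export
make_dataset <- function(n = 80L, rule = grade_rule(), seed = 1L,
                         cm_per_px = 0.05, canvas_back = 256L,
                         canvas_abdomen = 128L, with_images = TRUE,
                         dir = NULL) {
  stopifnot(n >= 10)
  n <- as.integer(n)
  n_male <- n %/% 2L
  base <- with_seed(child_seed(seed, "features"), {
    gender <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    draw <- function(k) {
      L <- pmin(pmax(rnorm(k, 6.2, 0.6), 4.8), 7.6)     # carapace cm
      K <- pmin(pmax(rnorm(k, 65, 12), 35), 95)         # condition factor
      data.frame(weight_g = K * L^3 / 100, carapace_cm = L,
                 fatness_pct = K, shell_gray = runif(k, 90, 200))
    }
    d <- cbind(gender = gender, draw(n), stringsAsFactors = FALSE)
    if (rule$margin > 0) {
      # stratified balanced grades: each specimen is redrawn until its
      # score lands in its target grade's band, `margin` clear of the
      # cutpoints, so every grade is populated and recoverable
      target <- sample(rep(seq_len(rule$G), length.out = n))
      lo <- c(-Inf, rule$cutpoints + rule$margin)[target]
      hi <- c(rule$cutpoints - rule$margin, Inf)[target]
      for (tries in 1:500) {
        sc <- grade_score(d, rule)
        bad <- sc <= lo | sc >= hi
        if (!any(bad)) break
        d[bad, -1] <- draw(sum(bad))
      }
      if (any(grade_score(d, rule) <= lo | grade_score(d, rule) >= hi))
        stop("could not populate all grade bands; widen the cutpoint gaps ",
             "or reduce the margin", call. = FALSE)
    }
    cbind(id = sprintf("crab%03d", seq_len(n)), d,
          stringsAsFactors = FALSE)[, c("id", "gender", "weight_g",
                                        "carapace_cm", "fatness_pct",
                                        "shell_gray")]
  })
  true_grade <- apply_grade_rule(base, rule)
  grade <- with_seed(child_seed(seed, "labelnoise"), {
    g <- true_grade
    flip <- runif(n) < rule$label_noise
    for (i in which(flip)) {
      adj <- intersect(c(g[i] - 1L, g[i] + 1L), seq_len(rule$G))
      g[i] <- if (length(adj) == 1) adj else sample(adj, 1)
    }
    g
  })
  feats <- cbind(base, grade = grade, grade_true = true_grade)

  specimens <- NULL
  template <- umbilicus_glyph("pointed")
  if (with_images) {
    specimens <- lapply(seq_len(n), function(i) {
      r_px <- base$carapace_cm[i] / cm_per_px / 2
      back <- make_back_image(r_px, canvas = canvas_back,
                              shell_gray_base = base$shell_gray[i],
                              seed = child_seed(seed, paste0("back", i)))
      abdo <- make_abdomen_image(
        if (base$gender[i] == "male") "pointed" else "rounded",
        canvas = canvas_abdomen,
        seed = child_seed(seed, paste0("abdo", i)))
      list(id = base$id[i], back = back, abdomen = abdo)
    })
  }
  manifest <- data.frame(id = base$id,
                         back_img = sprintf("images/%s_back.png", base$id),
                         abdomen_img = sprintf("images/%s_abdomen.png",
                                               base$id),
                         weight_g = base$weight_g,
                         stringsAsFactors = FALSE)
  ds <- structure(list(features = feats, manifest = manifest,
                       specimens = specimens, template = template,
                       rule = rule, cm_per_px = cm_per_px, seed = seed),
                  class = "crab_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a synthetic dataset to disk
#' @param ds a `crab_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(ds$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(ds$features, file.path(dir, "features_truth.csv"),
            row.names = FALSE)
  write_gray(ds$template, file.path(dir, "template.png"))
  if (!is.null(ds$specimens)) {
    for (sp in ds$specimens) {
      write_gray(sp$back$image,
                 file.path(dir, sprintf("images/%s_back.png", sp$id)))
      write_gray(sp$abdomen$image,
                 file.path(dir, sprintf("images/%s_abdomen.png", sp$id)))
    }
  }
  truth <- list(cm_per_px = ds$cm_per_px, seed = ds$seed,
                rule = unclass(ds$rule),
                circles = lapply(ds$specimens, function(sp) sp$back$circle),
                poses = lapply(ds$specimens, function(sp) sp$abdomen$truth))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
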