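test_that("an exact template copy matches with score 1 at its position", {
  img <- rand_gray(40, 40, seed = 1)
  tpl <- img[10:19, 22:31]
  m <- match_template(img, tpl, angles = 0, scales = 1)
  expect_equal(m$score, 1.0, tolerance = 1e-9)
  expect_equal(m$row, 10)
  expect_equal(m$col, 22)
})

test_that("a photometric negative and flat windows score low or zero", {
  tpl <- umbilicus_glyph("pointed", 15)
  m <- match_template(255 - tpl, tpl, angles = 0, scales = 1)
  expect_lte(m$score, 0.1)

  flat <- matrix(77, 30, 30)
  expect_equal(match_template(flat, tpl, angles = 0, scales = 1)$score, 0)
})

test_that("match score is invariant to affine intensity changes of the image", {
  tpl <- umbilicus_glyph("pointed", 13)
  img <- make_abdomen_image("pointed", canvas = 48, glyph_size = 13,
                            angles = 0, scales = 1, seed = 4)$image
  base <- match_template(img, tpl, angles = 0, scales = 1)$score
  # gains/offsets chosen so no pixel saturates (saturation is a genuine,
  # physical break of affine invariance)
  for (ab in list(c(0.5, 20), c(0.9, 10), c(0.7, 40))) {
    scaled <- pmin(pmax(ab[1] * img + ab[2], 0), 255)
    s2 <- match_template(scaled, tpl, angles = 0, scales = 1)$score
    expect_equal(s2, base, tolerance = 1e-6)
  }
})

test_that("match score equals the brute-force NCC oracle on random instances", {
  for (s in 1:100) {
    img <- rand_gray(12, 12, seed = s)
    tpl <- rand_gray(4, 5, seed = s + 1000)
    got <- match_template(img, tpl, angles = 0, scales = 1)$score
    expect_equal(got, ncc_oracle(img, tpl), tolerance = 1e-9)
  }
})

test_that("oversized templates are rejected", {
  expect_error(match_template(matrix(0, 5, 5), matrix(0, 9, 9)), "larger")
})

test_that("gender threshold is inclusive for male at 0.7", {
  expect_equal(classify_gender(0.7), "male")
  expect_equal(classify_gender(0.69), "female")
  expect_equal(classify_gender(1.0), "male")
  m <- structure(list(score = 0.71), class = "crab_match")
  expect_equal(classify_gender(m), "male")
  expect_equal(classify_gender(m, threshold = 0.75), "female")
})

test_that("blank images contain no circles", {
  expect_equal(nrow(detect_circles(matrix(50, 100, 100))), 0)
})

test_that("a synthetic disc is recovered within 2 px", {
  b <- make_back_image(20, cx = 60, cy = 50, canvas = 128,
                       speckle_sd = 5, seed = 2)
  d <- detect_circles(median_filter(b$image), min_dist = 30, param2 = 20,
                      r_min = 10, r_max = 40)
  expect_gte(nrow(d), 1)
  top <- pick_carapace(d, b$image)
  expect_lte(abs(top$cx - 60), 2)
  expect_lte(abs(top$cy - 50), 2)
  expect_lte(abs(top$r - 20), 2)
})

test_that("min_dist separates or merges nearby discs as documented", {
  img <- matrix(30, 200, 300)
  ij <- expand.grid(i = 1:200, j = 1:300)
  d1 <- (ij$i - 100)^2 + (ij$j - 100)^2 <= 25^2
  d2 <- (ij$i - 100)^2 + (ij$j - 200)^2 <= 25^2   # centers 100 px apart
  img[d1 | d2] <- 160
  img <- add_noise(img, "gaussian", 3, seed = 1)
  f <- median_filter(img)
  close_ok <- detect_circles(f, min_dist = 30, param2 = 20,
                             r_min = 15, r_max = 40)
  expect_equal(nrow(close_ok), 2)
  far_only <- detect_circles(f, min_dist = 150, param2 = 20,
                             r_min = 15, r_max = 40)
  expect_equal(nrow(far_only), 1)
})

test_that("carapace selection orders by votes, then radius, then centrality", {
  img <- matrix(0, 100, 100)
  two <- data.frame(cx = c(30, 70), cy = c(30, 70), r = c(20, 25),
                    votes = c(40, 25))
  expect_equal(pick_carapace(two, img)$votes, 40)
  tie <- data.frame(cx = c(30, 70), cy = c(30, 70), r = c(30, 20),
                    votes = c(30, 30))
  expect_equal(pick_carapace(tie, img)$r, 30)
  tie2 <- data.frame(cx = c(48, 10), cy = c(52, 10), r = c(20, 20),
                     votes = c(30, 30))
  expect_equal(pick_carapace(tie2, img)$cx, 48)
  expect_error(pick_carapace(two[0, ], img), "no carapace")
})

test_that("calibration is a guarded ratio that inverts cleanly", {
  expect_equal(calibrate(6.0, 120), 0.05)
  expect_equal(calibrate(5.0, 100), 0.05)
  expect_equal(2 * 60 * calibrate(6.0, 120), 6.0)  # diameter 120 px -> 6 cm
  expect_error(calibrate(-1, 100), "positive")
  expect_error(calibrate(5, 0), "positive")
})

test_that("fatness follows the cubic condition-factor formula", {
  expect_equal(fatness(100, 5), 80)
  expect_equal(fatness(125, 5), 100)
  expect_equal(fatness(100, 10), fatness(100, 5) / 8)  # doubling L: /8
  expect_error(fatness(0, 5), "positive")
  expect_error(fatness(100, -2), "positive")
})

test_that("fatness is monotone in weight and carapace length", {
  W <- seq(50, 400, by = 25); L <- seq(4, 9, by = 0.5)
  expect_true(all(diff(fatness(W, 6)) > 0))
  expect_true(all(diff(fatness(150, L)) < 0))
})

test_that("shell gray averages exactly the pixels inside the circle", {
  uni <- matrix(128, 50, 50)
  expect_equal(shell_gray(uni, list(cx = 25, cy = 25, r = 10)), 128)

  # half 100 / half 200 split through the circle center
  split <- cbind(matrix(100, 40, 20), matrix(200, 40, 20))
  expect_equal(shell_gray(split, list(cx = 20.5, cy = 20, r = 8)), 150)

  one <- matrix(0, 9, 9); one[4, 6] <- 42
  expect_equal(shell_gray(one, list(cx = 6, cy = 4, r = 0.9)), 42)
})

test_that("shell gray equals the enumeration oracle on random circles", {
  for (s in 1:100) {
    img <- rand_gray(20, 20, seed = s)
    circ <- withr::with_seed(s + 500, list(cx = runif(1, 5, 15),
                                           cy = runif(1, 5, 15),
                                           r = runif(1, 2, 8)))
    expect_equal(shell_gray(img, circ),
                 shell_gray_oracle(img, circ$cx, circ$cy, circ$r),
                 tolerance = 1e-12)
  }
  expect_error(shell_gray(matrix(0, 10, 10), list(cx = 99, cy = 99, r = 2)),
               "outside")
})

test_that("full feature extraction recovers generator ground truth", {
  ds <- make_dataset(10, seed = 42, canvas_back = 256)
  male_i <- which(ds$features$gender == "male")[1]
  fem_i <- which(ds$features$gender == "female")[1]
  hough <- list(min_dist = 40, param2 = 30, r_min = 40, r_max = 85)
  for (i in c(male_i, fem_i)) {
    sp <- ds$specimens[[i]]
    f <- extract_features(sp$back$image, sp$abdomen$image, ds$template,
                          weight_g = ds$features$weight_g[i],
                          cm_per_px = ds$cm_per_px, hough = hough)
    expect_equal(f$gender, ds$features$gender[i])
    expect_equal(f$fatness_pct, ds$features$fatness_pct[i],
                 tolerance = 0.1)
    expect_equal(f$fatness_pct, 100 * f$weight_g / f$carapace_cm^3)
  }

  # a back view with no disc must fail loudly at the carapace stage
  blank <- matrix(30, 256, 256)
  expect_error(
    extract_features(blank, ds$specimens[[1]]$abdomen$image, ds$template,
                     weight_g = 150, cm_per_px = 0.05, hough = hough),
    "no carapace")
})
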