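test_that("integrated density is the mask sum, additive and linear", {
  img <- matrix(7, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  expect_equal(integrated_density(img, mask), 7 * 36)

  one <- matrix(FALSE, 20, 20); one[3, 3] <- TRUE
  img[3, 3] <- 42.5
  expect_equal(integrated_density(img, one), 42.5)

  expect_error(integrated_density(img, matrix(FALSE, 20, 20)), "empty")

  set.seed(9)
  img2 <- matrix(runif(400), 20, 20)
  m1 <- matrix(FALSE, 20, 20); m1[1:5, ] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[10:12, ] <- TRUE
  expect_equal(integrated_density(img2, m1) + integrated_density(img2, m2),
               integrated_density(img2, m1 | m2))
  expect_equal(integrated_density(img2 * 3.5, m1),
               3.5 * integrated_density(img2, m1))
})

test_that("circularity matches closed forms for disc, square and line", {
  disc <- matrix(FALSE, 64, 64)
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  disc[(rr - 32)^2 + (cc - 32)^2 <= 20^2] <- TRUE
  expect_gte(circularity(disc), 0.9)
  expect_lte(circularity(disc), 1)

  square <- matrix(FALSE, 120, 120); square[11:110, 11:110] <- TRUE
  expect_lt(abs(circularity(square) - pi / 4), 0.02)

  line <- matrix(FALSE, 10, 30); line[5, 5:24] <- TRUE
  expect_lt(circularity(line), 0.3)
})

test_that("ROI selection caps at the target, flags shortfalls, breaks ties deterministically", {
  mk <- function(n, comp, circ, area = 100) {
    data.frame(label = seq_len(n), compartment = comp,
               circularity = circ, area_um2 = area,
               integrated_density = runif(n))
  }
  set.seed(4)
  cells <- rbind(mk(30, "humeral", runif(30, 0.85, 1)),
                 mk(12, "glenoid", runif(12, 0.85, 1)))
  sel <- select_rois(cells, circularity_min = 0.8, n_target = 20)
  expect_identical(sum(sel$selected$compartment == "humeral"), 20L)
  expect_identical(sum(sel$selected$compartment == "glenoid"), 12L)
  expect_identical(sel$under_target, c(humeral = FALSE, glenoid = TRUE))

  # sub-threshold cells never qualify
  low <- mk(5, "humeral", rep(0.5, 5))
  expect_identical(nrow(select_rois(low, 0.8, 20)$selected), 0L)

  # exact circularity ties: larger area first, then lower label
  tied <- mk(3, "humeral", rep(0.9, 3))
  tied$area_um2 <- c(50, 80, 80)
  s1 <- select_rois(tied, 0.8, 2)$selected
  expect_identical(s1$label, c(2L, 3L))
  s2 <- select_rois(tied, 0.8, 2)$selected
  expect_identical(s1, s2)
})

test_that("joint score sums compartment means and normalizes to control", {
  js <- joint_score(c(humeral = 10, glenoid = 6), control_joint = 16)
  expect_equal(js$joint, 16)
  expect_equal(js$normalized, 1)
  expect_equal(joint_score(c(humeral = 10, glenoid = NA))$joint, 10)
  expect_error(joint_score(c(humeral = 10), control_joint = 0), "positive")
  expect_error(joint_score(c(humeral = NA_real_)), "defined")
})

test_that("quantification of a noise-free generator field reproduces truth exactly", {
  sp <- if_field_spec(n_cells = c(humeral = 12, glenoid = 12),
                      noise_sd = 0, background_level = 0, seed = 31)
  fld <- generate_if_field(sp)
  res <- analyze_if_field(fld$image, fld$compartment_masks,
                          circularity_min = 0, n_target = 50)
  expect_identical(nrow(res$cells), nrow(fld$truth))
  for (i in seq_len(nrow(res$cells))) {
    d <- sqrt((fld$truth$row - res$cells$centroid_row[i])^2 +
              (fld$truth$col - res$cells$centroid_col[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_equal(res$cells$integrated_density[i],
                 fld$truth$integrated_density[j], tolerance = 1e-12)
    expect_identical(res$cells$compartment[i], fld$truth$compartment[j])
  }
})

test_that("normalized joint score recovers a simulated expression ratio", {
  ratios <- numeric(4)
  for (s in seq_along(ratios)) {
    sham_spec <- if_field_spec(n_cells = c(humeral = 28, glenoid = 28),
                               intensity_mean = c(humeral = 100, glenoid = 100),
                               width = 640, height = 320, seed = 100 + s)
    inj_spec <- if_field_spec(n_cells = c(humeral = 28, glenoid = 28),
                              intensity_mean = c(humeral = 60, glenoid = 60),
                              intensity_sd = c(humeral = 9, glenoid = 9),
                              width = 640, height = 320, seed = 200 + s)
    sham <- generate_if_field(sham_spec); inj <- generate_if_field(inj_spec)
    r_sham <- analyze_if_field(sham$image, sham$compartment_masks,
                               background = 10)
    r_inj <- analyze_if_field(inj$image, inj$compartment_masks,
                              background = 10,
                              control_joint = r_sham$joint_score)
    # control normalized against itself is exactly 1
    self <- analyze_if_field(sham$image, sham$compartment_masks,
                             background = 10,
                             control_joint = r_sham$joint_score)
    expect_identical(self$normalized_score, 1)
    ratios[s] <- r_inj$normalized_score
  }
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.6), 3 * max(se, 0.02))
})
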