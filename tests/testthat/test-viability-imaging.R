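test_that("maximum intensity projection collapses planes correctly", {
  set.seed(1)
  # single plane: identity
  m <- matrix(runif(64), 8, 8)
  s1 <- micrograph_stack(array(m, c(8, 8, 1, 1)), "live", 1)
  expect_equal(max_intensity_projection(s1, "live"), m)

  # two planes: elementwise max
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  s2 <- micrograph_stack(array(c(a, b), c(8, 8, 1, 2)), "live", 1)
  expect_equal(max_intensity_projection(s2, "live"), pmax(a, b))

  # five planes: explicit loop oracle, and idempotence
  arr <- array(runif(8 * 8 * 5), c(8, 8, 1, 5))
  s5 <- micrograph_stack(arr, "live", 1)
  oracle <- matrix(-Inf, 8, 8)
  for (z in 1:5) for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- max(oracle[i, j], arr[i, j, 1, z])
  mip <- max_intensity_projection(s5, "live")
  expect_equal(mip, oracle)
  expect_equal(max_intensity_projection(
    micrograph_stack(array(mip, c(8, 8, 1, 1)), "live", 1), "live"), mip)

  expect_error(max_intensity_projection(s5, "dead"), "live")
})

test_that("Otsu threshold maximizes between-class variance", {
  # two-valued image: clean separation
  img <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  t2 <- otsu_threshold(img)
  expect_gt(t2, 0); expect_lt(t2, 100)
  expect_identical(img > t2, img == 100)

  # exhaustive-scan oracle on random 8-bit images
  set.seed(42)
  for (rep in 1:10) {
    v <- sample(0:255, 4096, replace = TRUE,
                prob = runif(256)^sample(1:3, 1))
    img8 <- matrix(v, 64, 64)
    t_pkg <- otsu_threshold(img8)
    t_ora <- otsu_bruteforce(v)
    expect_identical(floor(t_pkg), as.numeric(t_ora))
    expect_identical(img8 > t_pkg, img8 > t_ora)
  }

  # bimodal mixture: no other candidate cut misclassifies fewer pixels
  set.seed(7)
  lab <- rep(0:1, each = 5000)
  v <- round(pmin(pmax(rnorm(10000, ifelse(lab == 1, 180, 30), 10), 0), 255))
  t_mix <- otsu_threshold(matrix(v, 100, 100))
  mis <- function(t) sum((v > t) != lab)
  expect_true(all(mis(t_mix) <= vapply(0:254, mis, numeric(1))))

  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("watershed segmentation recovers discs and splits touching pairs", {
  centers <- rbind(c(30, 30), c(30, 90), c(90, 45), c(95, 100), c(60, 65))
  radii <- c(8, 10, 7, 9, 6)
  img <- disc_image(centers, radii, 128, 128)
  seg <- segment_cells(img > 0, pixel_size = 1, min_cell_area = 20)
  expect_identical(nrow(seg$cells), 5L)
  m <- match_centroids(seg$cells, data.frame(row = centers[, 1], col = centers[, 2]), 1)
  expect_identical(m$tp, 5L)
  ord <- order(seg$cells$centroid_row)
  for (i in seq_len(5)) {
    j <- which.min((centers[, 1] - seg$cells$centroid_row[i])^2 +
                   (centers[, 2] - seg$cells$centroid_col[i])^2)
    expect_lt(abs(seg$cells$area_um2[i] / (pi * radii[j]^2) - 1), 0.05)
  }

  # two discs overlapping by less than one radius are split in two
  img2 <- disc_image(rbind(c(40, 40), c(40, 53)), c(8, 8), 80, 80)
  seg2 <- segment_cells(img2 > 0, pixel_size = 1, min_cell_area = 20)
  expect_identical(nrow(seg2$cells), 2L)

  # empty foreground: zero labels, no error
  seg0 <- segment_cells(matrix(FALSE, 32, 32))
  expect_identical(nrow(seg0$cells), 0L)
  expect_true(all(seg0$labels == 0L))
})

test_that("area filtering only removes labels and keeps label-pixel consistency", {
  centers <- rbind(c(20, 20), c(20, 60), c(60, 20), c(60, 60))
  radii <- c(2, 4, 7, 9)   # first two below the 20 um^2 / r~2.5 cut
  img <- disc_image(centers, radii, 96, 96)
  seg_all <- segment_cells(img > 0, min_cell_area = 0)
  seg_flt <- segment_cells(img > 0, min_cell_area = 60)
  expect_lte(nrow(seg_flt$cells), nrow(seg_all$cells))
  expect_true(all(seg_flt$cells$area_um2 >= 60))
  # every surviving label owns pixels, and pixel counts match the table
  px <- tabulate(seg_flt$labels[seg_flt$labels > 0])
  expect_identical(length(px), nrow(seg_flt$cells))
  expect_true(all(px > 0))
  expect_equal(seg_flt$cells$area_px, px)
})

test_that("live/dead classification follows scaled channel dominance", {
  img <- disc_image(rbind(c(20, 20), c(20, 60)), c(8, 8), 40, 80)
  seg <- segment_cells(img > 0)
  live <- disc_image(rbind(c(20, 20)), 8, 40, 80, level = 150) +
    matrix(runif(40 * 80, 0, 1), 40, 80)
  dead <- disc_image(rbind(c(20, 60)), 8, 40, 80, level = 90) +
    matrix(runif(40 * 80, 0, 1), 40, 80)
  cls <- classify_viability(seg, live, dead)$cells
  left <- which.min(cls$centroid_col)
  expect_identical(cls$class[left], "live")
  expect_identical(cls$class[-left], "dead")
})

test_that("classification accuracy on generator fields meets the assay bar", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    sp <- impact_spec(small_field(seed = seed, n_cells = 50),
                      impact_radius = 40)
    pair <- generate_impact_pair(sp)
    va <- analyze_viability_pair(pair$pre, pair$post)
    tr <- pair$truth
    shift <- attr(tr, "post_shift")
    cells <- va$post_seg$cells
    for (i in seq_len(nrow(cells))) {
      d <- sqrt((tr$row + shift[1] - cells$centroid_row[i])^2 +
                (tr$col + shift[2] - cells$centroid_col[i])^2)
      j <- which.min(d)
      if (d[j] <= tr$radius_px[j]) {
        total <- total + 1L
        if (cells$class[i] == tr$post_state[j]) hits <- hits + 1L
      }
    }
  }
  expect_gt(total, 100)
  expect_gte(hits / total, 0.98)
})

test_that("registration recovers translations and is inverse-symmetric", {
  set.seed(5)
  img <- disc_image(cbind(runif(25, 15, 110), runif(25, 15, 110)),
                    runif(25, 4, 7), 128, 128, level = 200, background = 10)
  # identical images
  id <- register_roi(img, img, max_shift = 20)
  expect_equal(id$offset, c(0, 0))
  expect_equal(id$score, 1)

  # constructed shift (+3, -2) with zero padding
  shifted <- matrix(0, 128, 128)
  shifted[4:128, 1:126] <- img[1:125, 3:128]
  al <- register_roi(img, shifted, max_shift = 20)
  expect_equal(al$offset, c(3, -2))

  # inverse symmetry on a noise-free generator pair
  sp <- impact_spec(clean_field(seed = 6), post_shift = c(7, -5))
  pair <- generate_impact_pair(sp)
  pre <- max_intensity_projection(pair$pre, "live") +
    max_intensity_projection(pair$pre, "dead")
  post <- max_intensity_projection(pair$post, "live") +
    max_intensity_projection(pair$post, "dead")
  fwd <- register_roi(pre, post, max_shift = 20)
  rev <- register_roi(post, pre, max_shift = 20)
  expect_equal(fwd$offset, c(7, -5))
  expect_equal(rev$offset, -fwd$offset)

  # offset bound is enforced
  expect_true(all(abs(fwd$offset) <= 20))
})

test_that("death-area accounting matches identity, single-flip and truth cases", {
  # post identical to pre: zero death area
  sp0 <- impact_spec(clean_field(seed = 10), death_probability_inside = 0,
                     death_probability_outside = 0, post_shift = c(0, 0))
  pair0 <- generate_impact_pair(sp0)
  va0 <- analyze_viability_pair(pair0$pre, pair0$post)
  expect_identical(va0$result$death_area_um2, 0)
  expect_identical(va0$result$death_area_raw_um2, 0)

  # exactly one disc flips to dead: death area ~ pi r^2 within 5%
  fld <- clean_field(seed = 12, n_cells = 12)
  sp1 <- impact_spec(fld, impact_radius = 1e-3, post_shift = c(0, 0),
                     death_probability_outside = 0,
                     death_probability_inside = 0)
  pair1 <- generate_impact_pair(sp1)
  tr <- pair1$truth
  flip <- which.min((tr$row - 96)^2 + (tr$col - 96)^2)
  tr$post_state[flip] <- "dead"
  post1 <- rasterize_truth(tr, fld, "post")
  va1 <- analyze_viability_pair(pair1$pre, post1)
  expect_lt(abs(va1$result$death_area_um2 / (pi * tr$radius_um[flip]^2) - 1),
            0.05)

  # generator truth: all cells inside the impact radius die
  sp2 <- impact_spec(small_field(seed = 13), impact_radius = 55,
                     death_probability_inside = 1,
                     death_probability_outside = 0)
  pair2 <- generate_impact_pair(sp2)
  va2 <- analyze_viability_pair(pair2$pre, pair2$post)
  truth_dead <- sum(pair2$truth$area_um2[pair2$truth$post_state == "dead"])
  expect_gt(truth_dead, 0)
  expect_lt(abs(va2$result$death_area_um2 / truth_dead - 1), 0.10)
})
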