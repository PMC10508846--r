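test_that("impact-pair generation is deterministic and truth-consistent", {
  sp <- impact_spec(clean_field(seed = 7), post_shift = c(4, -3))
  a <- generate_impact_pair(sp)
  b <- generate_impact_pair(sp)
  expect_identical(a, b)

  # truth record rasterizes back to the noise-free images exactly
  expect_equal(a$pre$data, rasterize_truth(a$truth, sp$field, "pre")$data)
  expect_equal(a$post$data, rasterize_truth(a$truth, sp$field, "post")$data)

  # label conservation and geometry invariants
  expect_identical(nrow(a$truth), sp$field$n_cells)
  d <- as.matrix(dist(a$truth[, c("row", "col")]))
  diag(d) <- Inf
  rsum <- outer(a$truth$radius_px, a$truth$radius_px, "+")
  expect_true(all(d > rsum))
})

test_that("cap mask restricts cell placement", {
  cap <- make_cap_mask(192, 192, radius_frac = 0.3)
  sp <- impact_spec(small_field(seed = 2, n_cells = 15, cap_mask = cap))
  tr <- generate_impact_pair(sp)$truth
  for (i in seq_len(nrow(tr)))
    expect_true(cap[round(tr$row[i]), round(tr$col[i])])
})

test_that("death states follow position-dependent probabilities and the seeded draw", {
  # deterministic limits: certain death inside, none outside
  sp <- impact_spec(clean_field(seed = 3), impact_radius = 50,
                    death_probability_inside = 1,
                    death_probability_outside = 0)
  tr <- generate_impact_pair(sp)$truth
  expect_true(all(tr$post_state[tr$inside_impact] == "dead"))
  expect_true(all(tr$post_state[!tr$inside_impact] == "live"))

  # no death at all: post equals pre translated by post_shift
  sp0 <- impact_spec(clean_field(seed = 3), death_probability_inside = 0,
                     death_probability_outside = 0, post_shift = c(6, 5))
  pair0 <- generate_impact_pair(sp0)
  h <- sp0$field$height; w <- sp0$field$width
  pre_live <- pair0$pre$data[1:(h - 6), 1:(w - 5), 1, ]
  post_live <- pair0$post$data[7:h, 6:w, 1, ]
  expect_equal(post_live, pre_live)
  expect_true(all(pair0$post$data[, , 2, ] == 0))

  # seeded Bernoulli oracle: replay the death-stream draw directly
  fld <- small_field(seed = 11, n_cells = 60)
  sp5 <- impact_spec(fld, impact_radius = 500,
                     death_probability_inside = 0.5,
                     death_probability_outside = 0.5)
  tr5 <- generate_impact_pair(sp5)$truth
  set.seed(fld$seed + 1L)
  oracle <- runif(60) < 0.5
  expect_identical(tr5$post_state == "dead", oracle)
})

test_that("impossible placements fail with an explicit constraint error", {
  sp <- small_field(seed = 1, width = 64, height = 64, n_cells = 200)
  expect_error(generate_impact_pair(impact_spec(sp)), "non-overlap")
})

test_that("trace generator honours labels, amplitudes and degenerate contracts", {
  # no responders
  tr0 <- generate_traces(trace_sim_spec(n_cells = 30, responder_fraction = 0,
                                        seed = 4))
  expect_false(any(tr0$truth$responsive))

  # noise-free responder: sampled peak is exactly amplitude above baseline;
  # with baseline_sd = 0 the amplitude is defined relative to sd_floor
  spd <- trace_sim_spec(n_cells = 5, baseline_sd = 0, sd_floor = 0.5,
                        response_amplitude_in_sd = 10,
                        responder_fraction = 1, seed = 9)
  trd <- generate_traces(spd)
  for (i in 1:5)
    expect_equal(max(trd$traces$traces[, i]) - spd$baseline_mean, 10 * 0.5)

  # seeded replay oracle for responder labels
  sp3 <- trace_sim_spec(n_cells = 100, responder_fraction = 0.3, seed = 21)
  tr3 <- generate_traces(sp3)
  set.seed(21 + 1L)
  expect_identical(tr3$truth$responsive, runif(100) < 0.3)

  expect_error(trace_sim_spec(sample_interval = 0), "sample_interval")
  expect_identical(generate_traces(sp3), generate_traces(sp3))
})

test_that("IF generator records analytic integrated densities and compartments", {
  # one uniform elliptical cell, noise- and background-free: density = I * A
  sp1 <- if_field_spec(n_cells = c(humeral = 1, glenoid = 0),
                       intensity_sd = c(humeral = 0, glenoid = 0),
                       noise_sd = 0, background_level = 0, seed = 5)
  f1 <- generate_if_field(sp1)
  img <- max_intensity_projection(f1$image, "expression")
  expect_identical(nrow(f1$truth), 1L)
  expect_equal(f1$truth$integrated_density, sum(img))
  expect_equal(f1$truth$integrated_density,
               f1$truth$intensity * f1$truth$area_px)

  # empty compartment is allowed
  expect_identical(sum(f1$truth$compartment == "glenoid"), 0L)

  # identical distributions: compartment truth means differ only by
  # sampling error (closed-form standard error of the difference)
  sp2 <- if_field_spec(n_cells = c(humeral = 30, glenoid = 30),
                       intensity_mean = c(humeral = 100, glenoid = 100),
                       intensity_sd = c(humeral = 15, glenoid = 15),
                       width = 640, height = 320, seed = 6)
  tr <- generate_if_field(sp2)$truth
  m <- tapply(tr$intensity, tr$compartment, mean)
  se_diff <- sqrt(15^2 / 30 + 15^2 / 30)
  expect_lt(abs(m[["humeral"]] - m[["glenoid"]]), 3 * se_diff)

  # determinism
  expect_identical(generate_if_field(sp2), generate_if_field(sp2))
})

test_that("micrograph TIFF round trip preserves geometry and intensities", {
  sp <- impact_spec(small_field(seed = 8, n_cells = 10))
  pre <- generate_impact_pair(sp)$pre
  path <- file.path(tempdir(), "roundtrip.tif")
  write_micrograph(pre, path)
  back <- read_micrograph(path)
  expect_identical(dim(back$data), dim(pre$data))
  expect_identical(back$channel_names, pre$channel_names)
  expect_equal(back$pixel_size, pre$pixel_size)
  expect_lt(max(abs(back$data - pre$data)), max(pre$data) * 2e-5)
  unlink(c(path, paste0(path, ".json")))
})

test_that("trace CSV round trip preserves the set", {
  tr <- generate_traces(trace_sim_spec(n_cells = 8, seed = 3))$traces
  path <- file.path(tempdir(), "traces.csv")
  write_traces_csv(tr, path)
  back <- read_traces_csv(path, treatment_time = tr$treatment_time)
  expect_equal(back$time, tr$time)
  expect_equal(back$traces, tr$traces, tolerance = 1e-12)
  unlink(path)
})
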