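test_that("cohort generation is deterministic and respects degenerate SDs", {
  a <- generate_cohort(c(healthy = 8, FFKC = 6, KC = 8), seed = 11)
  b <- generate_cohort(c(healthy = 8, FFKC = 6, KC = 8), seed = 11)
  expect_identical(a, b)
  d <- generate_cohort(c(healthy = 8, FFKC = 6, KC = 8), seed = 12)
  expect_false(identical(a, d))

  gc <- cohort_defaults()
  for (v in names(gc$healthy)) gc$healthy[[v]]["sd"] <- 0
  degen <- generate_cohort(c(healthy = 5), gc["healthy"], seed = 1)
  expect_equal(unique(degen$CCT), 534.5)
  expect_equal(unique(degen$E_true), 0.35)
})

test_that("cohort sampling reproduces the target group means within 2%", {
  coh <- generate_cohort(c(healthy = 5000, FFKC = 5000, KC = 5000), seed = 5)
  gc <- cohort_defaults()
  for (g in names(gc)) {
    rows <- coh[coh$group == g, ]
    for (v in c("CCT", "R", "bIOP", "SP_A1", "ARTh")) {
      expect_equal(mean(rows[[v]]), unname(gc[[g]][[v]]["mean"]),
                   tolerance = 0.02,
                   label = sprintf("%s mean of %s", g, v))
    }
    expect_equal(mean(rows$E_true), unname(gc[[g]]$E["mean"]),
                 tolerance = 0.02, label = paste(g, "E mean"))
    # moment matching also preserves the SD despite truncation
    expect_equal(sd(rows$R), unname(gc[[g]]$R["sd"]), tolerance = 0.05,
                 label = paste(g, "R sd"))
  }
  # truncation bounds are respected
  expect_true(all(coh$R >= 4 & coh$R <= 10))
  expect_true(all(coh$bIOP >= 5 & coh$bIOP <= 40))
})

test_that("invalid group configs are rejected", {
  gc <- cohort_defaults()
  gc$healthy$E["sd"] <- -1
  expect_error(generate_cohort(c(healthy = 5), gc, seed = 1), "negative SD")
  expect_error(generate_cohort(c(healthy = 0), seed = 1), "n_per_group")
  expect_error(generate_cohort(c(nosuch = 5), seed = 1), "no config")
})

test_that("a force-free, noise-free, motion-free examination is static", {
  sub <- template_subject()
  ap <- airpuff_config(peak_pressure = 1e-9)
  ex <- simulate_examination(sub, ap,
                             sim_config(sigma_noise = 0, eye_motion_a = 0))
  expect_lt(max(abs(ex$surface - ex$surface[, 1])), 1e-9)
})

test_that("the linear regime reproduces delta = f/k and E ordering drives deformation", {
  # small forces keep delta below the saturation knee
  ap <- airpuff_config(peak_pressure = 2)
  sub <- template_subject()
  ex <- simulate_examination(sub, ap, sim_config(sigma_noise = 0))
  k <- ex$truth$k_true
  expect_equal(ex$truth$delta_true, apex_force(ap, ex$time) / k,
               tolerance = 1e-12)
  tr <- extract_apex_trace(ex)
  expect_equal(tr$deformation, apex_force(ap, ex$time) / k,
               tolerance = 1e-9)

  soft <- simulate_examination(template_subject(E = 0.16),
                               sim = sim_config(sigma_noise = 0))
  stiff <- simulate_examination(template_subject(E = 0.35),
                                sim = sim_config(sigma_noise = 0))
  expect_gt(max(soft$truth$delta_true), max(stiff$truth$delta_true))
})

test_that("examinations are deterministic given the subject seed", {
  sub <- template_subject(seed = 77L)
  e1 <- simulate_examination(sub)
  e2 <- simulate_examination(sub)
  expect_identical(e1$surface, e2$surface)
  e3 <- simulate_examination(template_subject(seed = 78L))
  expect_false(identical(e1$surface, e3$surface))
})

test_that("frame 0 is the undeformed arc within noise", {
  sub <- template_subject()
  ex <- simulate_examination(sub, sim = sim_config(sigma_noise = 0))
  arc <- sqrt(pmax(sub$R^2 - ex$x^2, 0)) - sub$R
  expect_lt(max(abs(ex$surface[, 1] - arc)), 1e-12)
  exn <- simulate_examination(sub)
  expect_lt(max(abs(exn$surface[, 1] - arc)), 5 * 0.002)
})

test_that("a saturation cap below the slope window raises a simulation warning", {
  expect_warning(
    simulate_examination(template_subject(),
                         sim = sim_config(da_max_frac = 0.09,
                                          knee_frac = 0.2,
                                          sigma_noise = 0)),
    "slope window|knee")
})

test_that("examination containers round-trip through plain-text files", {
  dir <- withr::local_tempdir()
  ex <- simulate_examination(template_subject(seed = 3L))
  write_examination(ex, file.path(dir, "s1"))
  back <- read_examination(file.path(dir, "s1"))
  expect_equal(back$surface, unname(ex$surface), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$time, ex$time)
  expect_equal(back$truth$E_true, ex$truth$E_true)
  expect_equal(back$truth$k_true, ex$truth$k_true)
  # extraction gives the same modulus from the re-read container
  expect_equal(extract_subject(back)$E, extract_subject(ex)$E,
               tolerance = 1e-9)
})

test_that("rasterized frames round-trip through edge detection", {
  ex <- simulate_examination(template_subject(), sim = sim_config(sigma_noise = 0))
  stack <- rasterize_frames(ex, image_config(noise_sd = 0))
  got <- redetect_surface(stack)
  expect_lt(max(abs(got - ex$surface)), 0.5 * stack$mm_per_px)

  # blank band: no edge anywhere
  blank <- rasterize_frames(ex, image_config(band_intensity = 0))
  expect_error(detect_edge(blank$frames[[1]], blank$y0_mm, blank$mm_per_px),
               "no edge")
  # unrepresentable band
  expect_error(image_config(band_px = 0.5), "band")
})

test_that("noisy rasterization keeps sub-pixel accuracy and DCR timing", {
  ex <- simulate_examination(template_subject(seed = 9L),
                             sim = sim_config(sigma_noise = 0))
  stack <- rasterize_frames(ex, image_config(noise_sd = 0.05), seed = 4L)
  got <- redetect_surface(stack)
  expect_lt(median(abs(got - ex$surface)), stack$mm_per_px)

  # A1T from the re-detected surface within one frame of the direct one
  ex2 <- ex
  ex2$surface <- got
  a1_direct <- detect_events(extract_apex_trace(ex), ex)$A1T
  a1_raster <- detect_events(extract_apex_trace(ex2), ex2)$A1T
  expect_lt(abs(a1_direct - a1_raster), diff(ex$time[1:2]))
})
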