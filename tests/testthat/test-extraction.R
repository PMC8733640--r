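test_that("whole-eye-motion correction isolates the true deformation", {
  # no eye motion: estimated motion is ~0 and deformation matches truth
  ex <- simulate_examination(template_subject(),
                             sim = sim_config(eye_motion_a = 0,
                                              sigma_noise = 0))
  tr <- extract_apex_trace(ex)
  expect_lt(max(abs(tr$eye_motion)), 1e-12)
  expect_lt(max(abs(tr$deformation - ex$truth$delta_true)), 1e-12)

  # pure eye motion, essentially no force: deformation ~ 0 everywhere
  ap0 <- airpuff_config(peak_pressure = 1e-9)
  ex2 <- simulate_examination(template_subject(), ap0,
                              sim_config(sigma_noise = 0))
  tr2 <- extract_apex_trace(ex2)
  expect_lt(max(abs(tr2$deformation)), 1e-9)
  expect_equal(tr2$eye_motion, 1e-4 * ex2$time^2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # default noisy simulation stays within noise tolerance of the truth
  ex3 <- simulate_examination(template_subject(seed = 5L))
  tr3 <- extract_apex_trace(ex3)
  expect_lt(max(abs(tr3$deformation - ex3$truth$delta_true)),
            3 * ex3$truth$sigma_noise * 2)
  expect_error(extract_apex_trace(ex3, x_periph = 10), "peripheral")
})

test_that("quadratic whole-eye drift leaves the extracted deformation unchanged", {
  sub <- template_subject(seed = 21L)
  still <- simulate_examination(sub, sim = sim_config(eye_motion_a = 0))
  drift <- simulate_examination(sub, sim = sim_config(eye_motion_a = 5e-4))
  d_still <- extract_apex_trace(still)$deformation
  d_drift <- extract_apex_trace(drift)$deformation
  expect_lt(max(abs(d_still - d_drift)), 3 * still$truth$sigma_noise)
})

test_that("event detection recovers applanations, concavity peak and signs", {
  ex <- simulate_examination(template_subject(),
                             sim = sim_config(sigma_noise = 0))
  tr <- extract_apex_trace(ex)
  dcr <- detect_events(tr, ex)
  expect_true(dcr$A1T < dcr$HCT && dcr$HCT < dcr$A2T)
  # symmetric pulse, no noise: highest concavity at the force peak
  expect_equal(dcr$HCT, 15, tolerance = diff(ex$time[1:2]))
  expect_gt(dcr$A1V, 0)
  expect_lt(dcr$A2V, 0)
  expect_gt(dcr$DA, 0)
  expect_gt(dcr$PD, 0)
  expect_equal(dcr$DA, max(ex$truth$delta_true), tolerance = 0.05)
  expect_length(dcr$quality_flags, 0)
  # SP-A1 style index present when bIOP is known
  expect_true(is.finite(dcr$SPA1))
})

test_that("event detection errors on monotone or never-applanating traces", {
  # stiff cornea under a weak puff never flattens
  ap <- airpuff_config(peak_pressure = 0.5)
  ex <- simulate_examination(template_subject(E = 0.5), ap,
                             sim_config(sigma_noise = 0))
  tr <- extract_apex_trace(ex)
  expect_error(detect_events(tr, ex), "not applanated|no concave")
})

test_that("constructed-applanation exams pin A1T and noise keeps it sub-frame", {
  ex <- construct_applanation_exam(7.33, sigma_noise = 0)
  # truth timing is interpolated on the frame grid: exact to ~1e-3 ms
  expect_equal(ex$truth$A1T_true, 7.33, tolerance = 1e-3)
  dcr <- detect_events(extract_apex_trace(ex), ex)
  frame <- diff(ex$time[1:2])
  expect_lt(abs(dcr$A1T - 7.33), frame)

  errs <- vapply(1:20, function(s) {
    exn <- construct_applanation_exam(7.33, seed = s, sigma_noise = 0.002)
    d <- detect_events(extract_apex_trace(exn), exn)
    abs(d$A1T - exn$truth$A1T_true)
  }, numeric(1))
  expect_lt(median(errs), 0.25 * frame)
})

test_that("force-displacement pairing flags phases and aligns grids", {
  ap <- airpuff_config(peak_pressure = 2)  # stay linear
  ex <- simulate_examination(template_subject(), ap,
                             sim_config(sigma_noise = 0))
  tr <- extract_apex_trace(ex)
  cv <- force_displacement(tr, ap)
  # all points collinear through the origin with slope k
  sel <- cv$delta > 1e-6
  expect_lt(max(abs(cv$force[sel] / cv$delta[sel] - ex$truth$k_true)) /
              ex$truth$k_true, 1e-9)
  # phase switches exactly once at the deformation maximum
  expect_equal(sum(diff(cv$phase == "loading") != 0), 1)
  expect_equal(which.max(cv$delta), sum(cv$phase == "loading"))

  ap2 <- airpuff_config(duration = 30)
  expect_error(force_displacement(tr, ap2), "not aligned")

  # zero force: all-zero curve
  ex0 <- simulate_examination(template_subject(),
                              airpuff_config(peak_pressure = 1e-9),
                              sim_config(sigma_noise = 0))
  cv0 <- force_displacement(extract_apex_trace(ex0),
                            airpuff_config(peak_pressure = 1e-9))
  expect_lt(max(abs(cv0$force)), 1e-8)
  expect_lt(max(abs(cv0$delta)), 1e-8)
})

test_that("window slope fitting matches hand-built lines and OLS symmetry", {
  line <- data.frame(delta = c(0.20, 0.30, 0.40), force = c(2, 3, 4),
                     phase = "loading")
  st <- stiffness_slope(line)
  expect_equal(st$S_TSC, 10.0)
  expect_equal(st$fit_r2, 1.0)
  expect_equal(st$n_points, 3)
  # symmetric +/- eps perturbation on the outer points leaves the slope
  pert <- line
  pert$force <- pert$force + c(0.05, 0, -0.05) * c(1, 0, 1)
  expect_equal(stiffness_slope(pert)$S_TSC,
               cov(pert$delta, pert$force) / var(pert$delta))
  pert2 <- line
  pert2$force <- line$force + c(+0.05, 0, +0.05)
  expect_equal(stiffness_slope(pert2)$S_TSC, 10.0)

  few <- data.frame(delta = c(0.25, 0.35), force = c(1, 2), phase = "loading")
  expect_error(stiffness_slope(few), class = "insufficient_window")
  unload <- data.frame(delta = c(0.2, 0.3, 0.4), force = 1:3,
                       phase = "unloading")
  expect_error(stiffness_slope(unload), class = "insufficient_window")
})

test_that("noiseless extraction reproduces the forward stiffness and modulus", {
  g <- cornea_geometry(7.75, 0.5345)
  ex <- simulate_examination(template_subject(E = 0.35),
                             sim = sim_config(sigma_noise = 0))
  st <- stiffness_slope(force_displacement(extract_apex_trace(ex),
                                           ex$airpuff))
  expect_equal(st$S_TSC, forward_stiffness(0.35, g, 1.25),
               tolerance = 0.005)
  row <- extract_subject(ex)
  expect_equal(row$E, 0.35, tolerance = 1e-9)
  expect_equal(row$R_fit, 7.75, tolerance = 1e-6)
})

test_that("effective puff radius finds constructed flat zones and falls back", {
  ex <- simulate_examination(template_subject(),
                             sim = sim_config(sigma_noise = 0))
  # construct a frame that is exactly flat over |x| <= 1.25
  flat <- ex
  y <- sqrt(pmax(7.75^2 - ex$x^2, 0)) - 7.75
  y[abs(ex$x) <= 1.25] <- y[max(which(abs(ex$x) <= 1.25))]
  flat$surface[, 10] <- y
  rp <- effective_puff_radius(flat, A1T = flat$time[10])
  dx <- diff(ex$x[1:2])
  expect_equal(rp, 1.25, tolerance = 2 * dx)

  # undeformed frame: nothing flat, configured fallback with warning
  expect_warning(rp0 <- effective_puff_radius(ex, A1T = 0), "no flattened")
  expect_equal(rp0, ex$airpuff$rp)
})

test_that("cohort extraction keeps event ordering and QC accounting", {
  coh <- generate_cohort(c(healthy = 4, FFKC = 3, KC = 4), seed = 19)
  exams <- lapply(seq_len(nrow(coh)), function(i)
    simulate_examination(coh[i, ]))
  res <- extract_cohort(exams)
  expect_equal(nrow(res), nrow(coh))
  ok <- res$quality_flags == ""
  expect_true(all(res$A1T[ok] < res$HCT[ok]))
  expect_true(all(res$HCT[ok] < res$A2T[ok]))
  expect_true(all(res$S_TSC[ok] > 0))
  expect_true(all(res$fit_r2[ok] >= 0 & res$fit_r2[ok] <= 1))
})
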