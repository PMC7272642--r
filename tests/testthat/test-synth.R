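# Synthetic cohort generator: geometry, source simulation, forward
# projection, noise and artifacts, cohort bundling.

test_that("geometry is deterministic and every region is populated", {
  g1 <- make_geometry(160, 1000, 68, seed = 1)
  g2 <- make_geometry(160, 1000, 68, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$sensors$position), 160)
  expect_equal(nrow(g1$head$vertices), 1000)
  expect_true(all(table(g1$head$region) > 0))
  expect_equal(nlevels(g1$head$region), 68)
  # invariants
  expect_true(all(sqrt(rowSums(g1$head$vertices^2)) < g1$head$sphere_radius))
  expect_true(all(sqrt(rowSums(g1$sensors$position^2)) > g1$head$sphere_radius))
  expect_equal(sqrt(rowSums(g1$head$normals^2)), rep(1, 1000), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(g1$sensors$orientation^2)), rep(1, 160),
               tolerance = 1e-9)
  expect_false(any(duplicated(g1$sensors$channel_id)))
})

test_that("n_regions = n_vertices gives singleton regions; oversubscription errors", {
  g <- make_geometry(8, 8, 8, seed = 2)
  expect_equal(as.integer(table(g$head$region)), rep(1L, 8))
  expect_error(make_geometry(8, 7, 8), class = "megspect_invalid_spec")
})

test_that("region labels use the 68 Desikan-Killiany names, left hemisphere first", {
  labs <- region_labels(68)
  expect_length(labs, 68)
  expect_equal(sum(startsWith(labs, "lh_")), 34)
  expect_equal(sum(startsWith(labs, "rh_")), 34)
  expect_true(all(startsWith(labs[1:34], "lh_")))
  expect_true("rh_supramarginal" %in% labs)
  expect_false(any(duplicated(labs)))
})

test_that("zero amplitudes and zero floor give an all-zero source matrix", {
  spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 8, n_vertices = 68,
                      sampling_rate = 50, duration = 4,
                      noise_floor_amplitude = 0)
  spec$band_amplitude_table$mean <- 0
  spec$band_amplitude_table$sd <- 0
  g <- make_geometry(8, 68, 68, seed = 1)
  src <- simulate_source_timecourses(spec, g$head, "NC", "EC", 7)
  expect_equal(max(abs(src$values)), 0)
})

test_that("a single active alpha1 region produces a spectral peak inside 8-10 Hz", {
  fs <- 100
  spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 8, n_vertices = 68,
                      sampling_rate = fs, duration = 30,
                      noise_floor_amplitude = 0)
  tab <- spec$band_amplitude_table
  tab$mean <- ifelse(tab$band == "alpha1" & tab$region == "lh_cuneus",
                     5e-9, 0)
  tab$sd <- 0
  spec$band_amplitude_table <- tab
  g <- make_geometry(8, 68, 68, seed = 1)
  src <- simulate_source_timecourses(spec, g$head, "NC", "EC", 11)
  v <- which(g$head$region == "lh_cuneus")[1]
  x <- src$values[v, ]
  # periodogram oracle: peak frequency bin of |FFT|^2
  pxx <- Mod(fft(x))^2
  k <- 2:(length(x) %/% 2)
  fpeak <- (k[which.max(pxx[k])] - 1) * fs / length(x)
  expect_gt(fpeak, 8)
  expect_lt(fpeak, 10)
  # inactive regions carry nothing
  w <- which(g$head$region != "lh_cuneus")[1]
  expect_equal(max(abs(src$values[w, ])), 0)
})

test_that("eyes-closed activity exceeds eyes-open in every region under defaults", {
  spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 8, n_vertices = 68,
                      sampling_rate = 50, duration = 30)
  g <- make_geometry(8, 68, 68, seed = 1)
  ec <- simulate_source_timecourses(spec, g$head, "NC", "EC", 21)
  eo <- simulate_source_timecourses(spec, g$head, "NC", "EO", 21)
  m_ec <- tapply(rowMeans(abs(ec$values)), g$head$region, mean)
  m_eo <- tapply(rowMeans(abs(eo$values)), g$head$region, mean)
  expect_true(all(m_ec > m_eo))
})

test_that("forward projection is linear and zero for silent sources", {
  s <- tiny_setup()
  g <- s$geometry
  n <- 50
  src0 <- structure(list(values = matrix(0, 68, n), sampling_rate = 50),
                    class = "meg_sources")
  rec0 <- project_to_sensors(src0, g$head, g$sensors, s$L)
  expect_equal(max(abs(rec0$values)), 0)
  vals <- matrix(rnorm(68 * n), 68)
  src1 <- structure(list(values = vals, sampling_rate = 50),
                    class = "meg_sources")
  src2 <- structure(list(values = 2 * vals, sampling_rate = 50),
                    class = "meg_sources")
  r1 <- project_to_sensors(src1, g$head, g$sensors, s$L)
  r2 <- project_to_sensors(src2, g$head, g$sensors, s$L)
  expect_equal(r2$values, 2 * r1$values, tolerance = 1e-12)
  # single active vertex equals its lead-field column times the time course
  tc <- sin(2 * pi * 5 * seq_len(n) / 50)
  one <- matrix(0, 68, n); one[17, ] <- tc
  r3 <- project_to_sensors(
    structure(list(values = one, sampling_rate = 50), class = "meg_sources"),
    g$head, g$sensors, s$L)
  expect_equal(r3$values, unclass(s$L)[, 17] %o% tc, tolerance = 1e-12)
  # dimension mismatch
  expect_error(project_to_sensors(src1, g$head, g$sensors,
                                  unclass(s$L)[, 1:10]),
               class = "megspect_dim_mismatch")
})

test_that("noise/artifact injection is seeded and exceeds the rejection threshold", {
  rec <- sine_recording()
  same <- add_noise_and_artifacts(rec, noise_sd = 0, artifact_rate = 0,
                                  artifact_amplitude = 0, seed = 1)
  expect_equal(same$values, rec$values)
  a <- add_noise_and_artifacts(rec, 1e-14, 30, 12e-12, seed = 5)
  b <- add_noise_and_artifacts(rec, 1e-14, 30, 12e-12, seed = 5)
  expect_identical(a$values, b$values)
  expect_gt(nrow(a$artifact_log), 0)
  on1 <- a$artifact_log$onset_sample[1]
  ch1 <- a$artifact_log$channel[1]
  expect_gt(max(abs(a$values[ch1, on1:(on1 + 4)])), 10e-12)
})

test_that("artifact counts follow the Poisson rate", {
  # 2-minute recording at 3 events/min: mean count 6
  rec <- meg_recording(matrix(0, 2, 2400), 20, "S01", "EC")
  counts <- vapply(1:200, function(s) {
    nrow(add_noise_and_artifacts(rec, 0, 3, 12e-12, seed = s)$artifact_log)
  }, numeric(1))
  se <- sqrt(6 / 200)
  expect_lt(abs(mean(counts) - 6), 3 * se)
})

test_that("subject amplitude draws honor the table and the AD effect cell", {
  spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 8, n_vertices = 68,
                      sampling_rate = 50, duration = 4)
  expect_error(subject_amplitudes(spec, "XX", "EC", 1),
               class = "megspect_invalid_label")
  expect_error(subject_amplitudes(spec, "AD", "closed", 1),
               class = "megspect_invalid_label")
  # cohort-mean amplitude approaches the table mean (unit-mean factor)
  draws <- sapply(1:300, function(s)
    subject_amplitudes(spec, "NC", "EC", s)["lh_cuneus", "alpha1"])
  expect_equal(mean(draws), 8e-9, tolerance = 0.05)
  expect_equal(sd(draws) / mean(draws), 0.2, tolerance = 0.15)
  # designated AD cell raised by 2 between-subject SDs (factor 1.4)
  ad <- subject_amplitudes(spec, "AD", "EC", 9)
  nc <- subject_amplitudes(spec, "NC", "EC", 9)
  expect_equal(ad["rh_supramarginal", "alpha1"] /
                 nc["rh_supramarginal", "alpha1"], 1.4, tolerance = 1e-12)
  # subject factor shared across conditions
  ec <- subject_amplitudes(spec, "NC", "EC", 9)
  eo <- subject_amplitudes(spec, "NC", "EO", 9)
  expect_equal(ec["lh_cuneus", "theta1"] / eo["lh_cuneus", "theta1"],
               4e-9 / 3.5e-9, tolerance = 1e-12)
})

test_that("generate_cohort yields the full subject grid, reproducibly", {
  spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 8, n_vertices = 68,
                      sampling_rate = 50, duration = 10, seed = 3)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_equal(length(co1$recordings), 4)
  expect_setequal(names(co1$recordings), c("AD01", "AD02", "NC01", "NC02"))
  expect_setequal(names(co1$recordings$AD01), c("EC", "EO"))
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$recordings$NC02$EO$values, co2$recordings$NC02$EO$values)
  expect_equal(nrow(co1$truth), 4 * 2 * 5 * 68)
  expect_error(cohort_spec(n_ad = 1, n_nc = 5),
               class = "megspect_invalid_spec")
  expect_error(cohort_spec(n_ad = 2, n_nc = 2, sampling_rate = 3,
                           duration = 10.1),
               class = "megspect_invalid_spec")
})

test_that("default cohort sizes match the study design", {
  spec <- cohort_spec()
  expect_equal(spec$n_ad, 20)
  expect_equal(spec$n_nc, 27)
  expect_equal(nrow(megspect:::cohort_plan(spec)), 47)
})
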