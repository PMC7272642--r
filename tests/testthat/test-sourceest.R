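# Spherical forward model, minimum-norm inverse, regional power.

# Independent scalar implementation of the closed-form conducting-sphere
# dipole field (oracle; loops, no shared code with the package internals).
oracle_sphere_field <- function(r, r0, q) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(r^2))
  F_ <- a * (rn * a + rn^2 - sum(r0 * r))
  gF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_vec * r) / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  1e-7 / F_^2 * (F_ * qxr0 - sum(qxr0 * r) * gF)
}

test_that("central and radial dipoles are magnetically silent", {
  s <- tiny_setup()
  g <- s$geometry
  # dipole at the sphere center
  gc <- g
  gc$head$vertices[1, ] <- c(0, 0, 0)
  Lc <- compute_lead_field(gc$head, gc$sensors)
  tangential_ref <- max(abs(unclass(s$L)))
  expect_lt(max(abs(unclass(Lc)[, 1])), 1e-15 * tangential_ref)
  # radial orientation anywhere
  gr <- g
  gr$head$normals <- gr$head$vertices / sqrt(rowSums(gr$head$vertices^2))
  Lr <- compute_lead_field(gr$head, gr$sensors)
  expect_lt(max(abs(unclass(Lr))), 1e-15 * tangential_ref)
})

test_that("lead-field columns match an independent closed-form evaluation", {
  s <- tiny_setup(n_channels = 6, n_vertices = 10, n_regions = 5, seed = 4)
  g <- s$geometry
  for (v in c(1, 5, 10)) {
    expected <- vapply(seq_len(6), function(ch) {
      sum(oracle_sphere_field(g$sensors$position[ch, ],
                              g$head$vertices[v, ],
                              g$head$normals[v, ]) *
            g$sensors$orientation[ch, ])
    }, numeric(1))
    expect_equal(unclass(s$L)[, v], expected, tolerance = 1e-12)
  }
  # far-field decay along a ray: field shrinks monotonically with distance
  r0 <- g$head$vertices[1, ]
  q <- g$head$normals[1, ]
  ray <- c(0, 0, 1)
  mags <- vapply(c(0.15, 0.3, 0.6), function(d) {
    sqrt(sum(oracle_sphere_field(d * ray, r0, q)^2))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_equal(sqrt(sum(oracle_sphere_field(0.3 * ray, r0, q)^2)),
               mags[2], tolerance = 1e-14)
  # vertices outside the conductor are rejected
  gbad <- g
  gbad$head$vertices[2, ] <- c(0.2, 0, 0)
  expect_error(compute_lead_field(gbad$head, gbad$sensors),
               class = "megspect_vertex_outside")
})

test_that("the inverse operator is a shrinking, linear ridge estimator", {
  s <- tiny_setup()
  data <- matrix(rnorm(24 * 40, sd = 1e-13), 24)
  est3 <- apply_inverse(s$inv, data)
  inv_tiny <- compute_inverse_operator(s$L, snr = 1e-4)
  est0 <- apply_inverse(inv_tiny, data)
  expect_lt(max(abs(est0)), 1e-4 * max(abs(est3)))
  # linearity
  b1 <- matrix(rnorm(24 * 5), 24); b2 <- matrix(rnorm(24 * 5), 24)
  expect_equal(apply_inverse(s$inv, 3 * b1 + b2),
               3 * apply_inverse(s$inv, b1) + apply_inverse(s$inv, b2),
               tolerance = 1e-12)
  expect_gt(s$inv$lambda2, 0)
  expect_error(compute_inverse_operator(matrix(0, 4, 8)),
               class = "megspect_singular")
  expect_error(apply_inverse(s$inv, matrix(0, 7, 3)),
               class = "megspect_dim_mismatch")
})

test_that("noiseless single-vertex activity localizes to the correct region", {
  s <- tiny_setup(n_channels = 32, n_vertices = 136, seed = 1)
  set.seed(99)
  vs <- sample(136, 10)
  tc <- sin(2 * pi * 9 * seq_len(100) / 100)
  hits <- vapply(vs, function(v) {
    S <- apply_inverse(s$inv, unclass(s$L)[, v] %o% tc)
    s$geometry$head$region[which.max(rowMeans(abs(S)))] ==
      s$geometry$head$region[v]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("regional power equals the explicit-loop mean of absolute estimates", {
  s <- tiny_setup(n_channels = 6, n_vertices = 9, n_regions = 3, seed = 4)
  ep <- segment_epochs(meg_recording(matrix(rnorm(6 * 50), 6), 10), 2)
  vals <- extract_region_power(ep, s$inv, s$geometry$head)
  # brute force: loop over epochs, samples, vertices
  K <- s$inv$K
  n_ep <- dim(ep$epochs)[1]
  acc <- matrix(0, 9, 0)
  for (e in seq_len(n_ep)) acc <- cbind(acc, K %*% ep$epochs[e, , ])
  vmean <- numeric(9)
  for (v in 1:9) vmean[v] <- mean(abs(acc[v, ]))
  expected <- vapply(levels(s$geometry$head$region), function(r) {
    mean(vmean[s$geometry$head$region == r])
  }, numeric(1))
  expect_equal(as.numeric(vals), as.numeric(expected), tolerance = 1e-12)
  # constant estimates: every region reports |a|
  invc <- s$inv
  invc$K <- matrix(0, 9, 6); invc$K[, 1] <- 2  # estimate = 2 * channel-1 signal
  epc <- ep; epc$epochs[] <- 0; epc$epochs[, 1, ] <- 1
  valc <- extract_region_power(epc, invc, s$geometry$head)
  expect_equal(as.numeric(valc), rep(2, 3))
  # homogeneity: doubling the data doubles every region value
  ep2 <- ep; ep2$epochs <- 2 * ep$epochs
  expect_equal(as.numeric(extract_region_power(ep2, s$inv, s$geometry$head)),
               2 * as.numeric(vals), tolerance = 1e-12)
})

test_that("extracted regional power grows monotonically with simulated amplitude", {
  g <- make_geometry(24, 68, 68, seed = 1)
  L <- compute_lead_field(g$head, g$sensors)
  inv <- compute_inverse_operator(L)
  target <- "lh_precentral"
  powers <- vapply(c(2e-9, 4e-9, 8e-9), function(a) {
    spec <- cohort_spec(n_ad = 2, n_nc = 2, n_channels = 24, n_vertices = 68,
                        sampling_rate = 50, duration = 10,
                        noise_floor_amplitude = 0, sensor_noise_sd = 0,
                        artifact_rate = 0)
    tab <- spec$band_amplitude_table
    tab$mean <- ifelse(tab$band == "alpha1" & tab$region == target, a, 1e-9)
    tab$sd <- 0
    spec$band_amplitude_table <- tab
    spec$amplitude_cv <- 1e-9
    src <- simulate_source_timecourses(spec, g$head, "NC", "EC", 31)
    rec <- project_to_sensors(src, g$head, g$sensors, L, "s", "EC")
    pw <- recording_region_power(rec, inv, g$head)
    pw$power[pw$band == "alpha1" & pw$region == target]
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})
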