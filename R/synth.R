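# Synthetic cohort generation: group- and condition-dependent band-limited
# cortical source activity, forward projection through the spherical-head
# lead field, sensor noise and boxcar artifacts.

#' Default band amplitude table
#'
#' Mean source amplitudes (A*m per vertex) per group x condition x band x
#' region, with the between-subject SD given by a common coefficient of
#' variation. Defaults encode the structure the analysis assumes: every
#' band's amplitude is higher under eyes-closed (EC) than eyes-open (EO),
#' strongly so in the alpha bands (alpha blocking on eye opening), and the
#' AD group carries an elevated amplitude in one designated (band, region)
#' cell — by default alpha1 in the right supramarginal region, raised by
#' `effect_sd` between-subject standard deviations in both conditions.
#'
#' @param regions Region labels (default the 68 Desikan-Killiany labels).
#' @param bands Band names (default [meg_bands()]).
#' @param base_ec,base_eo Named per-band mean amplitudes (A*m) under EC/EO.
#' @param effect_region,effect_band Designated AD-effect cell (`NULL`
#'   disables the group effect — a global-null generator).
#' @param effect_sd AD elevation in units of the between-subject SD.
#' @param cv Coefficient of variation of the between-subject log-normal
#'   amplitude factor.
#' @return Data frame: `group`, `condition`, `band`, `region`, `mean`, `sd`.
#' @export
default_band_amplitude_table <- function(
    regions = region_labels(), bands = meg_bands()$name,
    base_ec = c(theta1 = 4e-9, theta2 = 4e-9, alpha1 = 8e-9,
                alpha2 = 7e-9, beta = 3e-9),
    base_eo = c(theta1 = 3.5e-9, theta2 = 3.5e-9, alpha1 = 4e-9,
                alpha2 = 3.5e-9, beta = 2.5e-9),
    effect_region = "rh_supramarginal", effect_band = "alpha1",
    effect_sd = 2, cv = 0.2) {
  stopifnot(all(bands %in% names(base_ec)), all(bands %in% names(base_eo)))
  tab <- expand.grid(region = regions, band = bands,
                     condition = c("EC", "EO"), group = c("NC", "AD"),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab$mean <- ifelse(tab$condition == "EC",
                     base_ec[tab$band], base_eo[tab$band])
  if (!is.null(effect_region) && !is.null(effect_band)) {
    if (!effect_region %in% regions || !effect_band %in% bands) {
      stop_megspect("designated effect cell not in the region/band grid",
                    "megspect_invalid_spec")
    }
    hit <- tab$group == "AD" & tab$region == effect_region &
      tab$band == effect_band
    tab$mean[hit] <- tab$mean[hit] * (1 + effect_sd * cv)
  }
  tab$sd <- cv * tab$mean
  tab[, c("group", "condition", "band", "region", "mean", "sd")]
}

#' Cohort simulation specification
#'
#' Bundles every parameter of the synthetic cohort. The desk-scale defaults
#' (64 channels, 500 vertices, 250 Hz, 30 s) keep a full cohort tractable on
#' a workstation; the acquisition scale of a 160-channel 1000-Hz system with
#' 2-minute recordings is available by passing `acquisition_scale = TRUE`.
#'
#' @param n_ad,n_nc Group sizes (default 20 AD, 27 NC).
#' @param n_channels,n_vertices,n_regions Geometry sizes.
#' @param sampling_rate Hz. @param duration Seconds per recording.
#' @param band_amplitude_table See [default_band_amplitude_table()];
#'   built with defaults when `NULL`.
#' @param amplitude_cv Between-subject coefficient of variation of the
#'   log-normal amplitude factor.
#' @param noise_floor_amplitude RMS of the region-level 1/f broadband
#'   floor (A*m).
#' @param sensor_noise_sd I.i.d. Gaussian sensor noise SD (tesla).
#' @param artifact_rate Boxcar artifact events per minute.
#' @param artifact_amplitude Artifact amplitude (tesla); default 12 pT so
#'   affected blocks exceed the 10 pT rejection threshold.
#' @param seed Master seed: the cohort is a pure function of the spec.
#' @param acquisition_scale If `TRUE`, use 160 channels / 15,000 vertices /
#'   1000 Hz / 120 s.
#' @return A list of class `meg_cohort_spec`.
#' @export
cohort_spec <- function(n_ad = 20, n_nc = 27,
                        n_channels = 64, n_vertices = 500, n_regions = 68,
                        sampling_rate = 250, duration = 30,
                        band_amplitude_table = NULL,
                        amplitude_cv = 0.2,
                        noise_floor_amplitude = 1e-9,
                        sensor_noise_sd = 5e-14,
                        artifact_rate = 2, artifact_amplitude = 12e-12,
                        seed = 1, acquisition_scale = FALSE) {
  if (acquisition_scale) {
    n_channels <- 160; n_vertices <- 15000
    sampling_rate <- 1000; duration <- 120
  }
  if (n_ad < 2 || n_nc < 2) {
    stop_megspect("need at least 2 subjects per group",
                  "megspect_invalid_spec")
  }
  n_samp <- duration * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop_megspect("duration x sampling_rate must be integral",
                  "megspect_invalid_spec")
  }
  if (is.null(band_amplitude_table)) {
    band_amplitude_table <- default_band_amplitude_table(
      regions = region_labels(n_regions), cv = amplitude_cv)
  }
  if (any(band_amplitude_table$mean < 0)) {
    stop_megspect("amplitudes must be non-negative", "megspect_invalid_spec")
  }
  structure(list(
    n_ad = n_ad, n_nc = n_nc, n_channels = n_channels,
    n_vertices = n_vertices, n_regions = n_regions,
    sampling_rate = sampling_rate, duration = duration,
    conditions = c("EC", "EO"), bands = meg_bands(),
    band_amplitude_table = band_amplitude_table,
    amplitude_cv = amplitude_cv,
    noise_floor_amplitude = noise_floor_amplitude,
    sensor_noise_sd = sensor_noise_sd,
    artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    seed = seed), class = "meg_cohort_spec")
}

# Draw the per-subject amplitude factor: one log-normal multiplier with
# unit mean and CV = spec$amplitude_cv per (band, region), shared across
# conditions so EC-EO reactivity is subject-consistent.
draw_subject_factors <- function(spec, subject_seed) {
  regions <- region_labels(spec$n_regions)
  bands <- spec$bands$name
  cv <- spec$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2  # unit mean
  with_seed(subject_seed, {
    m <- matrix(stats::rlnorm(length(regions) * length(bands),
                              mulog, sdlog),
                nrow = length(regions),
                dimnames = list(regions, bands))
    m
  })
}

#' Per-subject ground-truth amplitudes
#'
#' The amplitude (A*m) of each (band, region) band-limited process for one
#' subject and condition: table mean for the subject's group times the
#' subject's log-normal factor (drawn once per subject, shared across
#' conditions).
#'
#' @param spec A `meg_cohort_spec`.
#' @param group `"AD"` or `"NC"`. @param condition `"EC"` or `"EO"`.
#' @param subject_seed Seed of the subject's amplitude draw.
#' @return Matrix `[regions x bands]` of amplitudes.
#' @export
subject_amplitudes <- function(spec, group, condition, subject_seed) {
  if (!group %in% c("AD", "NC")) {
    stop_megspect("unknown group label", "megspect_invalid_label")
  }
  if (!condition %in% c("EC", "EO")) {
    stop_megspect("unknown condition label", "megspect_invalid_label")
  }
  regions <- region_labels(spec$n_regions)
  bands <- spec$bands$name
  tab <- spec$band_amplitude_table
  tab <- tab[tab$group == group & tab$condition == condition, , drop = FALSE]
  mu <- matrix(NA_real_, length(regions), length(bands),
               dimnames = list(regions, bands))
  mu[cbind(match(tab$region, regions), match(tab$band, bands))] <- tab$mean
  if (anyNA(mu)) {
    stop_megspect("band_amplitude_table does not cover the full grid",
                  "megspect_invalid_spec")
  }
  fac <- draw_subject_factors(spec, subject_seed)
  mu * fac[regions, bands]
}

# Region-level 1/f noise: rows are independent processes with amplitude
# spectrum ~ 1/sqrt(f), scaled to unit RMS, generated in the frequency
# domain.
one_over_f_rows <- function(n_rows, n_samples, fs) {
  m <- n_samples
  k <- floor(m / 2)
  f <- seq_len(k) * fs / m
  amp <- 1 / sqrt(f)
  re <- matrix(stats::rnorm(n_rows * k), n_rows)
  im <- matrix(stats::rnorm(n_rows * k), n_rows)
  half <- (re + 1i * im) * rep(amp, each = n_rows)
  spec_mat <- matrix(0i, n_rows, m)
  spec_mat[, 2:(k + 1)] <- half
  if (m %% 2 == 0) spec_mat[, k + 1] <- Re(spec_mat[, k + 1])
  spec_mat[, m - seq_len(m - k - 1) + 1] <-
    Conj(spec_mat[, 2:(m - k), drop = FALSE])
  x <- Re(t(stats::mvfft(t(spec_mat), inverse = TRUE))) / m
  rms <- sqrt(rowMeans(x^2))
  x / pmax(rms, .Machine$double.eps)
}

#' Simulate cortical source time courses for one subject and condition
#'
#' Each region carries, shared by all of its vertices, a sum over the five
#' analysis bands of band-limited Gaussian processes (white noise filtered
#' with the same zero-phase Butterworth band-pass as the preprocessing
#' module, scaled to the subject's drawn amplitude as RMS) plus a 1/f
#' broadband floor. Region coherence — identical time courses within a
#' region — is the package's model of locally synchronous cortical patches.
#'
#' @param spec A `meg_cohort_spec`.
#' @param geom A `meg_head` geometry (regions must match the spec).
#' @param subject_group `"AD"` or `"NC"`.
#' @param condition `"EC"` or `"EO"`.
#' @param subject_seed Seed for the subject's amplitude draw.
#' @param noise_seed Seed for the time-course realization (defaults to
#'   `subject_seed + 1`).
#' @return A list of class `meg_sources`: `values` (`[vertices x samples]`,
#'   A*m), `sampling_rate`, and `amplitudes` (the ground-truth
#'   `[regions x bands]` amplitude matrix).
#' @export
simulate_source_timecourses <- function(spec, geom, subject_group, condition,
                                        subject_seed,
                                        noise_seed = subject_seed + 1) {
  stopifnot(inherits(geom, "meg_head"))
  amps <- subject_amplitudes(spec, subject_group, condition, subject_seed)
  regions <- region_labels(spec$n_regions)
  n_samples <- as.integer(round(spec$duration * spec$sampling_rate))
  n_reg <- length(regions)
  fs <- spec$sampling_rate
  region_sig <- with_seed(noise_seed, {
    acc <- matrix(0, n_samples, n_reg)  # samples x regions
    for (b in seq_len(nrow(spec$bands))) {
      bw <- spec$bands[b, ]
      w <- matrix(stats::rnorm(n_reg * n_samples), n_samples)
      xb <- bandpass_cols(w, bw$low, bw$high, fs)
      scale <- amps[, bw$name] / pmax(sqrt(colMeans(xb^2)),
                                      .Machine$double.eps)
      acc <- acc + xb * rep(scale, each = n_samples)
    }
    if (spec$noise_floor_amplitude > 0) {
      acc <- acc + spec$noise_floor_amplitude *
        t(one_over_f_rows(n_reg, n_samples, fs))
    }
    t(acc)
  })
  ridx <- as.integer(geom$region)
  structure(list(values = region_sig[ridx, , drop = FALSE],
                 sampling_rate = fs, amplitudes = amps),
            class = "meg_sources")
}

#' Project source activity to the sensors
#'
#' Linear forward projection: `sensor data = leadfield %*% sources`, tesla.
#'
#' @param src A `meg_sources` (or list with `values`, `sampling_rate`).
#' @param geom The `meg_head` used to build the lead field.
#' @param sensors The `meg_sensors` array.
#' @param leadfield `[channels x vertices]` lead field.
#' @param subject_id,condition Labels for the resulting recording.
#' @return A `meg_recording`.
#' @export
project_to_sensors <- function(src, geom, sensors, leadfield,
                               subject_id = NA_character_,
                               condition = NA_character_) {
  L <- unclass(leadfield)
  if (ncol(L) != nrow(src$values) || nrow(L) != nrow(sensors$position)) {
    stop_megspect("lead field dimensions do not match sensors x vertices",
                  "megspect_dim_mismatch")
  }
  meg_recording(L %*% src$values, src$sampling_rate, subject_id, condition)
}

#' Add sensor noise and boxcar artifacts
#'
#' Adds i.i.d. Gaussian sensor noise and, at Poisson-distributed onsets
#' (`artifact_rate` events per minute), 100-ms boxcar amplitude steps of
#' `artifact_amplitude` tesla on one random channel each — the
#' large-amplitude contamination the 10 pT rejection stage removes.
#'
#' @param rec A `meg_recording`.
#' @param noise_sd Gaussian noise SD, tesla (>= 0).
#' @param artifact_rate Events per minute.
#' @param artifact_amplitude Tesla.
#' @param seed RNG seed.
#' @return The noisy `meg_recording`; the artifact log (data frame with
#'   `onset_sample`, `channel`) is attached as field `artifact_log`.
#' @export
add_noise_and_artifacts <- function(rec, noise_sd, artifact_rate = 0,
                                    artifact_amplitude = 0, seed = 1) {
  stopifnot(inherits(rec, "meg_recording"), noise_sd >= 0)
  n <- ncol(rec$values); nch <- nrow(rec$values)
  fs <- rec$sampling_rate
  with_seed(seed, {
    if (noise_sd > 0) {
      rec$values <- rec$values + matrix(stats::rnorm(nch * n, sd = noise_sd),
                                        nch, n)
    }
    log <- data.frame(onset_sample = integer(0), channel = integer(0))
    if (artifact_rate > 0 && artifact_amplitude != 0) {
      minutes <- n / fs / 60
      k <- stats::rpois(1, artifact_rate * minutes)
      if (k > 0) {
        width <- max(1L, as.integer(round(0.1 * fs)))  # 100 ms boxcar
        onset <- sort(sample.int(max(1L, n - width), k, replace = TRUE))
        chan <- sample.int(nch, k, replace = TRUE)
        for (i in seq_len(k)) {
          idx <- onset[i]:(onset[i] + width - 1L)
          rec$values[chan[i], idx] <- rec$values[chan[i], idx] +
            artifact_amplitude
        }
        log <- data.frame(onset_sample = onset, channel = chan)
      }
    }
    rec$artifact_log <- log
    rec
  })
}

# Internal: simulate one subject/condition recording end to end.
simulate_subject_recording <- function(spec, geom, sensors, leadfield,
                                       group, condition, subject_id,
                                       subject_seed, noise_seed) {
  src <- simulate_source_timecourses(spec, geom, group, condition,
                                     subject_seed)
  rec <- project_to_sensors(src, geom, sensors, leadfield,
                            subject_id, condition)
  rec <- add_noise_and_artifacts(rec, spec$sensor_noise_sd,
                                 spec$artifact_rate,
                                 spec$artifact_amplitude, noise_seed)
  list(recording = rec, amplitudes = src$amplitudes)
}

# Internal: cohort bookkeeping — subject ids, groups, per-subject seeds.
cohort_plan <- function(spec) {
  ids <- c(sprintf("AD%02d", seq_len(spec$n_ad)),
           sprintf("NC%02d", seq_len(spec$n_nc)))
  groups <- c(rep("AD", spec$n_ad), rep("NC", spec$n_nc))
  n <- length(ids)
  seeds <- matrix(derive_seeds(spec$seed, 3L * n), ncol = 3)
  data.frame(subject_id = ids, group = groups,
             subject_seed = seeds[, 1],
             noise_seed_ec = seeds[, 2], noise_seed_eo = seeds[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Builds the geometry and lead field (unless supplied), then simulates an
#' EC and an EO recording for every subject. Fully reproducible from
#' `spec$seed`. For large cohorts prefer [run_pipeline()], which streams
#' subjects instead of keeping all recordings in memory.
#'
#' @param spec A `meg_cohort_spec`.
#' @param geometry Optional list `(sensors, head)` from [make_geometry()].
#' @param leadfield Optional precomputed lead field.
#' @return A list of class `meg_cohort`: `recordings` (nested list
#'   `[[subject_id]][[condition]]`), `meta` (subject table), `truth` (long
#'   data frame of ground-truth amplitudes), `geometry`, `leadfield`,
#'   `spec`.
#' @export
generate_cohort <- function(spec, geometry = NULL, leadfield = NULL) {
  stopifnot(inherits(spec, "meg_cohort_spec"))
  if (is.null(geometry)) {
    geometry <- make_geometry(spec$n_channels, spec$n_vertices,
                              spec$n_regions, seed = spec$seed)
  }
  if (is.null(leadfield)) {
    leadfield <- compute_lead_field(geometry$head, geometry$sensors)
  }
  plan <- cohort_plan(spec)
  recordings <- list()
  truth <- vector("list", 2L * nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sid <- plan$subject_id[i]
    recordings[[sid]] <- list()
    for (cond in c("EC", "EO")) {
      nseed <- if (cond == "EC") plan$noise_seed_ec[i] else plan$noise_seed_eo[i]
      sim <- simulate_subject_recording(
        spec, geometry$head, geometry$sensors, leadfield,
        plan$group[i], cond, sid, plan$subject_seed[i], nseed)
      recordings[[sid]][[cond]] <- sim$recording
      amps <- sim$amplitudes
      truth[[2L * (i - 1L) + (cond == "EO") + 1L]] <- data.frame(
        subject_id = sid, group = plan$group[i], condition = cond,
        band = rep(colnames(amps), each = nrow(amps)),
        region = rep(rownames(amps), times = ncol(amps)),
        amplitude = as.vector(amps), stringsAsFactors = FALSE)
    }
  }
  structure(list(recordings = recordings, meta = plan,
                 truth = do.call(rbind, truth),
                 geometry = geometry, leadfield = leadfield, spec = spec),
            class = "meg_cohort")
}
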