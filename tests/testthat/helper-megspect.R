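# Shared fixtures, built in code.

# Small geometry + lead field + inverse, cached per test file run.
tiny_setup <- function(n_channels = 24, n_vertices = 68, n_regions = 68,
                       seed = 2, snr = 3) {
  g <- make_geometry(n_channels, n_vertices, n_regions, seed = seed)
  L <- compute_lead_field(g$head, g$sensors)
  list(geometry = g, L = L,
       inv = compute_inverse_operator(L, snr = snr))
}

# A complete random region-power table for `n` subjects over the full
# default grid (5 bands x 68 regions x EC/EO), positive powers.
random_power_table <- function(n_subjects = 2, seed = 1,
                               regions = region_labels(),
                               bands = meg_bands()$name) {
  withr::with_seed(seed, {
    grid <- expand.grid(region = regions, band = bands,
                        condition = c("EC", "EO"),
                        subject_id = sprintf("S%02d", seq_len(n_subjects)),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid$group <- ifelse(as.integer(factor(grid$subject_id)) %% 2 == 0,
                         "AD", "NC")
    grid$power <- stats::rlnorm(nrow(grid), log(5e-9), 0.3)
    grid
  })
}

# A short clean recording of sinusoids (deterministic).
sine_recording <- function(n_channels = 2, fs = 50, duration = 10,
                           freq = 9, amp = 1e-13) {
  tt <- seq_len(duration * fs) / fs
  vals <- t(vapply(seq_len(n_channels),
                   function(ch) amp * sin(2 * pi * freq * tt + ch),
                   numeric(length(tt))))
  meg_recording(vals, fs, "S01", "EC")
}
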