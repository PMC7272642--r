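# Forward and inverse modelling: closed-form magnetic field of a current
# dipole in a homogeneous conducting sphere (Sarvas), depth-weighted
# Tikhonov-regularized minimum-norm inverse with fixed source orientations,
# and regional absolute-power extraction.

# Magnetic field of unit dipoles at sensor positions, Sarvas closed form.
# r: sensor positions [n_s x 3]; r0: dipole position (3); q: dipole moment
# (3, A*m). All relative to the sphere center. Returns [n_s x 3] tesla.
sarvas_field <- function(r, r0, q) {
  a_vec <- sweep(r, 2, r0)              # r - r0
  a <- sqrt(rowSums(a_vec^2))
  rn <- sqrt(rowSums(r^2))
  r0r <- drop(r %*% r0)                 # r0 . r per sensor
  F_ <- a * (rn * a + rn^2 - r0r)
  adotr <- rowSums(a_vec * r)
  gF_r <- a^2 / rn + adotr / a + 2 * a + 2 * rn          # coefficient on r
  gF_r0 <- a + 2 * rn + adotr / a                        # coefficient on r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  dot_qxr0_r <- drop(r %*% qxr0)
  mu0_4pi <- 1e-7
  B <- mu0_4pi / F_^2 *
    (F_ %o% qxr0 - dot_qxr0_r * (gF_r * r - gF_r0 %o% r0))
  B
}

#' Compute the lead field of a spherical conductor
#'
#' Column `v` is the sensing-direction projection of the closed-form
#' magnetic field (Sarvas solution for a homogeneous conducting sphere) of a
#' unit current dipole at vertex `v`, oriented along the vertex normal
#' (fixed-orientation constraint). Radially oriented dipoles and dipoles at
#' the sphere center are magnetically silent, so their columns are
#' numerically zero.
#'
#' @param head A `meg_head` geometry.
#' @param sensors A `meg_sensors` array.
#' @return A `[channels x vertices]` matrix of class `meg_leadfield`, tesla
#'   per (A*m).
#' @export
compute_lead_field <- function(head, sensors) {
  stopifnot(inherits(head, "meg_head"), inherits(sensors, "meg_sensors"))
  ctr <- head$sphere_center
  vtx <- sweep(head$vertices, 2, ctr)
  pos <- sweep(sensors$position, 2, ctr)
  rad <- sqrt(rowSums(vtx^2))
  if (any(rad >= head$sphere_radius)) {
    stop_megspect("all source vertices must lie strictly inside the sphere",
                  "megspect_vertex_outside")
  }
  n_s <- nrow(pos); n_v <- nrow(vtx)
  L <- matrix(0, n_s, n_v)
  for (v in seq_len(n_v)) {
    B <- sarvas_field(pos, vtx[v, ], head$normals[v, ])
    L[, v] <- rowSums(B * sensors$orientation)
  }
  structure(L, class = c("meg_leadfield", "matrix", "array"))
}

#' Compute a depth-weighted minimum-norm inverse operator
#'
#' Tikhonov-regularized weighted minimum-norm estimate with fixed source
#' orientations:
#' \deqn{K = W L' (L W L' + \lambda^2 I)^{-1}}
#' with diagonal depth weights \eqn{W_{vv} = \|L_{.v}\|^{-2 p}} (exponent
#' `p = depth_exponent`; 0 disables weighting) and regularization
#' \eqn{\lambda^2 = \mathrm{trace}(L W L') / (n_{channels} \cdot snr^2)},
#' the convention of minimum-norm source imaging software. Numerically
#' silent columns (e.g. radial sources) receive zero weight and zero
#' estimates.
#'
#' @param L A `meg_leadfield` or plain `[channels x vertices]` matrix.
#' @param snr Assumed amplitude signal-to-noise ratio (default 3).
#' @param depth_exponent Depth-weighting exponent (default 0.5).
#' @return A list of class `meg_inverse`: `K` (`[vertices x channels]`,
#'   (A*m)/T), `lambda2`, `weights`.
#' @export
compute_inverse_operator <- function(L, snr = 3, depth_exponent = 0.5) {
  L <- unclass(L)
  stopifnot(is.matrix(L), all(is.finite(L)), nrow(L) >= 1, snr > 0)
  cn2 <- colSums(L^2)
  nz <- cn2 > max(cn2) * 1e-24
  w <- numeric(length(cn2))
  w[nz] <- cn2[nz]^(-depth_exponent)
  G <- L %*% (w * t(L))
  lambda2 <- sum(diag(G)) / (nrow(L) * snr^2)
  M <- G + diag(lambda2, nrow(L))
  Minv <- tryCatch(solve(M), error = function(e) {
    stop_megspect("regularized Gram matrix is singular", "megspect_singular")
  })
  K <- (w * t(L)) %*% Minv
  structure(list(K = K, lambda2 = lambda2, weights = w,
                 snr = snr, depth_exponent = depth_exponent),
            class = "meg_inverse")
}

#' Apply an inverse operator to sensor data
#'
#' @param inv A `meg_inverse`.
#' @param data `[channels x samples]` matrix.
#' @return `[vertices x samples]` source estimates, A*m.
#' @export
apply_inverse <- function(inv, data) {
  stopifnot(inherits(inv, "meg_inverse"))
  if (nrow(data) != ncol(inv$K)) {
    stop_megspect("channel dimension mismatch between inverse and data",
                  "megspect_dim_mismatch")
  }
  inv$K %*% data
}

#' Extract regional absolute power from band-filtered epochs
#'
#' Applies the inverse operator to every epoch, averages the absolute value
#' of the source estimate over all epochs and samples per vertex, then takes
#' the unweighted mean over each region's vertices (scout mean). The result
#' is the band's regional "absolute power" — a mean absolute current
#' amplitude in A*m, not a squared spectral density.
#'
#' @param epochs A band-filtered `meg_epochs`.
#' @param inv A `meg_inverse`.
#' @param head The `meg_head` geometry providing the parcellation.
#' @return A named numeric vector of regional values (atlas order), with
#'   attribute `n_epochs`.
#' @export
extract_region_power <- function(epochs, inv, head) {
  stopifnot(inherits(epochs, "meg_epochs"), inherits(head, "meg_head"))
  d <- dim(epochs$epochs)
  if (any(table(head$region) == 0)) {
    stop_megspect("parcellation contains an empty region",
                  "megspect_empty_region")
  }
  # channels x (epochs*samples): epoch-wise inverse is linear, so one
  # application to the concatenation is identical.
  flat <- matrix(aperm(epochs$epochs, c(2, 3, 1)), nrow = d[2])
  src <- apply_inverse(inv, flat)
  vertex_mean <- rowMeans(abs(src))
  vals <- tapply(vertex_mean, head$region, mean)
  out <- as.numeric(vals)
  names(out) <- names(vals)
  attr(out, "n_epochs") <- d[1]
  out
}
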