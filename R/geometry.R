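# Synthetic head and sensor geometry: spherical conductor, quasi-uniform
# cortical shell, Desikan-Killiany-style 68-region parcellation.

#' Desikan-Killiany region labels
#'
#' The 34 gyral parcels of the Desikan-Killiany atlas, prefixed `lh_` / `rh_`.
#' Left hemisphere first, alphabetical within hemisphere; this is the
#' canonical region order of every table and feature vector in the package.
#'
#' @param n_regions Number of labels requested. For 68 the atlas names are
#'   returned; otherwise generic `region_###` labels.
#' @return Character vector of length `n_regions`.
#' @export
region_labels <- function(n_regions = 68) {
  if (n_regions == 68) {
    base <- c(
      "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
      "cuneus", "entorhinal", "frontalpole", "fusiform",
      "inferiorparietal", "inferiortemporal", "insula",
      "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
      "lingual", "medialorbitofrontal", "middletemporal",
      "paracentral", "parahippocampal", "parsopercularis",
      "parsorbitalis", "parstriangularis", "pericalcarine",
      "postcentral", "posteriorcingulate", "precentral", "precuneus",
      "rostralanteriorcingulate", "rostralmiddlefrontal",
      "superiorfrontal", "superiorparietal", "superiortemporal",
      "supramarginal", "temporalpole", "transversetemporal"
    )
    c(paste0("lh_", base), paste0("rh_", base))
  } else {
    sprintf("region_%03d", seq_len(n_regions))
  }
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)  # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Greedy farthest-point subsample of rows of `pts`; returns indices.
farthest_point_seeds <- function(pts, k) {
  n <- nrow(pts)
  stopifnot(k <= n)
  sel <- integer(k)
  # start from the point farthest from the centroid: deterministic
  ctr <- colMeans(pts)
  d2 <- rowSums(sweep(pts, 2, ctr)^2)
  sel[1] <- which.max(d2)
  mind <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  if (k > 1) {
    for (j in 2:k) {
      sel[j] <- which.max(mind)
      dj <- rowSums(sweep(pts, 2, pts[sel[j], ])^2)
      mind <- pmin(mind, dj)
    }
  }
  sort(sel)
}

#' Generate sensor-array and head-model geometry
#'
#' Builds a synthetic whole-head magnetometer array on a spherical cap and a
#' quasi-uniform cortical vertex shell inside a homogeneous conducting
#' sphere, partitioned into contiguous regions (Desikan-Killiany labels when
#' `n_regions = 68`). Sensors are modelled as point magnetometers with
#' radially inward sensing direction; vertex source orientations are seeded
#' pseudo-random unit vectors, standing in for cortical surface normals.
#'
#' @param n_channels Number of sensors.
#' @param n_vertices Number of cortical vertices.
#' @param n_regions Number of parcellation regions (`<= n_vertices`).
#' @param seed Integer seed; the geometry is a pure function of the arguments.
#' @param head_radius Conductor sphere radius (m).
#' @param shell_radius Radius of the cortical vertex shell (m); must be
#'   strictly inside the conductor.
#' @param sensor_radius Radius of the sensor cap (m); outside the scalp.
#' @param vertex_z_min Lower edge of the cortical cap as a fraction of the
#'   shell radius: vertices satisfy `z / shell_radius > vertex_z_min`,
#'   mimicking a cortical mantle confined to the cranial vault.
#' @return A list with elements `sensors` (class `meg_sensors`: `position`,
#'   `orientation` matrices, `channel_id`) and `head` (class `meg_head`:
#'   `vertices`, `normals`, `region` factor, `sphere_center`,
#'   `sphere_radius`).
#' @export
#' @examples
#' g <- make_geometry(16, 68, 68, seed = 1)
#' table(table(g$head$region))  # every region non-empty
make_geometry <- function(n_channels, n_vertices, n_regions = 68, seed = 1,
                          head_radius = 0.09, shell_radius = 0.07,
                          sensor_radius = 0.11, vertex_z_min = -0.25) {
  if (n_regions > n_vertices) {
    stop_megspect("n_regions must not exceed n_vertices",
                  "megspect_invalid_spec")
  }
  stopifnot(n_channels >= 1, shell_radius < head_radius,
            sensor_radius > head_radius)

  # Sensors: Fibonacci lattice on a cap covering the upper ~2/3 of the
  # sphere (whole-head helmet); sensing direction radially inward.
  cap <- fibonacci_sphere(n_channels)
  z0 <- -0.35
  capz <- z0 + (cap[, 3] + 1) / 2 * (1 - z0)
  capr <- sqrt(pmax(0, 1 - capz^2))
  ang <- atan2(cap[, 2], cap[, 1])
  pos <- sensor_radius * cbind(capr * cos(ang), capr * sin(ang), capz)
  orient <- -pos / sqrt(rowSums(pos^2))  # unit, pointing at sphere center
  sensors <- structure(list(
    channel_id = sprintf("MEG%03d", seq_len(n_channels)),
    position = pos, orientation = orient
  ), class = "meg_sensors")

  # Cortical shell: quasi-uniform on the upper cap of the inner sphere
  # (z/r > vertex_z_min), mimicking the cerebral mantle inside the cranial
  # vault; the sensor cap extends slightly below it so every region is
  # covered by the array.
  vshell <- fibonacci_sphere(n_vertices)
  vz <- vertex_z_min + (vshell[, 3] + 1) / 2 * (1 - vertex_z_min)
  vr <- sqrt(pmax(0, 1 - vz^2))
  vang <- atan2(vshell[, 2], vshell[, 1])
  vtx <- shell_radius * cbind(x = vr * cos(vang), y = vr * sin(vang), z = vz)
  # Source orientations: seeded pseudo-random unit vectors tangential to the
  # shell. A spherical conductor is blind to radial dipole components, so
  # tangential orientations are the visible part of any cortical normal
  # field; they keep every vertex magnetically represented.
  normals <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_vertices), ncol = 3)
    rad <- vtx / sqrt(rowSums(vtx^2))
    m <- m - rowSums(m * rad) * rad
    m / sqrt(rowSums(m^2))
  })

  # Parcellation: nearest-seed patches, seeds chosen among the vertices so
  # every region owns at least its seed. For even n_regions with enough
  # vertices per hemisphere (split on x), seed each hemisphere separately so
  # labels pair left/right.
  half <- n_regions %/% 2L
  left <- which(vtx[, 1] < 0)
  right <- which(vtx[, 1] >= 0)
  if (n_regions %% 2L == 0L && length(left) >= half && length(right) >= half) {
    seeds <- c(left[farthest_point_seeds(vtx[left, , drop = FALSE], half)],
               right[farthest_point_seeds(vtx[right, , drop = FALSE], half)])
  } else {
    seeds <- farthest_point_seeds(vtx, n_regions)
  }
  d2 <- outer(rowSums(vtx^2), rep(1, n_regions)) -
    2 * vtx %*% t(vtx[seeds, , drop = FALSE]) +
    outer(rep(1, n_vertices), rowSums(vtx[seeds, , drop = FALSE]^2))
  assign_idx <- max.col(-d2, ties.method = "first")
  labels <- region_labels(n_regions)
  region <- factor(labels[assign_idx], levels = labels)
  stopifnot(all(table(region) > 0))

  head <- structure(list(
    sphere_center = c(0, 0, 0), sphere_radius = head_radius,
    vertices = vtx, normals = normals, region = region
  ), class = "meg_head")
  list(sensors = sensors, head = head)
}
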