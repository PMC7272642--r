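# Feature construction: whole-cerebral normalization (WCN), EC-EO
# reactivity, and the canonical 2,040-element per-subject feature vector
# (6 value types x 5 bands x 68 regions).

#' Whole-cerebral normalization (WCN)
#'
#' Z-scores a vector of regional values against the whole-cerebral mean and
#' standard deviation across regions:
#' `(value_a - mean(all regions)) / sd(all regions)`.
#' The population SD (divisor N) is used by default so the output has
#' exactly zero mean and unit SD; the sample SD (N-1) is available as an
#' option.
#'
#' @param x Numeric vector of regional values (>= 2 regions).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named numeric vector of z-scores, same order as the input.
#' @export
#' @examples
#' wcn_normalize(c(2, 4, 6))
wcn_normalize <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  m <- mean(x)
  n <- length(x)
  s2 <- sum((x - m)^2) / if (sd_type == "population") n else n - 1
  s <- sqrt(s2)
  if (s <= 0 || s < max(abs(x), 1) * 1e-14) {
    stop_megspect(
      "degenerate dispersion: all regional values are (numerically) equal",
      "megspect_degenerate_dispersion")
  }
  (x - m) / s
}

#' Eyes-closed minus eyes-open regional difference
#'
#' @param power_ec,power_eo Named numeric vectors over the same regions.
#' @return `power_ec - power_eo`, elementwise, in the EC order.
#' @export
ec_eo_difference <- function(power_ec, power_eo) {
  if (length(power_ec) != length(power_eo) ||
      (!is.null(names(power_ec)) && !is.null(names(power_eo)) &&
       !identical(names(power_ec), names(power_eo)))) {
    stop_megspect("EC and EO regional vectors must share the same index",
                  "megspect_index_mismatch")
  }
  power_ec - power_eo
}

#' Canonical feature value types
#' @return Character vector: absolute power EC/EO, WCN power EC/EO, EC-EO
#'   difference, WCN of the difference.
#' @export
feature_value_types <- function() {
  c("absEC", "absEO", "wcnEC", "wcnEO", "diffECEO", "wcnDiff")
}

#' Canonical feature index
#'
#' The fixed ordering of the per-subject feature vector: value-type major,
#' then band (theta1, theta2, alpha1, alpha2, beta), then region (atlas
#' order, left hemisphere first). With defaults this enumerates
#' 6 x 5 x 68 = 2,040 features named `valueType.band.region`.
#'
#' @param bands Character vector of band names (default [meg_bands()]).
#' @param regions Character vector of region labels (default
#'   [region_labels()]).
#' @return Data frame with columns `value_type`, `band`, `region`, `name`.
#' @export
feature_index <- function(bands = meg_bands()$name,
                          regions = region_labels()) {
  grid <- expand.grid(region = regions, band = bands,
                      value_type = feature_value_types(),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("value_type", "band", "region")]
  grid$name <- paste(grid$value_type, grid$band, grid$region, sep = ".")
  grid
}

#' Assemble the canonical per-subject feature vector
#'
#' From a long region-power table (one row per condition x band x region for
#' one subject), computes the six value types per band x region — absolute
#' power under EC and EO, their WCN z-scores, the EC-EO difference, and the
#' WCN of the difference — and flattens them in the canonical
#' [feature_index()] order.
#'
#' @param power_table Data frame with columns `subject_id`, `condition`
#'   (`"EC"`/`"EO"`), `band`, `region`, `power` (for one or more subjects).
#' @param subject_id Subject to assemble.
#' @param bands,regions Canonical band and region orders.
#' @return Named numeric feature vector (length `6 * bands * regions`) with
#'   attribute `subject_id`.
#' @export
assemble_features <- function(power_table, subject_id,
                              bands = meg_bands()$name,
                              regions = NULL) {
  tab <- power_table[power_table$subject_id == subject_id, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop_megspect(sprintf("no rows for subject %s", subject_id),
                  "megspect_missing_subject")
  }
  if (is.null(regions)) {
    regions <- if (is.factor(power_table$region)) {
      levels(power_table$region)
    } else {
      unique(power_table$region)
    }
  }
  idx <- feature_index(bands, regions)
  out <- numeric(nrow(idx))
  names(out) <- idx$name
  key <- function(cond, band) {
    sl <- tab[tab$condition == cond & tab$band == band, , drop = FALSE]
    v <- sl$power[match(regions, as.character(sl$region))]
    if (anyNA(v)) {
      stop_megspect(sprintf(
        "incomplete power table for subject %s: condition %s, band %s",
        subject_id, cond, band), "megspect_missing_cell")
    }
    names(v) <- regions
    v
  }
  for (b in bands) {
    ec <- key("EC", b)
    eo <- key("EO", b)
    dd <- ec_eo_difference(ec, eo)
    put <- function(vt, vals) {
      out[idx$value_type == vt & idx$band == b] <<- vals
    }
    put("absEC", ec)
    put("absEO", eo)
    put("wcnEC", wcn_normalize(ec))
    put("wcnEO", wcn_normalize(eo))
    put("diffECEO", dd)
    put("wcnDiff", wcn_normalize(dd))
  }
  attr(out, "subject_id") <- subject_id
  out
}

#' Assemble the cohort feature matrix
#'
#' @param power_table Long region-power table for all subjects (columns
#'   `subject_id`, `group`, `condition`, `band`, `region`, `power`).
#' @param bands,regions Canonical orders (defaults inferred as in
#'   [assemble_features()]).
#' @return A list of class `meg_features`: `x` (subjects x features matrix,
#'   canonical column names), `group` (factor `NC`/`AD`), `subject_id`,
#'   `index` (the [feature_index()] table).
#' @export
assemble_feature_matrix <- function(power_table, bands = meg_bands()$name,
                                    regions = NULL) {
  subjects <- unique(power_table$subject_id)
  if (is.null(regions)) {
    regions <- if (is.factor(power_table$region)) {
      levels(power_table$region)
    } else {
      unique(power_table$region)
    }
  }
  idx <- feature_index(bands, regions)
  x <- matrix(NA_real_, length(subjects), nrow(idx),
              dimnames = list(subjects, idx$name))
  for (s in subjects) {
    x[s, ] <- assemble_features(power_table, s, bands, regions)
  }
  grp <- power_table$group[match(subjects, power_table$subject_id)]
  structure(list(x = x, group = factor(grp, levels = c("NC", "AD")),
                 subject_id = subjects, index = idx),
            class = "meg_features")
}
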