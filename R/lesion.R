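# Alkaline-gel lesion quantification: ladder calibration (log-linear in
# fragment size), median-intensity fragment size per lane, and Poisson
# fragment statistics converting median mass-weighted fragment size into
# lesions per kb, with background (no-enzyme) subtraction.

# linear interpolation with linear extrapolation beyond the end knots
lin_interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) >= 2, !is.unsorted(x, strictly = TRUE))
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    k <- length(x)
    s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    out[hi] <- y[k] + s * (xout[hi] - x[k])
  }
  out
}

#' Standard HindIII-digested lambda phage ladder fragment sizes
#'
#' The seven resolvable bands in bp; an editable default, not a constant
#' of the method — pair with gel-specific migration distances to build a
#' calibration.
#'
#' @return numeric vector of fragment sizes (bp), largest first.
#' @export
lambda_hindiii_sizes <- function() {
  c(23130, 9416, 6557, 4361, 2322, 2027, 564)
}

#' Calibrate a migration-to-size map from ladder bands
#'
#' Fits a monotone map from migration distance to fragment size by
#' linear interpolation of log10(size) against migration, with linear
#' extrapolation beyond the outermost bands. Queries at band migrations
#' return the band sizes exactly.
#'
#' @param bands tibble/data frame with columns `size_bp` and `migration`;
#'   at least two bands, migration strictly increasing as size strictly
#'   decreases.
#' @return object of class `gel_calibration` with functions `size_at()`
#'   (migration -> size bp) and `migration_at()` (size bp -> migration).
#' @export
calibrate_ladder <- function(bands) {
  if (!all(c("size_bp", "migration") %in% names(bands))) {
    abort("bands must have columns size_bp and migration")
  }
  if (nrow(bands) < 2) abort("at least two ladder bands are required")
  ord <- order(bands$migration)
  mig <- bands$migration[ord]
  size <- bands$size_bp[ord]
  if (any(diff(mig) <= 0) || any(diff(size) >= 0)) {
    abort("ladder bands must be strictly monotone: migration increasing, size decreasing")
  }
  structure(list(
    bands = tibble(size_bp = size, migration = mig),
    size_at = function(migration) {
      10^lin_interp_extrap(mig, log10(size), migration)
    },
    migration_at = function(size_bp) {
      lin_interp_extrap(rev(log10(size)), rev(mig), log10(size_bp))
    }
  ), class = "gel_calibration")
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat("<gel_calibration> ", nrow(x$bands), " bands, ",
      min(x$bands$size_bp), "-", max(x$bands$size_bp), " bp\n", sep = "")
  invisible(x)
}

#' Read a densitometry lane profile
#'
#' @param path 2-column TSV (`migration`, `intensity`).
#' @param lane_role one of `"no_enzyme"`, `"t4_endoV"`, `"cpdpl_uvde"`.
#' @return tibble with the role in the `"lane_role"` attribute.
#' @export
read_lane_profile <- function(path, lane_role = c("no_enzyme", "t4_endoV", "cpdpl_uvde")) {
  lane_role <- match.arg(lane_role)
  lane <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("migration", "intensity") %in% names(lane))) {
    abort("lane profile must have columns migration and intensity")
  }
  attr(lane, "lane_role") <- lane_role
  lane
}

#' Median-intensity fragment size of a lane
#'
#' Finds the migration at which cumulative lane intensity reaches 50% of
#' the lane total (weighted median with midpoint convention, linear
#' interpolation between samples) and maps it to a fragment size through
#' the ladder calibration. Scaling all intensities by a positive
#' constant leaves the result unchanged.
#'
#' @param lane tibble with `migration` (strictly increasing) and
#'   `intensity` (>= 0, positive total).
#' @param calibration a [calibrate_ladder()] object.
#' @return median fragment size in kb. Warns when the median migration
#'   lies outside the calibrated band range (extrapolation).
#' @export
estimate_median_fragment_size <- function(lane, calibration) {
  if (is.unsorted(lane$migration, strictly = TRUE)) {
    abort("lane migrations must be strictly increasing")
  }
  if (any(lane$intensity < 0)) abort("intensities must be non-negative")
  total <- sum(lane$intensity)
  if (total <= 0) abort("lane has zero total intensity")
  pos <- lane[lane$intensity > 0, ]
  cum <- cumsum(pos$intensity)
  f <- (cum - 0.5 * pos$intensity) / total
  med_mig <- if (nrow(pos) == 1 || f[1] >= 0.5) {
    pos$migration[1]
  } else if (f[length(f)] <= 0.5) {
    pos$migration[nrow(pos)]
  } else {
    stats::approx(f, pos$migration, xout = 0.5)$y
  }
  rng <- range(calibration$bands$migration)
  if (med_mig < rng[1] || med_mig > rng[2]) {
    warn("median migration outside the calibrated ladder range; extrapolating")
  }
  calibration$size_at(med_mig) / 1000
}

#' Lesion frequency from an enzyme-digested and a control lane
#'
#' Under random (Poisson) lesion placement, fragment lengths after
#' complete lesion-specific cleavage are exponential with rate equal to
#' the break frequency, and the mass-weighted median fragment length is
#' about 1.678/rate (median of the length-biased, i.e. gamma(2),
#' distribution) — hence the default `correction = 1.678` applied to the
#' reciprocal median size. `correction = 1` gives the naive reciprocal.
#' The no-enzyme control frequency is subtracted to remove background
#' cutting; a negative net frequency floors at 0 with `floored = TRUE`.
#'
#' @param enzyme_lane,control_lane lane tibbles (see
#'   [read_lane_profile()]).
#' @param calibration a [calibrate_ladder()] object.
#' @param correction Poisson fragment-size correction factor.
#' @param lesion_kind `"CPD"` (T4 endoV digestion) or `"non_CPD"`
#'   (photolyase-pretreated UVDE digestion).
#' @return one-row tibble: `lesion_kind`, `median_size_enzyme_kb`,
#'   `median_size_control_kb`, `freq_enzyme`, `freq_control`,
#'   `net_lesions_per_kb`, `correction`, `floored`.
#' @export
lesion_frequency <- function(enzyme_lane, control_lane, calibration,
                             correction = 1.678,
                             lesion_kind = c("CPD", "non_CPD")) {
  lesion_kind <- match.arg(lesion_kind)
  stopifnot(correction > 0)
  m_e <- estimate_median_fragment_size(enzyme_lane, calibration)
  m_c <- estimate_median_fragment_size(control_lane, calibration)
  f_e <- correction / m_e
  f_c <- correction / m_c
  net <- f_e - f_c
  floored <- net < 0
  if (floored) {
    warn("background exceeds enzyme-lane signal; net lesion frequency floored at 0")
    net <- 0
  }
  tibble(lesion_kind = lesion_kind,
         median_size_enzyme_kb = m_e, median_size_control_kb = m_c,
         freq_enzyme = f_e, freq_control = f_c,
         net_lesions_per_kb = net, correction = correction,
         floored = floored)
}

#' Total lesions formed per cell
#'
#' lesions/kb per strand x haploid genome size (kb) x ploidy x 2 strands.
#'
#' @param net_lesions_per_kb net lesion frequency (per kb per strand).
#' @param genome a [uv_genome()], or NULL with explicit size/ploidy.
#' @param haploid_size_kb,ploidy explicit genome size and ploidy.
#' @return lesion count (numeric scalar).
#' @export
total_lesions <- function(net_lesions_per_kb, genome = NULL,
                          haploid_size_kb = NULL, ploidy = NULL) {
  if (!is.null(genome)) {
    haploid_size_kb <- haploid_size_kb %||% genome$haploid_size_kb
    ploidy <- ploidy %||% genome$ploidy
  }
  stopifnot(net_lesions_per_kb >= 0, haploid_size_kb > 0, ploidy >= 1)
  net_lesions_per_kb * haploid_size_kb * ploidy * 2
}
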