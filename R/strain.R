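#' Per-element area strain curves
#'
#' Percentage area change of each local surface element with respect to the
#' end-diastolic reference anatomy (frame 1): `100 * (A_e(t) - A_e(0)) /
#' A_e(0)`. Positive strain denotes endocardial expansion, negative strain
#' contraction.
#'
#' @param seq A [mesh_frame_sequence()].
#' @return Numeric `F x T` matrix of strains (%). Elements whose reference
#'   area is degenerate (< 1e-12 mm^2) are excluded: their rows are `NA` and
#'   their indices stored in attribute `"excluded_elements"`.
#' @export
area_strain <- function(seq) {
  ref <- element_areas(seq$vertices_per_frame[[1]], seq$faces)
  degen <- attr(ref, "degenerate")
  out <- vapply(seq$vertices_per_frame, function(v) {
    a <- element_areas(v, seq$faces)
    100 * (a - ref) / ref
  }, numeric(length(ref)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(ref))
  if (!is.null(degen)) {
    out[degen, ] <- NA_real_
    attr(out, "excluded_elements") <- degen
    message(length(degen), " degenerate reference element(s) excluded from strain")
  }
  out
}

#' Aggregate elemental strain into global and regional curves
#'
#' Global curve = unweighted mean of elemental area strains over all
#' non-excluded LA body elements; regional curves = unweighted means within
#' each of the five wall regions. Elements labelled `"excluded"` (pulmonary
#' vein / appendage analogues) and degenerate elements are omitted. Strain
#' rates are first differences with respect to normalized time: central
#' differences at interior samples, one-sided at the ends.
#'
#' @param elem_strain `F x T` matrix from [area_strain()].
#' @param region_labels Per-face labels (see [LA_REGIONS]).
#' @param frame_times Normalized R-R times of the columns.
#' @param area_weights Optional per-face weights for area-weighted averaging;
#'   default `NULL` means unweighted means.
#' @return A `strain_curve_set`: list with `frame_times`, `global` (length
#'   T), `regional` (`T x 5` matrix), `global_sr`, `regional_sr` (% per
#'   normalized time).
#' @export
aggregate_curves <- function(elem_strain, region_labels, frame_times,
                             area_weights = NULL) {
  keep <- region_labels %in% LA_REGIONS & !is.na(elem_strain[, 1])
  if (!any(keep)) stop("no usable body elements")
  w <- if (is.null(area_weights)) rep(1, nrow(elem_strain)) else area_weights
  wmean <- function(rows) {
    if (!any(rows)) stop("empty region")
    colSums(elem_strain[rows, , drop = FALSE] * w[rows]) / sum(w[rows])
  }
  gl <- wmean(keep)
  # regions absent from the labelling yield NA curves; a declared region
  # whose elements are all excluded/degenerate is an error
  reg <- sapply(LA_REGIONS, function(r) {
    if (!any(region_labels == r)) return(rep(NA_real_, ncol(elem_strain)))
    wmean(keep & region_labels == r)
  })
  structure(list(frame_times = frame_times, global = gl, regional = reg,
                 global_sr = strain_rate(gl, frame_times),
                 regional_sr = apply(reg, 2, strain_rate, t = frame_times)),
            class = "strain_curve_set")
}

#' First time-derivative of a sampled strain curve
#'
#' Central differences at interior samples, forward/backward differences at
#' the first/last sample, with respect to normalized R-R time.
#'
#' @param s Sampled strain values (%).
#' @param t Sample times (normalized R-R fraction).
#' @return Strain rate (% per normalized time), same length as `s`.
#' @export
strain_rate <- function(s, t) {
  n <- length(s)
  sr <- numeric(n)
  sr[1] <- (s[2] - s[1]) / (t[2] - t[1])
  sr[n] <- (s[n] - s[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    sr[i] <- (s[i + 1] - s[i - 1]) / (t[i + 1] - t[i - 1])
  }
  sr
}

# monotone-cubic interpolant of a sampled cyclic strain curve; the cycle is
# closed by appending S(1) = S(0)
curve_interpolant <- function(s, t) {
  stats::splinefun(c(t, 1), c(s, s[1]), method = "monoH.FC")
}

#' Automatic reservoir / conduit / contractile phase segmentation
#'
#' Identifies the atrial functional phase boundaries on a sampled global area
#' strain curve. Minimum strain defines end-diastole (`t_ed`); if the minimum
#' is not at frame 1 the curve is cyclically re-referenced (times rotated,
#' strain re-zeroed at the minimum). Peak reservoir strain time `t_peak` is
#' the argmax of a monotone-cubic interpolant. The conduit-contractile
#' boundary `t_cc` is the level-off point: the earliest post-downslope time
#' at which the downslope magnitude falls below `alpha` times the peak
#' conduit downslope, snapped to the nearest frame time. Detection failures
#' return `status = "needs_correction"` rather than a silent default; a
#' manual override is available through [correct_phases()].
#'
#' @param s Sampled global strain curve (%), length >= 8.
#' @param t Normalized frame times, same length.
#' @param alpha Level-off fraction of the peak conduit downslope (default
#'   0.2).
#' @param min_contractile_frac Minimum fraction of reservoir strain that must
#'   remain at the candidate `t_cc` for automatic acceptance; below it the
#'   curve has no usable contractile phase and review is requested.
#' @return A `phase_boundaries` object: list with `t_ed` (always 0 after
#'   re-referencing), `t_peak`, `t_cc`, `status` (`"automatic"` or
#'   `"needs_correction"`), `detection_mode`, `rotation` (frame offset applied),
#'   and `alpha`.
#' @export
detect_phases <- function(s, t, alpha = 0.2, min_contractile_frac = 0.05) {
  if (length(s) < 8) stop("need at least 8 samples")
  rot <- which.min(s) - 1L
  if (rot != 0) {
    idx <- c((rot + 1):length(s), seq_len(rot))
    s <- s[idx] - s[rot + 1]
    # rotated sampling grid re-expressed on [0, 1)
    t <- sort((t - t[rot + 1]) %% 1)
  }
  if (max(s) <= 0) stop("strain curve has no positive peak")
  f <- curve_interpolant(s, t)
  grid <- seq(0, 1, length.out = 2001)
  vals <- f(grid)
  t_peak <- grid[which.max(vals)]
  post <- grid > t_peak & grid < 1
  ds <- f(grid[post], deriv = 1)
  res <- list(t_ed = 0, t_peak = t_peak, t_cc = NA_real_,
              status = "needs_correction", detection_mode = "automatic",
              rotation = rot, alpha = alpha)
  class(res) <- "phase_boundaries"
  # the conduit downslope is the first local minimum of dS/dt after the
  # peak; the later contractile downslope may be steeper and must not win
  turn <- which(diff(ds) > 0)
  i_down <- if (length(turn)) turn[1] else which.min(ds)
  peak_down <- ds[i_down]
  if (peak_down >= 0) return(res)  # no conduit decline after the peak
  level <- which(abs(ds[i_down:length(ds)]) <= alpha * abs(peak_down))
  if (!length(level)) return(res)
  t_cc_raw <- grid[post][i_down + level[1] - 1L]
  dt <- stats::median(diff(t))
  t_cc <- t[which.min(abs(t - t_cc_raw))]  # snap to frame grid
  if (t_cc <= t_peak) t_cc <- min(t[t > t_peak])
  # reject level-offs in the terminal return to baseline (no contractile
  # phase) or in the last sampling interval
  if (f(t_cc) < min_contractile_frac * max(vals) || t_cc_raw >= 1 - dt)
    return(res)
  res$t_cc <- t_cc
  res$status <- "automatic"
  res
}

#' Manually correct automatically detected phase boundaries
#'
#' Mirrors the manual review step of phase segmentation: overrides the
#' automatic conduit-contractile boundary (and optionally the peak time) and
#' marks the result as corrected.
#'
#' @param phases A `phase_boundaries` object from [detect_phases()].
#' @param t_cc Replacement conduit-contractile boundary time.
#' @param t_peak Optional replacement peak reservoir time.
#' @return The corrected `phase_boundaries` object.
#' @export
correct_phases <- function(phases, t_cc, t_peak = NULL) {
  stopifnot(inherits(phases, "phase_boundaries"))
  if (!is.null(t_peak)) phases$t_peak <- t_peak
  if (!(phases$t_peak < t_cc && t_cc < 1))
    stop("require t_peak < t_cc < 1")
  phases$t_cc <- t_cc
  phases$status <- "automatic"
  phases$detection_mode <- "corrected"
  phases
}

#' @export
print.phase_boundaries <- function(x, ...) {
  cat(sprintf("phase_boundaries: t_ed = 0, t_peak = %.3f, t_cc = %s [%s, %s]\n",
              x$t_peak, ifelse(is.na(x$t_cc), "NA", sprintf("%.3f", x$t_cc)),
              x$status, x$detection_mode))
  invisible(x)
}

# apply the cyclic re-referencing chosen by detect_phases to a curve set
rereference_curves <- function(curves, phases) {
  rot <- phases$rotation
  if (rot == 0) return(curves)
  n <- length(curves$global)
  idx <- c((rot + 1):n, seq_len(rot))
  t <- sort((curves$frame_times - curves$frame_times[rot + 1]) %% 1)
  gl <- curves$global[idx] - curves$global[rot + 1]
  reg <- sweep(curves$regional[idx, , drop = FALSE], 2,
               curves$regional[rot + 1, ])
  structure(list(frame_times = t, global = gl, regional = reg,
                 global_sr = strain_rate(gl, t),
                 regional_sr = apply(reg, 2, strain_rate, t = t)),
            class = "strain_curve_set")
}

#' Extract phasic strains and peak strain rates
#'
#' Reads reservoir, conduit and contractile strain and the three peak strain
#' rates off the global and five regional curves, using the global phase
#' boundaries for every scope. With `S` the (re-referenced) strain curve:
#' reservoir = `S(t_peak)`, conduit = `S(t_peak) - S(t_cc)`, contractile =
#' `S(t_cc)`, so reservoir = conduit + contractile exactly for every scope.
#' Peak SRs are the maximum SR in the reservoir window and the (signed,
#' negative) minima in the conduit and contractile windows.
#'
#' @param curves A `strain_curve_set` from [aggregate_curves()].
#' @param phases A `phase_boundaries` object with a detected or corrected
#'   `t_cc`.
#' @return A `phasic_metrics` data frame with one row per scope (`global`
#'   plus the five regions) and columns `reservoir_strain`, `conduit_strain`,
#'   `contractile_strain` (%), `reservoir_sr`, `conduit_sr`, `contractile_sr`
#'   (% per normalized time; conduit/contractile stored signed).
#' @export
phasic_metrics <- function(curves, phases) {
  stopifnot(inherits(phases, "phase_boundaries"))
  if (is.na(phases$t_cc))
    stop("phase boundaries need correction before metric extraction")
  curves <- rereference_curves(curves, phases)
  t <- curves$frame_times
  tp <- phases$t_peak; tcc <- phases$t_cc
  if (tp <= 0 || tcc >= 1) stop("phase boundaries outside curve support")
  scope_metrics <- function(s, sr) {
    fs <- curve_interpolant(s, t)
    res <- fs(tp) - s[1]
    ctr <- fs(tcc) - s[1]
    con <- res - ctr
    c(reservoir_strain = res, conduit_strain = con, contractile_strain = ctr,
      reservoir_sr = max(sr[t <= tp]),
      conduit_sr = min(sr[t >= tp & t <= tcc]),
      contractile_sr = min(sr[t >= tcc]))
  }
  present <- LA_REGIONS[!is.na(curves$regional[1, ])]
  rows <- rbind(global = scope_metrics(curves$global, curves$global_sr),
                t(vapply(present, function(r)
                  scope_metrics(curves$regional[, r], curves$regional_sr[, r]),
                  numeric(6))))
  out <- data.frame(scope = rownames(rows), rows, row.names = NULL)
  class(out) <- c("phasic_metrics", "data.frame")
  out
}

#' Flatten phasic metrics into the 36-parameter feature vector
#'
#' @param metrics A `phasic_metrics` data frame (6 scopes x 6 parameters).
#' @return Named numeric vector of length 36 (`<scope>.<parameter>`).
#' @export
feature_vector <- function(metrics) {
  stopifnot(inherits(metrics, "phasic_metrics"))
  vals <- as.matrix(metrics[, -1])
  out <- as.numeric(t(vals))
  names(out) <- as.vector(t(outer(metrics$scope, colnames(vals), paste,
                                  sep = ".")))
  out
}

#' Body surface area (Mosteller)
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BSA in m^2, `sqrt(height * weight / 3600)`.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  stopifnot(all(height_cm > 0), all(weight_kg > 0))
  sqrt(height_cm * weight_kg / 3600)
}

#' CT chamber volumetrics
#'
#' End-diastolic and end-systolic volumes, stroke volumes, emptying/ejection
#' fractions and BSA-indexed volumes from per-frame LA and LV volume curves.
#' LA EDV is the frame-1 (minimum) volume and LA ESV the maximum; for the LV
#' the convention reverses (EDV = maximum, ESV = minimum). LAEF =
#' `100 * (ESV - EDV) / ESV`; LVEF = `100 * (EDV - ESV) / EDV`.
#'
#' @param la_curve,lv_curve `volume_curve` objects (mL per frame).
#' @param height_cm,weight_kg Subject anthropometrics for BSA indexing.
#' @return Named list of volumetric parameters (`la_edv`, `la_esv`, `la_sv`,
#'   `laef`, `la_edvi`, `la_esvi`, `lv_edv`, `lv_esv`, `lv_sv`, `lvef`,
#'   `lv_edvi`, `lv_esvi`, `bsa`). A `flag` element notes non-physiologic
#'   curves (LA frame-1 volume not the minimum).
#' @export
volumetrics <- function(la_curve, lv_curve, height_cm, weight_kg) {
  stopifnot(all(la_curve$volumes > 0), all(lv_curve$volumes > 0))
  bsa <- bsa_mosteller(height_cm, weight_kg)
  la <- la_curve$volumes; lv <- lv_curve$volumes
  la_edv <- la[1]; la_esv <- max(la)
  flag <- NULL
  if (min(la) < la_edv - 1e-9)
    flag <- "non-physiologic LA curve: frame-1 volume is not the minimum"
  lv_edv <- max(lv); lv_esv <- min(lv)
  list(la_edv = la_edv, la_esv = la_esv, la_sv = la_esv - la_edv,
       laef = 100 * (la_esv - la_edv) / la_esv,
       la_edvi = la_edv / bsa, la_esvi = la_esv / bsa,
       lv_edv = lv_edv, lv_esv = lv_esv, lv_sv = lv_edv - lv_esv,
       lvef = 100 * (lv_edv - lv_esv) / lv_edv,
       lv_edvi = lv_edv / bsa, lv_esvi = lv_esv / bsa,
       bsa = bsa, flag = flag)
}

#' Full strain analysis of one mesh sequence
#'
#' Convenience wrapper: elemental area strain, curve aggregation, automatic
#' phase detection and phasic metric extraction for a single subject.
#'
#' @param seq A [mesh_frame_sequence()].
#' @param alpha Level-off fraction for [detect_phases()].
#' @return List with `curves`, `phases`, `metrics` and `features` (the
#'   36-parameter vector).
#' @export
analyze_sequence <- function(seq, alpha = 0.2) {
  es <- area_strain(seq)
  curves <- aggregate_curves(es, seq$region_labels, seq$frame_times)
  phases <- detect_phases(curves$global, curves$frame_times, alpha = alpha)
  if (phases$status == "needs_correction")
    stop("automatic phase detection failed; use detect_phases()/correct_phases()")
  metrics <- phasic_metrics(curves, phases)
  list(curves = curves, phases = phases, metrics = metrics,
       features = feature_vector(metrics))
}

#' Compare phasic metrics at 10-frame vs 20-frame sampling
#'
#' Re-analyses a 20-frame sequence (5% R-R increments) using only every
#' other frame (10 frames at 10% increments) and returns per-parameter
#' absolute differences of the global phasic strains and peak SRs between the
#' two temporal resolutions.
#'
#' @param seq A 20-frame [mesh_frame_sequence()].
#' @param alpha Level-off fraction for phase detection.
#' @return List with `metrics_20`, `metrics_10` (global rows), and
#'   `abs_diff`, a named vector of |difference| for the six global
#'   parameters.
#' @export
frame_count_comparison <- function(seq, alpha = 0.2) {
  if (n_frames(seq) != 20) stop("frame count must be 20")
  res20 <- analyze_sequence(seq, alpha = alpha)
  keep <- seq(1, 20, by = 2)
  seq10 <- mesh_frame_sequence(seq$vertices_per_frame[keep], seq$faces,
                               seq$frame_times[keep], seq$region_labels)
  res10 <- analyze_sequence(seq10, alpha = alpha)
  g20 <- unlist(res20$metrics[res20$metrics$scope == "global", -1])
  g10 <- unlist(res10$metrics[res10$metrics$scope == "global", -1])
  list(metrics_20 = g20, metrics_10 = g10, abs_diff = abs(g10 - g20))
}

#' Cohort-level 10- vs 20-frame robustness summary
#'
#' Runs [frame_count_comparison()] on a list of 20-frame sequences and
#' summarizes the mean absolute differences across subjects, separately for
#' the three phasic strains and the three peak SRs.
#'
#' @param seqs List of 20-frame mesh sequences.
#' @param alpha Level-off fraction for phase detection.
#' @return List with `per_subject` (matrix of |differences|),
#'   `mean_abs_strain_diff` (%), `mean_abs_sr_diff` (% per normalized time).
#' @export
cohort_frame_count_comparison <- function(seqs, alpha = 0.2) {
  per <- t(vapply(seqs, function(s) frame_count_comparison(s, alpha)$abs_diff,
                  numeric(6)))
  strain_cols <- c("reservoir_strain", "conduit_strain", "contractile_strain")
  sr_cols <- c("reservoir_sr", "conduit_sr", "contractile_sr")
  list(per_subject = per,
       mean_abs_strain_diff = mean(per[, strain_cols]),
       mean_abs_sr_diff = mean(per[, sr_cols]))
}
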