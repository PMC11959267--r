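test_that("area strain matches per-triangle recomputation on anisotropic stretch", {
  withr::with_seed(3, {
    ico <- unit_sphere(2)
    v0 <- ico$vertices * 15 + matrix(stats::rnorm(length(ico$vertices), sd = 0.5),
                                     ncol = 3)
  })
  A <- diag(c(1.2, 1.0, 1.0))
  sq <- mesh_frame_sequence(list(v0, v0 %*% A), ico$faces, c(0, 0.5),
                            rep("lateral", nrow(ico$faces)))
  es <- area_strain(sq)
  # brute-force oracle: recompute both triangle areas directly
  tri_area <- function(p1, p2, p3) {
    cr <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
            (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
            (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
    0.5 * sqrt(sum(cr^2))
  }
  v1 <- v0 %*% A
  for (t in sample(nrow(ico$faces), 40)) {
    f <- ico$faces[t, ]
    a0 <- tri_area(v0[f[1], ], v0[f[2], ], v0[f[3], ])
    a1 <- tri_area(v1[f[1], ], v1[f[2], ], v1[f[3], ])
    expect_equal(es[t, 2], 100 * (a1 - a0) / a0, tolerance = 1e-10)
  }
  expect_true(all(es[, 1] == 0))
})

test_that("curve aggregation takes unweighted means within and across regions", {
  # 4 elements, two regions, strains 10 and 30
  elem <- matrix(c(0, 0, 0, 0, 10, 10, 30, 30), ncol = 2)
  lab <- c("septum", "septum", "lateral", "lateral")
  cv <- aggregate_curves(elem, lab, c(0, 0.5))
  expect_equal(unname(cv$global), c(0, 20))
  expect_equal(unname(cv$regional[2, "septum"]), 10)
  expect_equal(unname(cv$regional[2, "lateral"]), 30)
  expect_error(aggregate_curves(elem, rep("excluded", 4), c(0, 0.5)),
               "no usable body elements")
})

test_that("uniform elemental strain propagates unchanged to every curve", {
  elem <- matrix(rep(c(0, 21), each = 20), nrow = 20)
  lab <- rep(LA_REGIONS, each = 4)
  cv <- aggregate_curves(elem, lab, c(0, 0.5))
  expect_equal(unname(cv$global[2]), 21)
  expect_true(all(cv$regional[2, ] == 21))
})

test_that("strain rate is the central-difference derivative and inverts exactly", {
  t <- seq(0, 0.9, by = 0.1)
  s <- pwl_curve(t)
  sr <- strain_rate(s, t)
  # linear rise 0->25 over [0, 0.4]: slope 62.5 at interior linear samples
  expect_equal(sr[1], 62.5)
  expect_equal(sr[2], 62.5)
  expect_equal(sr[3], 62.5)
  # exact inversion of the scheme: s[i+1] = s[i-1] + 2 dt sr[i]
  rec <- numeric(length(s))
  rec[1] <- s[1]
  rec[2] <- rec[1] + 0.1 * sr[1]
  for (i in 3:length(s)) rec[i] <- rec[i - 2] + 2 * 0.1 * sr[i - 1]
  expect_equal(rec, s, tolerance = 1e-12)
})

test_that("phase detection finds the constructed level-off and flags degenerate curves", {
  t <- seq(0, 0.95, by = 0.05)
  ph <- detect_phases(pwl_curve(t), t)
  expect_equal(ph$status, "automatic")
  expect_equal(ph$t_peak, 0.4, tolerance = 0.01)
  expect_equal(ph$t_cc, 0.7)

  # pure single bump with no plateau: explicit needs-correction status
  t10 <- seq(0, 0.9, by = 0.1)
  bump <- 10 * (1 - cos(2 * pi * t10)) / 2
  ph2 <- detect_phases(bump, t10)
  expect_equal(ph2$status, "needs_correction")
  expect_true(is.na(ph2$t_cc))

  # curve with no positive excursion: no reservoir peak
  expect_error(detect_phases(rep(0, 10), t10), "no positive peak")
  # monotone decline (no conduit level-off after re-referencing)
  expect_equal(detect_phases(c(0, -(1:9)), t10)$status, "needs_correction")
  expect_error(detect_phases(pwl_curve(c(0, 0.5)), c(0, 0.5)), "8 samples")
})

test_that("smooth-mode generator boundaries are detected within one frame interval", {
  p <- motion_params(25, 0.55, t_peak = 0.4, t_cc = 0.7, n_frames = 20,
                     transient_mode = "smooth")
  sq <- generate_mesh_sequence(p, la_base_shape(subdivisions = 2))
  cv <- aggregate_curves(area_strain(sq), sq$region_labels, sq$frame_times)
  ph <- detect_phases(cv$global, cv$frame_times)
  expect_equal(ph$status, "automatic")
  expect_lt(abs(ph$t_peak - 0.4), 0.05 + 1e-9)
  expect_lt(abs(ph$t_cc - 0.7), 0.05 + 1e-9)
})

test_that("manual correction overrides t_cc and records the mode", {
  t <- seq(0, 0.95, by = 0.05)
  ph <- detect_phases(pwl_curve(t), t)
  ph2 <- correct_phases(ph, t_cc = 0.75)
  expect_equal(ph2$t_cc, 0.75)
  expect_equal(ph2$detection_mode, "corrected")
  expect_error(correct_phases(ph, t_cc = 0.2), "t_peak < t_cc")
})

test_that("phasic metrics partition reservoir into conduit + contractile", {
  t <- seq(0, 0.95, by = 0.05)
  elem <- rbind(pwl_curve(t), pwl_curve(t))  # two identical elements
  cv <- aggregate_curves(elem, c("septum", "anterior"), t)
  ph <- detect_phases(cv$global, t)
  m <- phasic_metrics(cv, ph)
  g <- m[m$scope == "global", ]
  # the monotone interpolant may overshoot the sampled peak by O(1e-2)
  expect_equal(g$reservoir_strain, 25, tolerance = 2e-3)
  expect_equal(g$conduit_strain, 13, tolerance = 2e-3)
  expect_equal(g$contractile_strain, 12, tolerance = 2e-3)
  # identity holds exactly for every scope
  expect_equal(m$reservoir_strain,
               m$conduit_strain + m$contractile_strain, tolerance = 1e-12)
  # reservoir SR on the linear rise: slope 25/0.4
  expect_equal(g$reservoir_sr, 62.5)
  expect_true(g$conduit_sr <= 0)
  expect_true(g$contractile_sr <= 0)
})

test_that("cyclic re-referencing recovers metrics from a rotated curve", {
  t <- seq(0, 0.95, by = 0.05)
  s <- pwl_curve(t)
  # rotate so the minimum lands mid-sequence, with a baseline offset
  rot <- 7
  s_rot <- c(s[(rot + 1):length(s)], s[seq_len(rot)]) + 5
  ph <- detect_phases(s_rot, t)
  expect_equal(ph$rotation, length(t) - rot)
  elem <- rbind(s_rot, s_rot)
  cv <- aggregate_curves(elem, c("septum", "anterior"), t)
  m <- phasic_metrics(cv, ph)
  g <- m[m$scope == "global", ]
  expect_equal(g$reservoir_strain, 25, tolerance = 0.3)
  expect_equal(g$conduit_strain, 13, tolerance = 0.3)
})

test_that("metric extraction refuses unresolved phase boundaries", {
  t10 <- seq(0, 0.9, by = 0.1)
  bump <- 10 * (1 - cos(2 * pi * t10)) / 2
  ph <- detect_phases(bump, t10)
  elem <- rbind(bump, bump)
  cv <- aggregate_curves(elem, c("septum", "anterior"), t10)
  expect_error(phasic_metrics(cv, ph), "need correction")
})

test_that("volumetrics reproduce the closed-form definitions", {
  la <- structure(list(chamber = "LA", volumes = c(50, 70, 100, 90, 60),
                       frame_times = seq(0, 0.8, by = 0.2)),
                  class = "volume_curve")
  lv <- structure(list(chamber = "LV", volumes = c(150, 100, 75, 100, 140),
                       frame_times = seq(0, 0.8, by = 0.2)),
                  class = "volume_curve")
  v <- volumetrics(la, lv, height_cm = 180, weight_kg = 81)
  expect_equal(v$laef, 50)
  expect_equal(v$la_sv, 50)
  expect_equal(v$bsa, sqrt(180 * 81 / 3600))
  expect_equal(v$bsa, 2.012, tolerance = 1e-3)
  expect_equal(v$la_edvi, 50 / v$bsa)
  expect_equal(v$lvef, 50)
  expect_null(v$flag)

  flat <- structure(list(chamber = "LA", volumes = rep(80, 5),
                         frame_times = seq(0, 0.8, by = 0.2)),
                    class = "volume_curve")
  v2 <- volumetrics(flat, lv, 180, 81)
  expect_equal(v2$laef, 0)
  expect_equal(v2$la_sv, 0)

  sag <- structure(list(chamber = "LA", volumes = c(50, 40, 100, 90, 60),
                        frame_times = seq(0, 0.8, by = 0.2)),
                   class = "volume_curve")
  expect_match(volumetrics(sag, lv, 180, 81)$flag, "non-physiologic")
})

test_that("the feature vector flattens 6 scopes x 6 parameters", {
  p <- motion_params(21, 0.5, n_frames = 10)
  ana <- analyze_sequence(generate_mesh_sequence(p, la_base_shape(2)))
  expect_length(ana$features, 36)
  expect_setequal(names(ana$features), phasic_feature_names())
})
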