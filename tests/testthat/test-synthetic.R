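test_that("uniform radial motion reproduces the scaling law to machine precision", {
  p <- motion_params(reservoir_amplitude = 21, contractile_fraction = 0.5,
                     noise_sd = 0, n_frames = 10)
  sq <- generate_mesh_sequence(p)
  es <- area_strain(sq)
  S <- strain_transient(p)
  expect_lt(max(abs(sweep(es, 2, S(sq$frame_times)))), 1e-9)
  # at t_peak = 0.4 (a sample) every element is at 21% (scale sqrt(1.21))
  k <- which(sq$frame_times == 0.4)
  expect_equal(unname(es[, k]), rep(21, nrow(es)), tolerance = 1e-12)
})

test_that("zero reservoir amplitude yields identity motion", {
  p <- motion_params(reservoir_amplitude = 0, contractile_fraction = 0.5)
  sq <- generate_mesh_sequence(p)
  for (k in 2:length(sq$vertices_per_frame))
    expect_identical(sq$vertices_per_frame[[k]], sq$vertices_per_frame[[1]])
  expect_true(all(abs(area_strain(sq)) < 1e-12))
})

test_that("the prescribed transient partitions emptying into conduit + contractile", {
  for (mode in c("cubic", "smooth")) {
    p <- motion_params(28, 15.6 / 28.2, transient_mode = mode)
    S <- strain_transient(p)
    reservoir <- S(p$t_peak)
    conduit <- S(p$t_peak) - S(p$t_cc)
    contractile <- S(p$t_cc) - S(0)
    expect_equal(reservoir, 28)
    expect_equal(conduit + contractile, reservoir, tolerance = 1e-12)
    expect_equal(S(0), 0)
    # monotone rise then monotone fall around the prescribed knots
    tt <- seq(0, p$t_peak, length.out = 50)
    expect_true(all(diff(S(tt)) >= 0))
  }
})

test_that("downstream extraction recovers prescribed phasic strains", {
  # 20-frame noise-free mesh path: 0.5% absolute
  p20 <- motion_params(28, 15.6 / 28.2, n_frames = 20,
                       transient_mode = "smooth")
  m20 <- analyze_sequence(generate_mesh_sequence(p20))$metrics
  g20 <- m20[m20$scope == "global", ]
  expect_lt(abs(g20$reservoir_strain - 28), 0.5)
  expect_lt(abs(g20$conduit_strain - 12.51), 0.5)
  expect_lt(abs(g20$contractile_strain - 15.49), 0.5)
  # 10-frame: 1.5% absolute
  p10 <- motion_params(28, 15.6 / 28.2, n_frames = 10,
                       transient_mode = "smooth")
  m10 <- analyze_sequence(generate_mesh_sequence(p10))$metrics
  g10 <- m10[m10$scope == "global", ]
  expect_lt(abs(g10$reservoir_strain - 28), 1.5)
  expect_lt(abs(g10$conduit_strain - 12.51), 1.5)
  expect_lt(abs(g10$contractile_strain - 15.49), 1.5)
})

test_that("regional modifiers scale regional strain curves", {
  mods <- stats::setNames(rep(1, 5), LA_REGIONS)
  mods["anterior"] <- 1.5
  p <- motion_params(20, 0.5, regional_modifiers = mods, n_frames = 10)
  sq <- generate_mesh_sequence(p)
  cv <- aggregate_curves(area_strain(sq), sq$region_labels, sq$frame_times)
  k <- which(sq$frame_times == 0.4)
  ant <- cv$regional[k, "anterior"]
  others <- cv$regional[k, setdiff(LA_REGIONS, "anterior")]
  # interior anterior elements sit at 1.5x; boundary vertex averaging pulls
  # the regional mean slightly toward 1
  expect_gt(ant / mean(others), 1.3)
  expect_lt(abs(mean(others) - 20), 1.5)
})

test_that("generation is bitwise reproducible under a fixed seed", {
  p <- motion_params(21, 0.5, noise_sd = 0.1, seed = 7)
  s1 <- generate_mesh_sequence(p)
  s2 <- generate_mesh_sequence(p)
  expect_identical(s1$vertices_per_frame, s2$vertices_per_frame)

  spec <- small_cohort_spec(n = c(a = 2, b = 2), seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$table, c2$table)
})

test_that("motion parameter validation enforces the phase ordering", {
  expect_error(motion_params(t_peak = 0.7, t_cc = 0.4), "t_peak < t_cc")
  expect_error(motion_params(contractile_fraction = 1.2), "\\[0, 1\\]")
  expect_error(motion_params(regional_modifiers =
                               stats::setNames(c(-1, 1, 1, 1, 1), LA_REGIONS)),
               "positive")
  shape <- la_base_shape(subdivisions = 2)
  open_shape <- shape
  open_shape$faces <- shape$faces[-1, ]
  expect_error(generate_mesh_sequence(motion_params(), open_shape),
               "not closed")
})

test_that("cohort feature means track configured group means at large n", {
  spec <- cohort_spec(
    n_per_group = c(a = 250, b = 250),
    group_effects = list(a = c(), b = c(contractile = -6.6)),
    seed = 99)
  tab <- generate_cohort(spec)$table
  bl <- spec$baseline
  ma <- mean(tab$true_contractile[tab$group == "a"])
  mb <- mean(tab$true_contractile[tab$group == "b"])
  se <- bl$contractile_sd / sqrt(250)
  expect_lt(abs(ma - bl$contractile), 4 * se)
  expect_lt(abs(mb - (bl$contractile - 6.6)), 4 * se + 0.2)
  # measured features follow the prescribed truth
  expect_lt(mean(abs(tab$global.contractile_strain - tab$true_contractile)),
            0.5)
})

test_that("degenerate cohort effect configurations are rejected", {
  expect_error(cohort_spec(group_effects = list(
    recurrence = c(reservoir = -30), no_recurrence = c())),
    "degenerate effect")
  expect_error(cohort_spec(n_per_group = c(a = 1, b = 5)), "n_per_group")
})

test_that("CHA2DS2-VASc follows the standard rubric", {
  expect_equal(chads_vasc(62, female = TRUE, hypertension = TRUE), 2L)
  expect_equal(chads_vasc(80, female = FALSE), 2L)
  expect_equal(chads_vasc(80, female = TRUE, chf = TRUE, hypertension = TRUE,
                          diabetes = TRUE, stroke = TRUE, vascular = TRUE),
               9L)
  expect_error(chads_vasc(-1, FALSE), "negative age")
})
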