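# shared fixtures, all built in code at test time

unit_sphere <- function(subdiv = 3) icosphere(subdiv)

# two-frame sequence: sphere of radius r scaled by s at the second frame
scaled_sphere_seq <- function(r = 20, s = 1.1, subdiv = 3) {
  ico <- icosphere(subdiv)
  mesh_frame_sequence(list(ico$vertices * r, ico$vertices * r * s),
                      ico$faces, c(0, 0.5),
                      rep("septum", nrow(ico$faces)))
}

# piecewise-linear global strain fixture: rise 0->25 on [0,0.4], fall to 12
# on [0.4,0.7], flat to 0.8, fall to 0 on [0.8,1]
pwl_curve <- function(t) {
  s <- numeric(length(t))
  i <- t <= 0.4;             s[i] <- 25 * t[i] / 0.4
  i <- t > 0.4 & t <= 0.7;   s[i] <- 25 - 13 * (t[i] - 0.4) / 0.3
  i <- t > 0.7 & t <= 0.8;   s[i] <- 12
  i <- t > 0.8;              s[i] <- 12 * (1 - t[i]) / 0.2
  s
}

small_cohort_spec <- function(n = c(a = 6, b = 6), seed = 11,
                              effects = list(a = c(), b = c()), ...) {
  cohort_spec(n_per_group = n, group_effects = effects, seed = seed, ...)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
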