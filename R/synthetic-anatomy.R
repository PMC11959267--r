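#' Prescribed phasic motion model parameters
#'
#' Parameter set driving the synthetic 4D atrial motion: the global area
#' strain transient rises from 0 at end-diastole to `reservoir_amplitude` at
#' `t_peak` (reservoir filling), declines by the conduit share
#' `(1 - contractile_fraction) * reservoir_amplitude` to the
#' conduit-contractile boundary `t_cc`, holds a diastasis plateau until
#' `t_act`, and returns to 0 by the end of the cycle (active contraction).
#'
#' @param reservoir_amplitude Peak global area strain (%), > 0 (0 is allowed
#'   and yields identity motion).
#' @param contractile_fraction Share of total emptying due to active
#'   contraction, in `[0, 1]`.
#' @param t_peak Normalized time of peak reservoir strain, in `(0, t_cc)`.
#' @param t_cc Normalized time of the conduit-contractile boundary, in
#'   `(t_peak, 1)`.
#' @param t_act Normalized time at which active contraction begins (end of
#'   the diastasis plateau); default midway-ish between `t_cc` and 1.
#' @param regional_modifiers Named multiplicative amplitude factors, one per
#'   wall region in [LA_REGIONS]; all > 0.
#' @param noise_sd Isotropic per-vertex Gaussian displacement noise (mm),
#'   applied after motion.
#' @param n_frames Number of frames over the R-R interval (10 or 20).
#' @param transient_mode `"cubic"` for C1 smoothstep segments with an exact
#'   plateau onset at `t_cc`, or `"smooth"` for C2 quintic segments whose
#'   slope eases gradually into the plateau (harder for the phase detector).
#' @param seed Integer seed used whenever `noise_sd > 0`.
#' @return A `motion_params` list.
#' @export
motion_params <- function(reservoir_amplitude = 21,
                          contractile_fraction = 0.5,
                          t_peak = 0.4, t_cc = 0.7,
                          t_act = t_cc + 0.6 * (0.95 - t_cc),
                          regional_modifiers = stats::setNames(rep(1, 5), LA_REGIONS),
                          noise_sd = 0, n_frames = 10,
                          transient_mode = c("cubic", "smooth"),
                          seed = 1L) {
  transient_mode <- match.arg(transient_mode)
  if (reservoir_amplitude < 0) stop("reservoir_amplitude must be >= 0")
  if (contractile_fraction < 0 || contractile_fraction > 1)
    stop("contractile_fraction must lie in [0, 1]")
  if (!(0 < t_peak && t_peak < t_cc && t_cc < 1))
    stop("require 0 < t_peak < t_cc < 1")
  if (!(t_cc <= t_act && t_act < 1)) stop("require t_cc <= t_act < 1")
  if (!all(n_frames %in% c(10L, 20L))) stop("n_frames must be 10 or 20")
  rm_ <- regional_modifiers
  if (is.null(names(rm_))) names(rm_) <- LA_REGIONS
  if (!setequal(names(rm_), LA_REGIONS) || any(rm_ <= 0))
    stop("regional_modifiers must be positive and named by the five regions")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(reservoir_amplitude = reservoir_amplitude,
                 contractile_fraction = contractile_fraction,
                 t_peak = t_peak, t_cc = t_cc, t_act = t_act,
                 regional_modifiers = rm_[LA_REGIONS], noise_sd = noise_sd,
                 n_frames = as.integer(n_frames),
                 transient_mode = transient_mode, seed = as.integer(seed)),
            class = "motion_params")
}

# smoothstep easing: cubic (C1, zero end slopes) or quintic (C2, zero end
# slopes and curvatures)
ease <- function(tau, mode) {
  tau <- pmin(1, pmax(0, tau))
  if (mode == "cubic") tau^2 * (3 - 2 * tau) else tau^3 * (6 * tau^2 - 15 * tau + 10)
}

#' Continuous global strain transient prescribed by a motion model
#'
#' Returns the piecewise-smooth function `S(t)` (% area strain vs normalized
#' R-R time) defined by `params`: monotone rise to the reservoir peak, conduit
#' decline to the plateau at `t_cc`, diastasis, and contractile return to 0 at
#' `t = 1`. By construction `S(t_peak) = S(t_peak) - S(t_cc) + S(t_cc)`, i.e.
#' reservoir = conduit + contractile exactly.
#'
#' @param params A [motion_params()] object.
#' @return Vectorized function of normalized time (values in %).
#' @export
strain_transient <- function(params) {
  A <- params$reservoir_amplitude
  cf <- params$contractile_fraction
  tp <- params$t_peak; tcc <- params$t_cc; tact <- params$t_act
  plateau <- cf * A
  mode <- params$transient_mode
  function(t) {
    t <- t %% 1
    s <- numeric(length(t))
    i <- t <= tp
    s[i] <- A * ease(t[i] / tp, mode)
    i <- t > tp & t <= tcc
    s[i] <- A - (A - plateau) * ease((t[i] - tp) / (tcc - tp), mode)
    i <- t > tcc & t <= tact
    s[i] <- plateau
    i <- t > tact
    s[i] <- plateau * (1 - ease((t[i] - tact) / (1 - tact), mode))
    s
  }
}

#' Synthetic LA-like base anatomy
#'
#' A superellipsoid-deformed icosphere standing in for the LA body, with the
#' five contiguous wall patches labelled in the fixed spherical chart of
#' [assign_regions()].
#'
#' @param subdivisions Icosphere refinement level (3 gives 1280 faces).
#' @param radius Mean radius (mm); the default gives an end-diastolic volume
#'   in the tens-of-mL range typical for the LA.
#' @param axes Length-3 semi-axis scale factors applied to x/y/z.
#' @param superellipse_exponent Radial shaping exponent `p`; `p = 2` is the
#'   ellipsoid, larger values flatten the body toward a box-like atrium.
#' @return List with `vertices`, `faces`, `region_labels`, `center`.
#' @export
la_base_shape <- function(subdivisions = 3, radius = 25,
                          axes = c(1.15, 1.0, 0.9),
                          superellipse_exponent = 2.5) {
  ico <- icosphere(subdivisions)
  d <- ico$vertices
  p <- superellipse_exponent
  # superellipsoid radius along each unit direction
  rr <- (abs(d[, 1] / axes[1])^p + abs(d[, 2] / axes[2])^p +
         abs(d[, 3] / axes[3])^p)^(-1 / p)
  v <- d * rr * radius
  labels <- assign_regions(v, ico$faces, "spherical")
  list(vertices = v, faces = ico$faces, region_labels = labels,
       center = c(0, 0, 0))
}

#' Generate a deforming 4D mesh sequence
#'
#' Applies the prescribed phasic transient to a closed LA-like base shape by
#' radial scaling about the shape centre. Per-vertex scale factors are
#' `sqrt(1 + m_v * S(t)/100)` with `m_v` the (face-region averaged) regional
#' amplitude modifier, so that with all modifiers equal to 1 every element's
#' area strain equals the prescribed transient exactly (uniform scaling law
#' `strain = (s^2 - 1) * 100`). Optional Gaussian vertex jitter emulates
#' tracking noise.
#'
#' @param params A [motion_params()] object.
#' @param base_shape A closed labelled surface from [la_base_shape()] (or any
#'   list with `vertices`, `faces`, `region_labels`, `center`).
#' @return A [mesh_frame_sequence()] with `n_frames` frames at uniform R-R
#'   increments; frame 1 is the undeformed reference. The analytic
#'   frame-k vertex mapping is attached as attribute `"motion_maps"` (a list
#'   of functions of an `N x 3` matrix) for ground-truth tracking.
#' @export
generate_mesh_sequence <- function(params, base_shape = la_base_shape()) {
  stopifnot(inherits(params, "motion_params"))
  check_closed(base_shape$vertices, base_shape$faces)
  v0 <- base_shape$vertices
  faces <- as_face_matrix(base_shape$faces)
  ctr <- base_shape$center
  labels <- base_shape$region_labels
  S <- strain_transient(params)
  times <- seq(0, by = 1 / params$n_frames, length.out = params$n_frames)

  # vertex modifier = mean of incident-face region modifiers (smooth across
  # patch boundaries); excluded faces count as modifier 1
  fm <- ifelse(labels %in% LA_REGIONS,
               params$regional_modifiers[labels], 1)
  mv <- numeric(nrow(v0)); cnt <- numeric(nrow(v0))
  for (j in 1:3) {
    idx <- faces[, j]
    mv <- mv + unname(tapply(fm, factor(idx, levels = seq_len(nrow(v0))),
                             sum, default = 0))
    cnt <- cnt + tabulate(idx, nbins = nrow(v0))
  }
  mv[is.na(mv)] <- 0
  mv <- ifelse(cnt > 0, mv / cnt, 1)

  rel0 <- sweep(v0, 2, ctr)
  map_at <- function(t) {
    s <- sqrt(1 + mv * S(t) / 100)
    function(x) sweep(sweep(x, 2, ctr) * s, 2, ctr, "+")
  }
  maps <- lapply(times, map_at)
  frames <- lapply(seq_along(times), function(k) {
    s <- sqrt(1 + mv * S(times[k]) / 100)
    sweep(rel0 * s, 2, ctr, "+")
  })
  if (params$noise_sd > 0) {
    frames <- withr::with_seed(params$seed, {
      lapply(seq_along(frames), function(k) {
        if (k == 1) return(frames[[k]])  # reference anatomy is noise-free
        frames[[k]] + matrix(stats::rnorm(length(frames[[k]]),
                                          sd = params$noise_sd),
                             ncol = 3)
      })
    })
  }
  out <- mesh_frame_sequence(frames, faces, times, labels)
  attr(out, "motion_maps") <- maps
  attr(out, "params") <- params
  out
}

#' Voxelize a mesh sequence into CT-like image frames
#'
#' Rasterizes each closed surface frame onto a common voxel grid by casting
#' rays along z voxel columns and filling between parity crossings
#' (blood-pool bright, background dark). Optional separable Gaussian
#' smoothing and additive noise emulate reconstruction blur and image noise.
#'
#' @param seq A [mesh_frame_sequence()].
#' @param voxel_size Voxel edge length(s) in mm; scalar or length-3.
#' @param inside,outside Intensities for blood pool and background.
#' @param pad Padding (mm) added around the joint bounding box of all frames.
#' @param smooth_sd Gaussian smoothing sigma in voxels (0 = off).
#' @param noise_sd Additive Gaussian intensity noise (0 = off), seeded.
#' @param seed Seed for the intensity noise.
#' @return A `volume_stack`: list with `frames` (list of 3D arrays), `origin`
#'   (mm, centre of voxel `[1,1,1]`), `spacing` (mm) and `frame_times`.
#' @export
voxelize_sequence <- function(seq, voxel_size = 2, inside = 100, outside = 0,
                              pad = 6, smooth_sd = 0, noise_sd = 0, seed = 1L) {
  spacing <- rep(voxel_size, length.out = 3)
  allv <- do.call(rbind, seq$vertices_per_frame)
  lo <- apply(allv, 2, min) - pad
  hi <- apply(allv, 2, max) + pad
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  if (any(dims > 256)) stop("mesh exceeds requested field of view budget")
  origin <- lo
  frames <- lapply(seq$vertices_per_frame, function(v)
    rasterize_closed_mesh(v, seq$faces, origin, spacing, dims,
                          inside = inside, outside = outside))
  if (smooth_sd > 0) frames <- lapply(frames, gaussian_blur3d, sd = smooth_sd)
  if (noise_sd > 0) {
    frames <- withr::with_seed(seed, lapply(frames, function(a)
      a + array(stats::rnorm(length(a), sd = noise_sd), dim = dim(a))))
  }
  structure(list(frames = frames, origin = origin, spacing = spacing,
                 frame_times = seq$frame_times),
            class = "volume_stack")
}

# z-column parity rasterization of one closed mesh; columns are offset by a
# small irrational fraction of a voxel so rays do not pass through vertices
# or edges of generic meshes
rasterize_closed_mesh <- function(vertices, faces, origin, spacing, dims,
                                  inside = 100, outside = 0) {
  eps <- c(0.12345, 0.23456) * 1e-2 * spacing[1:2]
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1] + eps[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2] + eps[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  crossings <- vector("list", dims[1] * dims[2])
  tri <- lapply(1:3, function(j) vertices[faces[, j], , drop = FALSE])
  for (t in seq_len(nrow(faces))) {
    p1 <- tri[[1]][t, ]; p2 <- tri[[2]][t, ]; p3 <- tri[[3]][t, ]
    ix <- which(xs >= min(p1[1], p2[1], p3[1]) & xs <= max(p1[1], p2[1], p3[1]))
    iy <- which(ys >= min(p1[2], p2[2], p3[2]) & ys <= max(p1[2], p2[2], p3[2]))
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    # 2D barycentric in the xy projection
    d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
    if (abs(d) < 1e-12) next  # vertical triangle: measure-zero footprint
    l1 <- ((p2[2] - p3[2]) * (px - p3[1]) + (p3[1] - p2[1]) * (py - p3[2])) / d
    l2 <- ((p3[2] - p1[2]) * (px - p3[1]) + (p1[1] - p3[1]) * (py - p3[2])) / d
    l3 <- 1 - l1 - l2
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) next
    zhit <- l1[hit] * p1[3] + l2[hit] * p2[3] + l3[hit] * p3[3]
    cols <- (rep(ix, times = length(iy)) +
             (rep(iy, each = length(ix)) - 1L) * dims[1])[hit]
    for (q in seq_along(cols))
      crossings[[cols[q]]] <- c(crossings[[cols[q]]], zhit[q])
  }
  vol <- array(outside, dim = dims)
  nz <- which(lengths(crossings) > 0)
  for (col in nz) {
    z <- sort(crossings[[col]])
    if (length(z) %% 2 != 0) next  # grazing ray; skip rather than mis-fill
    i <- ((col - 1L) %% dims[1]) + 1L
    j <- ((col - 1L) %/% dims[1]) + 1L
    for (p in seq(1, length(z), by = 2)) {
      kk <- which(zs > z[p] & zs < z[p + 1])
      if (length(kk)) vol[i, j, kk] <- inside
    }
  }
  vol
}

# separable 3D Gaussian blur (reflective borders)
gaussian_blur3d <- function(a, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd); k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(x[r:1], x, x[n:(n - r + 1)])
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  for (ax in 1:3) a <- apply(a, setdiff(1:3, ax), conv1) |>
      array(dim = dim(a)[c(ax, setdiff(1:3, ax))]) |>
      aperm(order(c(ax, setdiff(1:3, ax))))
  a
}
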