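#' Registration settings for the baseline B-spline tracker
#'
#' @param grid_spacing Control-point spacing (mm) of the cubic B-spline
#'   free-form deformation.
#' @param lambda Bending-energy regularization weight.
#' @param levels Multi-resolution image levels (coarse-to-fine; images are
#'   downsampled by powers of 2).
#' @param maxit L-BFGS-B iterations per level.
#' @param background Intensity assumed outside the moving image support.
#' @return A `reg_settings` list.
#' @export
reg_settings <- function(grid_spacing = 12, lambda = 1e-4, levels = 2,
                         maxit = 100, background = 0) {
  structure(list(grid_spacing = grid_spacing, lambda = lambda,
                 levels = as.integer(levels), maxit = as.integer(maxit),
                 background = background),
            class = "reg_settings")
}

# cubic uniform B-spline weights for fractional offset u in [0,1):
# support covers lattice nodes i-1 .. i+2
bspline_w <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# control lattice covering a world-space box with full cubic support
make_grid <- function(lo, hi, spacing) {
  origin <- lo - 2 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 5L
  list(origin = origin, spacing = spacing, dims = dims)
}

# sparse N x prod(dims) cubic B-spline basis for arbitrary points (mm)
basis_matrix <- function(points, grid) {
  n <- nrow(points)
  iw <- vector("list", 3)
  for (d in 1:3) {
    u_abs <- (points[, d] - grid$origin[d]) / grid$spacing
    i0 <- floor(u_abs)
    if (any(i0 < 1) || any(i0 + 2 > grid$dims[d] - 1))
      stop("point leaves the deformation domain")
    iw[[d]] <- list(i = as.integer(i0), w = bspline_w(u_abs - i0))
  }
  nx <- grid$dims[1]; ny <- grid$dims[2]
  ii <- jj <- xx <- vector("list", 64)
  q <- 0L
  for (c3 in 0:3) for (c2 in 0:3) for (c1 in 0:3) {
    q <- q + 1L
    # 0-based lattice nodes (i-1)+c per dim -> 1-based column index
    cx <- iw[[1]]$i - 1L + c1
    cy <- iw[[2]]$i - 1L + c2
    cz <- iw[[3]]$i - 1L + c3
    jj[[q]] <- cz * nx * ny + cy * nx + cx + 1L
    ii[[q]] <- seq_len(n)
    xx[[q]] <- iw[[1]]$w[, c1 + 1] * iw[[2]]$w[, c2 + 1] * iw[[3]]$w[, c3 + 1]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, prod(grid$dims)))
}

# second-difference bending penalty matrix over the control lattice
bending_matrix <- function(dims) {
  n <- prod(dims)
  idx <- array(seq_len(n), dim = dims)
  K <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  for (ax in 1:3) {
    m <- dims[ax]
    if (m < 3) next
    take <- function(off) {
      sl <- rep(list(quote(expr = )), 3)
      sl[[ax]] <- seq_len(m - 2) + off
      do.call(`[`, c(list(idx), sl))
    }
    a <- as.vector(take(0)); b <- as.vector(take(1)); c_ <- as.vector(take(2))
    r <- seq_along(a)
    D <- Matrix::sparseMatrix(i = c(r, r, r), j = c(a, b, c_),
                              x = rep(c(1, -2, 1), each = length(r)),
                              dims = c(length(r), n))
    K <- K + Matrix::crossprod(D)
  }
  K
}

# trilinear sampling of a volume at world points; values outside -> fill
interp3 <- function(vol, origin, spacing, points, fill = 0) {
  d <- dim(vol)
  cx <- (points[, 1] - origin[1]) / spacing[1]
  cy <- (points[, 2] - origin[2]) / spacing[2]
  cz <- (points[, 3] - origin[3]) / spacing[3]
  inside <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 &
            cz >= 0 & cz <= d[3] - 1
  out <- rep(fill, nrow(points))
  if (!any(inside)) return(out)
  cx <- pmin(cx[inside], d[1] - 1 - 1e-9)
  cy <- pmin(cy[inside], d[2] - 1 - 1e-9)
  cz <- pmin(cz[inside], d[3] - 1 - 1e-9)
  i0 <- floor(cx); j0 <- floor(cy); k0 <- floor(cz)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  at <- function(i, j, k) vol[i + 1L + j * d[1] + k * d[1] * d[2]]
  i0 <- as.integer(i0); j0 <- as.integer(j0); k0 <- as.integer(k0)
  v <- at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(i0 + 1L, j0, k0) * fx * (1 - fy) * (1 - fz) +
       at(i0, j0 + 1L, k0) * (1 - fx) * fy * (1 - fz) +
       at(i0 + 1L, j0 + 1L, k0) * fx * fy * (1 - fz) +
       at(i0, j0, k0 + 1L) * (1 - fx) * (1 - fy) * fz +
       at(i0 + 1L, j0, k0 + 1L) * fx * (1 - fy) * fz +
       at(i0, j0 + 1L, k0 + 1L) * (1 - fx) * fy * fz +
       at(i0 + 1L, j0 + 1L, k0 + 1L) * fx * fy * fz
  out[inside] <- v
  out
}

# central-difference spatial gradient volumes (per mm)
gradient_volumes <- function(vol, spacing) {
  d <- dim(vol)
  g <- list()
  for (ax in 1:3) {
    gp <- array(0, d)
    n <- d[ax]
    hi <- function(off) {
      sl <- rep(list(quote(expr = )), 3); sl[[ax]] <- pmin(seq_len(n) + off, n)
      do.call(`[`, c(list(vol), sl, drop = FALSE))
    }
    lo <- function(off) {
      sl <- rep(list(quote(expr = )), 3); sl[[ax]] <- pmax(seq_len(n) - off, 1)
      do.call(`[`, c(list(vol), sl, drop = FALSE))
    }
    g[[ax]] <- (hi(1) - lo(1)) / (2 * spacing[ax])
  }
  g
}

# stride-2 downsampling of a volume frame
downsample2 <- function(frame) {
  d <- dim(frame$data)
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2); iz <- seq(1, d[3], by = 2)
  list(data = frame$data[ix, iy, iz, drop = FALSE], origin = frame$origin,
       spacing = frame$spacing * 2)
}

#' Extract one frame of a volume stack
#'
#' @param stack A `volume_stack` from [voxelize_sequence()] or
#'   [read_volume_frames()].
#' @param k Frame index.
#' @return List with `data`, `origin`, `spacing`.
#' @export
volume_frame <- function(stack, k) {
  list(data = stack$frames[[k]], origin = stack$origin,
       spacing = stack$spacing)
}

#' Pairwise deformable registration (cubic B-spline FFD)
#'
#' Estimates the deformation mapping fixed-frame coordinates to moving-frame
#' coordinates with a multi-resolution cubic B-spline free-form deformation,
#' maximizing normalized cross-correlation between the fixed image and the
#' warped moving image under a bending-energy penalty. Fully deterministic:
#' fixed voxel sampling, analytic gradient, L-BFGS-B optimizer.
#'
#' @param fixed,moving Volume frames (lists with `data`, `origin`,
#'   `spacing`), e.g. from [volume_frame()]. Must share world metadata.
#' @param settings A [reg_settings()] object.
#' @return A `deformation_field`: list with the control-point displacement
#'   matrix `theta` (mm), the control `grid`, and the initial/final
#'   similarity. If the optimizer fails to improve on the identity the field
#'   carries `improved = FALSE` and a warning is raised.
#' @export
register_pair <- function(fixed, moving, settings = reg_settings()) {
  if (!isTRUE(all.equal(fixed$origin, moving$origin)) ||
      !isTRUE(all.equal(fixed$spacing, moving$spacing)))
    stop("volumes must share world metadata")
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("constant image: intensity ranges do not overlap usefully")
  lo <- fixed$origin
  hi <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing
  grid <- make_grid(lo, hi, settings$grid_spacing)
  nc <- prod(grid$dims)
  K <- bending_matrix(grid$dims)
  theta <- matrix(0, nc, 3)
  ncc0_full <- NA_real_
  ncc_final <- NA_real_
  for (lev in seq(settings$levels, 1)) {
    fx <- fixed; mv <- moving
    for (s in seq_len(lev - 1)) { fx <- downsample2(fx); mv <- downsample2(mv) }
    d <- dim(fx$data)
    pts <- cbind(
      rep(fx$origin[1] + (seq_len(d[1]) - 1) * fx$spacing[1], times = d[2] * d[3]),
      rep(rep(fx$origin[2] + (seq_len(d[2]) - 1) * fx$spacing[2], each = d[1]),
          times = d[3]),
      rep(fx$origin[3] + (seq_len(d[3]) - 1) * fx$spacing[3], each = d[1] * d[2]))
    B <- basis_matrix(pts, grid)
    fvals <- as.vector(fx$data)
    fc <- fvals - mean(fvals)
    sf <- sqrt(sum(fc^2))
    gvols <- gradient_volumes(mv$data, mv$spacing)
    bg <- settings$background
    lam <- settings$lambda
    objective <- function(par) {
      th <- matrix(par, nc, 3)
      disp <- as.matrix(B %*% th)
      w <- pts + disp
      m <- interp3(mv$data, mv$origin, mv$spacing, w, fill = bg)
      mc <- m - mean(m)
      sm <- sqrt(sum(mc^2))
      if (sm == 0) return(list(value = 0, grad = rep(0, length(par))))
      ncc <- sum(fc * mc) / (sf * sm)
      dm <- (fc / (sf * sm) - ncc * mc / sm^2)
      gx <- interp3(gvols[[1]], mv$origin, mv$spacing, w)
      gy <- interp3(gvols[[2]], mv$origin, mv$spacing, w)
      gz <- interp3(gvols[[3]], mv$origin, mv$spacing, w)
      gncc <- cbind(as.vector(Matrix::crossprod(B, dm * gx)),
                    as.vector(Matrix::crossprod(B, dm * gy)),
                    as.vector(Matrix::crossprod(B, dm * gz)))
      pen <- lam * sum(vapply(1:3, function(dd)
        as.numeric(Matrix::crossprod(th[, dd], K %*% th[, dd])), numeric(1)))
      gpen <- 2 * lam * as.matrix(K %*% th)
      list(value = -ncc + pen, grad = as.vector(-gncc + gpen), ncc = ncc)
    }
    cache <- new.env()
    fn <- function(par) {
      o <- objective(par); cache$o <- o; o$value
    }
    gr <- function(par) cache$o$grad
    if (lev == 1) ncc0_full <- objective(rep(0, 3 * nc))$ncc
    opt <- stats::optim(as.vector(theta), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = settings$maxit))
    theta <- matrix(opt$par, nc, 3)
    if (lev == 1) ncc_final <- objective(opt$par)$ncc
  }
  improved <- isTRUE(ncc_final >= ncc0_full - 1e-8)
  if (!improved)
    warning("registration failed to improve similarity beyond initialization")
  structure(list(theta = theta, grid = grid,
                 similarity = c(initial = ncc0_full, final = ncc_final),
                 improved = improved, settings = settings),
            class = "deformation_field")
}

#' Apply a deformation field to points
#'
#' @param field A `deformation_field` from [register_pair()].
#' @param points Numeric `N x 3` matrix of world coordinates (mm) inside the
#'   field's domain.
#' @return Deformed `N x 3` matrix (fixed-frame coordinates mapped to
#'   moving-frame coordinates).
#' @export
apply_deformation <- function(field, points) {
  stopifnot(inherits(field, "deformation_field"))
  points + as.matrix(basis_matrix(points, field$grid) %*% field$theta)
}

#' Propagate an end-diastolic mesh through a cardiac cycle
#'
#' Transports the frame-1 mesh vertices through composed consecutive-pair
#' deformation fields (frame k-1 to frame k) to every later frame;
#' connectivity and region labels are preserved and frame 1 is returned
#' unchanged.
#'
#' @param ed_mesh List with `vertices`, `faces` and optionally
#'   `region_labels` (the end-diastolic anatomy).
#' @param fields List of length `n_frames - 1`; each element either a
#'   `deformation_field` or a function mapping an `N x 3` matrix of frame
#'   k-1 coordinates to frame k coordinates.
#' @param frame_times Normalized R-R times of the resulting frames.
#' @return A [mesh_frame_sequence()].
#' @export
propagate_mesh <- function(ed_mesh, fields, frame_times) {
  v <- ed_mesh$vertices
  frames <- vector("list", length(fields) + 1)
  frames[[1]] <- v
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    v <- if (is.function(f)) f(v) else apply_deformation(f, v)
    frames[[k + 1]] <- v
  }
  mesh_frame_sequence(frames, ed_mesh$faces, frame_times,
                      ed_mesh$region_labels)
}

#' Track a mesh through an image-frame sequence
#'
#' Baseline feature tracking: registers consecutive volume frames and
#' propagates the end-diastolic mesh through the composed fields. The
#' tracker is pluggable: `method = "ground_truth"` bypasses registration and
#' returns the generator's analytic motion (for isolating downstream
#' stages), and externally tracked mesh sequences can skip this stage
#' entirely.
#'
#' @param volumes A `volume_stack` of image frames.
#' @param ed_mesh End-diastolic mesh (list with `vertices`, `faces`,
#'   optionally `region_labels`).
#' @param settings A [reg_settings()] object.
#' @param method `"bspline"` (default) or `"ground_truth"`.
#' @param truth_seq The generator sequence carrying `"motion_maps"`, required
#'   for `method = "ground_truth"`.
#' @return A [mesh_frame_sequence()]; for `"bspline"` the per-pair fields are
#'   attached as attribute `"fields"`.
#' @export
track_sequence <- function(volumes, ed_mesh, settings = reg_settings(),
                           method = c("bspline", "ground_truth"),
                           truth_seq = NULL) {
  method <- match.arg(method)
  nt <- length(volumes$frames)
  if (method == "ground_truth") {
    maps <- attr(truth_seq, "motion_maps")
    if (is.null(maps)) stop("truth_seq must carry generator motion maps")
    frames <- lapply(maps, function(m) m(ed_mesh$vertices))
    return(mesh_frame_sequence(frames, ed_mesh$faces, volumes$frame_times,
                               ed_mesh$region_labels))
  }
  fields <- vector("list", nt - 1)
  for (k in seq_len(nt - 1)) {
    fields[[k]] <- register_pair(volume_frame(volumes, k),
                                 volume_frame(volumes, k + 1), settings)
  }
  out <- propagate_mesh(ed_mesh, fields, volumes$frame_times)
  attr(out, "fields") <- fields
  out
}
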