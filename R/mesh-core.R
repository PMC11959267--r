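#' @keywords internal
"_PACKAGE"

#' Anatomical wall regions of the left atrial body
#'
#' Canonical region labels used throughout the package for the five-wall
#' decomposition of the LA body (pulmonary veins and appendage analogues are
#' carried as `"excluded"`).
#'
#' @format Character vector of length 5.
#' @export
LA_REGIONS <- c("septum", "lateral", "posterior", "anterior", "inferior")

#' Construct a 4D mesh frame sequence
#'
#' Bundles one closed triangulated endocardial surface per cardiac frame with
#' fixed vertex correspondence across frames, normalized R-R frame times and a
#' per-face region labelling. Frame 1 is the end-diastolic reference anatomy.
#'
#' @param vertices_per_frame List of numeric `V x 3` matrices (mm), one per
#'   frame; all frames must have the same vertex count.
#' @param faces Integer `F x 3` matrix of 1-based triangle indices shared by
#'   all frames.
#' @param frame_times Numeric vector of normalized R-R times in `[0, 1)`,
#'   strictly increasing with `frame_times[1] == 0`.
#' @param region_labels Character or factor of length `F`; values in
#'   [LA_REGIONS] or `"excluded"`. Defaults to all `"excluded"`.
#' @return An object of class `mesh_sequence`.
#' @export
mesh_frame_sequence <- function(vertices_per_frame, faces, frame_times,
                                region_labels = NULL) {
  stopifnot(is.list(vertices_per_frame), length(vertices_per_frame) >= 1)
  faces <- as_face_matrix(faces)
  nv <- nrow(vertices_per_frame[[1]])
  for (k in seq_along(vertices_per_frame)) {
    v <- vertices_per_frame[[k]]
    if (!is.matrix(v) || ncol(v) != 3)
      stop("frame ", k, ": vertices must be a V x 3 matrix")
    if (nrow(v) != nv)
      stop("frame ", k, ": vertex count differs from frame 1 (",
           nrow(v), " vs ", nv, ")")
    if (!all(is.finite(v))) stop("frame ", k, ": non-finite vertex coordinate")
  }
  if (max(faces) > nv || min(faces) < 1)
    stop("faces reference vertices outside 1..", nv)
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != length(vertices_per_frame))
    stop("frame_times length must equal the number of frames")
  if (frame_times[1] != 0) stop("frame_times[1] must be 0 (end-diastole)")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (any(frame_times >= 1)) stop("frame_times must lie in [0, 1)")
  if (is.null(region_labels)) region_labels <- rep("excluded", nrow(faces))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(faces))
    stop("region_labels length must equal the face count")
  bad <- setdiff(unique(region_labels), c(LA_REGIONS, "excluded"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  structure(
    list(vertices_per_frame = vertices_per_frame, faces = faces,
         frame_times = frame_times, region_labels = region_labels),
    class = "mesh_sequence")
}

as_face_matrix <- function(faces) {
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stop("faces must be an F x 3 triangle matrix")
  faces
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat("mesh_sequence:", length(x$vertices_per_frame), "frames,",
      nrow(x$vertices_per_frame[[1]]), "vertices,",
      nrow(x$faces), "faces\n")
  cat("  frame times:", paste(format(x$frame_times), collapse = " "), "\n")
  cat("  regions:", paste(names(table(x$region_labels)), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(seq) length(seq$vertices_per_frame)

#' Per-face triangle areas
#'
#' Area of every triangular surface element of one mesh frame, computed as
#' half the cross-product magnitude of two edge vectors.
#'
#' @param vertices Numeric `V x 3` matrix (mm).
#' @param faces Integer `F x 3` triangle matrix.
#' @return Numeric vector of face areas (mm^2). Degenerate faces (area below
#'   `1e-12`) are reported via a `"degenerate"` attribute holding their
#'   indices.
#' @export
element_areas <- function(vertices, faces) {
  faces <- as_face_matrix(faces)
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  degen <- which(area < 1e-12)
  if (length(degen)) attr(area, "degenerate") <- degen
  area
}

#' Enclosed volume of a closed surface
#'
#' Signed divergence-theorem volume of a closed, consistently oriented
#' triangulated surface, returned positive regardless of orientation.
#'
#' @inheritParams element_areas
#' @return Scalar volume in the cube of the coordinate unit (mm^3 for mm
#'   meshes).
#' @export
enclosed_volume <- function(vertices, faces) {
  faces <- as_face_matrix(faces)
  check_closed(vertices, faces)
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  # signed volume of tetrahedra against the origin: det([a b c]) / 6
  v <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
       a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
       a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(v)) / 6
}

# every edge of a closed orientable triangulation is shared by exactly 2 faces
check_closed <- function(vertices, faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2))
    stop("surface is not closed: ", sum(cnt != 2),
         " edge(s) not shared by exactly two faces")
  invisible(TRUE)
}

#' Chamber volume curve from a mesh sequence
#'
#' @param seq A [mesh_frame_sequence()].
#' @param chamber Chamber name stored with the curve, `"LA"` or `"LV"`.
#' @return A `volume_curve` object: list with `chamber`, `volumes` (mL) and
#'   `frame_times`.
#' @export
volume_curve <- function(seq, chamber = "LA") {
  chamber <- match.arg(chamber, c("LA", "LV"))
  vols <- vapply(seq$vertices_per_frame, enclosed_volume, numeric(1),
                 faces = seq$faces) / 1000  # mm^3 -> mL
  structure(list(chamber = chamber, volumes = vols,
                 frame_times = seq$frame_times),
            class = "volume_curve")
}

#' Assign the five-wall region labels to mesh faces
#'
#' Labels every non-excluded face of the LA body with one of the five wall
#' regions. The default parametric chart works on star-shaped bodies: face
#' centroids are expressed in spherical coordinates about the mesh centroid,
#' the superior cap (`colat < pi/3`) is the anterior wall, the inferior cap
#' (`colat > 2*pi/3`) the inferior wall, and the equatorial band is split by
#' longitude into septal, lateral and posterior thirds. Faces straddling a
#' boundary are assigned by their centroid (centroid rule).
#'
#' @param vertices Numeric `V x 3` matrix.
#' @param faces Integer `F x 3` triangle matrix.
#' @param chart Either `"spherical"` (default chart described above) or an
#'   explicit character vector of per-face labels, which is validated and
#'   passed through unchanged.
#' @return Character vector of per-face labels.
#' @export
assign_regions <- function(vertices, faces, chart = "spherical") {
  faces <- as_face_matrix(faces)
  if (is.character(chart) && length(chart) > 1) {
    if (length(chart) != nrow(faces))
      stop("explicit label vector length (", length(chart),
           ") must equal face count (", nrow(faces), ")")
    bad <- setdiff(unique(chart), c(LA_REGIONS, "excluded"))
    if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
    return(chart)
  }
  if (!identical(chart, "spherical")) stop("unknown chart: ", chart)
  ctr <- colMeans(vertices)
  cen <- (vertices[faces[, 1], , drop = FALSE] +
          vertices[faces[, 2], , drop = FALSE] +
          vertices[faces[, 3], , drop = FALSE]) / 3
  d <- sweep(cen, 2, ctr)
  r <- sqrt(rowSums(d^2))
  colat <- acos(pmin(1, pmax(-1, d[, 3] / r)))
  lon <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  lab <- character(nrow(faces))
  lab[colat < pi / 3] <- "anterior"
  lab[colat > 2 * pi / 3] <- "inferior"
  band <- lab == ""
  lab[band & lon < 2 * pi / 3] <- "septum"
  lab[band & lon >= 2 * pi / 3 & lon < 4 * pi / 3] <- "lateral"
  lab[band & lon >= 4 * pi / 3] <- "posterior"
  lab
}

#' Icosphere triangulation of the unit sphere
#'
#' Recursively subdivided icosahedron with vertices projected onto the unit
#' sphere; the standard quasi-uniform sphere triangulation.
#'
#' @param subdivisions Number of 4-to-1 subdivision passes (0 gives the
#'   icosahedron; each pass quadruples the face count).
#' @return List with `vertices` (`V x 3`, unit norm) and `faces` (`F x 3`).
#' @export
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      edge_mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(c(i, a, c_), c(j, b, a),
                                       c(k, c_, b), c(a, b, c_))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, faces = as_face_matrix(f))
}
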