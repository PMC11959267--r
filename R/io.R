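read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fraw <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)
  if (any(fraw[, 1] != 3)) stop("non-triangular face in ", path)
  list(vertices = v, faces = as_face_matrix(fraw[, 2:4] + 1L))
}

write_off <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(vertices), nrow(faces)), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  endh <- which(trimws(ln) == "end_header")[1]
  if (is.na(endh)) stop("not an ASCII PLY file: ", path)
  head <- ln[1:endh]
  if (!any(grepl("^format ascii", head))) stop("only ASCII PLY supported: ", path)
  nv <- as.integer(sub(".*element vertex ", "",
                       grep("element vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face ", "",
                       grep("element face", head, value = TRUE)[1]))
  v <- matrix(scan(text = ln[endh + (1:nv)], quiet = TRUE), ncol = 3,
              byrow = TRUE)
  fraw <- matrix(scan(text = ln[endh + nv + (1:nf)], quiet = TRUE), ncol = 4,
                 byrow = TRUE)
  if (any(fraw[, 1] != 3)) stop("non-triangular face in ", path)
  list(vertices = v, faces = as_face_matrix(fraw[, 2:4] + 1L))
}

write_ply <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
}

#' Write a mesh frame sequence to disk
#'
#' One mesh file per frame (OFF or ASCII PLY) plus a face-indexed region
#' label table (`regions.csv`) and a JSON metadata sidecar recording each
#' frame's file and normalized R-R time, so temporal order never depends on
#' file names.
#'
#' @param seq A [mesh_frame_sequence()].
#' @param dir Output directory (created if missing).
#' @param format `"off"` or `"ply"`.
#' @return Invisibly, the metadata file path.
#' @export
write_mesh_sequence <- function(seq, dir, format = c("off", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writer <- if (format == "off") write_off else write_ply
  files <- sprintf("frame_%03d.%s", seq_along(seq$vertices_per_frame) - 1L,
                   format)
  for (k in seq_along(files))
    writer(seq$vertices_per_frame[[k]], seq$faces, file.path(dir, files[k]))
  utils::write.csv(data.frame(face_index = seq_len(nrow(seq$faces)),
                              region = seq$region_labels),
                   file.path(dir, "regions.csv"), row.names = FALSE)
  meta <- list(format = format,
               frames = lapply(seq_along(files), function(k)
                 list(file = files[k], time_rr_fraction = seq$frame_times[k])),
               region_labels = "regions.csv")
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "sequence.json"))
}

#' Read a mesh frame sequence from disk
#'
#' Reads the `sequence.json` metadata written by [write_mesh_sequence()] (or
#' hand-authored to the same schema), restores the frames in declared
#' temporal order regardless of file naming, and validates that connectivity
#' is identical across frames and that the region label table matches the
#' face count.
#'
#' @param dir Directory containing `sequence.json`.
#' @return A [mesh_frame_sequence()].
#' @export
read_mesh_sequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sequence.json"))
  times <- vapply(meta$frames, function(f) f$time_rr_fraction, numeric(1))
  ord <- order(times)
  frames <- vector("list", length(ord))
  faces <- NULL
  for (k in seq_along(ord)) {
    fr <- meta$frames[[ord[k]]]
    path <- file.path(dir, fr$file)
    m <- switch(meta$format, off = read_off(path), ply = read_ply(path),
                stop("unsupported mesh format: ", meta$format))
    if (is.null(faces)) faces <- m$faces
    else if (!identical(dim(faces), dim(m$faces)) || !all(faces == m$faces))
      stop("inconsistent connectivity in frame file ", fr$file)
    frames[[k]] <- m$vertices
  }
  lab <- utils::read.csv(file.path(dir, meta$region_labels))
  if (nrow(lab) != nrow(faces))
    stop("region label table length (", nrow(lab),
         ") does not match face count (", nrow(faces), ")")
  mesh_frame_sequence(frames, faces, times[ord], lab$region)
}

#' Write image frames as NIfTI volumes
#'
#' @param stack A `volume_stack`.
#' @param dir Output directory; writes `frame_<k>.nii.gz` plus a
#'   `frames.json` sidecar with per-frame R-R fractions.
#' @return Invisibly, the written file paths.
#' @export
write_volume_frames <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%03d.nii.gz", seq_along(stack$frames) - 1L)
  aff <- diag(c(stack$spacing, 1))
  aff[1:3, 4] <- stack$origin
  for (k in seq_along(files)) {
    img <- RNifti::asNifti(stack$frames[[k]])
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, file.path(dir, files[k]))
  }
  jsonlite::write_json(
    list(frames = lapply(seq_along(files), function(k)
      list(file = files[k], time_rr_fraction = stack$frame_times[k]))),
    file.path(dir, "frames.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, files))
}

#' Read NIfTI image frames into a volume stack
#'
#' Frames are ordered by their declared R-R fraction (from the `frames.json`
#' sidecar or the `frame_times` argument); mixed voxel spacings or
#' orientations across frames are rejected.
#'
#' @param paths Either a directory containing `frames.json`, or a character
#'   vector of NIfTI paths (then `frame_times` is required).
#' @param frame_times Normalized R-R fraction per file when `paths` is a
#'   vector of files.
#' @return A `volume_stack`.
#' @export
read_volume_frames <- function(paths, frame_times = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    meta <- jsonlite::read_json(file.path(paths, "frames.json"))
    frame_times <- vapply(meta$frames, function(f) f$time_rr_fraction,
                          numeric(1))
    paths <- file.path(paths, vapply(meta$frames, function(f) f$file, ""))
  }
  if (is.null(frame_times)) stop("frame_times required for explicit file lists")
  ord <- order(frame_times)
  paths <- paths[ord]; frame_times <- frame_times[ord]
  ref <- NULL
  frames <- vector("list", length(paths))
  origin <- spacing <- NULL
  for (k in seq_along(paths)) {
    img <- RNifti::readNifti(paths[k])
    aff <- RNifti::xform(img)
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
    org <- aff[1:3, 4]
    if (is.null(ref)) {
      ref <- list(dim = dim(img), sp = sp, org = org, rot = aff[1:3, 1:3] / rep(sp, each = 3))
      origin <- org; spacing <- sp
    } else {
      if (!identical(ref$dim, dim(img)) ||
          !isTRUE(all.equal(ref$sp, sp, tolerance = 1e-6)) ||
          !isTRUE(all.equal(ref$rot, aff[1:3, 1:3] / rep(sp, each = 3),
                            tolerance = 1e-6)) ||
          !isTRUE(all.equal(ref$org, org, tolerance = 1e-6)))
        stop("mixed spacings/orientations across frames: ", paths[k])
    }
    frames[[k]] <- array(as.numeric(img), dim = dim(img))
  }
  structure(list(frames = frames, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), frame_times = frame_times),
            class = "volume_stack")
}
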