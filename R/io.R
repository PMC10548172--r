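# On-disk formats. Volumes and masks travel as multi-page TIFF, vector
# and tensor fields as NRRD (raw little-endian), profiles as CSV, tract
# output as legacy-VTK polydata, tile manifests as JSON. Degrees and
# micrometres everywhere in user-facing files.

# ---- TIFF -------------------------------------------------------------

# Minimal uncompressed 32-bit IEEE-float multipage TIFF writer
# (little-endian). Written directly because the available TIFF bindings
# only emit normalized integer samples; the libtiff-based reader in the
# tiff package reads these pages back bit-exactly (at float32 precision).
write_stack_float_tiff <- function(a, path, voxel_size_um) {
  d <- dim(a)
  nx <- d[2]; ny <- d[1]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  strip_bytes <- nx * ny * 4L
  res_ppcm <- 1e4 / voxel_size_um              # pixels per centimetre
  res_num <- round(res_ppcm * 100); res_den <- 100L
  # per page: [strip data][rational block 16B][IFD]
  n_tags <- 13L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  page_bytes <- strip_bytes + 16L + ifd_bytes
  first_off <- 8L
  for (z in seq_len(nz)) {
    page_off <- first_off + (z - 1L) * page_bytes
    data_off <- page_off
    rat_off <- data_off + strip_bytes
    ifd_off <- rat_off + 16L
    next_ifd <- if (z < nz) page_off + page_bytes + strip_bytes + 16L else 0L
    if (z == 1L) w4(ifd_off)                   # header next-IFD pointer
    writeBin(as.vector(t(a[, , z])), con, size = 4, endian = "little")
    w4(c(res_num, res_den, res_num, res_den))  # X and Y resolution rationals
    tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    w2(n_tags)                                 # tags in ascending id order
    tag(256L, 4L, 1L, nx)                      # ImageWidth
    tag(257L, 4L, 1L, ny)                      # ImageLength
    tag(258L, 3L, 1L, 32L)                     # BitsPerSample
    tag(259L, 3L, 1L, 1L)                      # Compression: none
    tag(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off)                # StripOffsets
    tag(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                      # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    tag(282L, 5L, 1L, rat_off)                 # XResolution
    tag(283L, 5L, 1L, rat_off + 8L)            # YResolution
    tag(296L, 3L, 1L, 3L)                      # ResolutionUnit: cm
    tag(339L, 3L, 1L, 3L)                      # SampleFormat: IEEE float
    w4(next_ifd)
  }
  invisible(path)
}

#' Write a volume as a multi-page 32-bit float TIFF
#'
#' Pages are short-axis (y, x) slices in z order; voxel size is recorded
#' in the TIFF resolution tags (pixels per centimetre).
#'
#' @param vol a `volume3d` (or 3D array plus `voxel_size_um`).
#' @param path output file.
#' @param voxel_size_um used when `vol` is a bare array.
#' @return the path, invisibly.
#' @export
write_stack <- function(vol, path, voxel_size_um = NULL) {
  if (inherits(vol, "volume3d")) voxel_size_um <- voxel_size(vol)
  if (is.null(voxel_size_um)) voxel_size_um <- 2
  a <- if (is.matrix(vol)) array(unclass(vol), c(dim(vol), 1L)) else bare_array(vol)
  storage.mode(a) <- "double"
  write_stack_float_tiff(a, path, voxel_size_um)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a volume
#'
#' @param path TIFF file (8/16/32-bit integer or 32-bit float,
#'   single channel).
#' @param voxel_size_um fallback voxel size when the file carries no
#'   resolution tags (a warning is emitted).
#' @return a `volume3d`.
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  # as.is returns raw integer counts; float pages are already unscaled
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, integer(1)) > 2L))
    stop("multi-channel (e.g. RGB) TIFF: expected a single-channel grayscale stack")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("mixed page shapes in ", path)
  a <- array(0, c(dims[[1]], length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]]
  xres <- attr(pages[[1]], "x.resolution")
  unit <- attr(pages[[1]], "resolution.unit")
  vs <- NULL
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    per_um <- switch(as.character(unit %||% "cm"),
                     cm = xres / 1e4, inch = xres / 25400, `2` = xres / 25400,
                     `3` = xres / 1e4, xres / 1e4)
    vs <- 1 / per_um
  }
  if (is.null(vs)) {
    vs <- voxel_size_um %||% 2
    warning("no resolution tags in ", path, "; using voxel size ", vs, " um")
  }
  as_volume(a, vs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NRRD -------------------------------------------------------------

# write a [y, x, z, k] channel array as NRRD0004, raw little-endian double,
# channel axis fastest
write_nrrd_field <- function(a, path, channel_names, voxel_size_um, extra = list()) {
  d <- dim(a)
  stopifnot(length(d) == 4L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# cardiofiber field; axes: component, y, x, z; vectors are (x,y,z)",
           "type: double",
           "dimension: 4",
           sprintf("sizes: %d %d %d %d", d[4], d[1], d[2], d[3]),
           "kinds: list space space space",
           "encoding: raw",
           "endian: little",
           sprintf("spacings: nan %g %g %g", voxel_size_um, voxel_size_um, voxel_size_um),
           sprintf("cardiofiber:channels:=%s", paste(channel_names, collapse = ",")),
           sprintf("cardiofiber:voxel_size_um:=%g", voxel_size_um))
  for (nm in names(extra)) hdr <- c(hdr, sprintf("cardiofiber:%s:=%s", nm, extra[[nm]]))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  writeBin(as.numeric(aperm(a, c(4L, 1L, 2L, 3L))), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, raw(), file.size(path))
  nl <- which(raw == as.raw(10L))
  blank <- nl[which(diff(nl) == 1L)[1] + 1L]   # the "\n\n" header terminator
  if (is.na(blank)) stop("malformed NRRD header in ", path)
  lines <- strsplit(rawToChar(raw[seq_len(blank - 2L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  getv <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ":=?\\s*"), "", hit[1])
  }
  if (!identical(getv("encoding"), "raw")) stop("only raw encoding supported")
  sizes <- as.integer(strsplit(getv("sizes"), "\\s+")[[1]])
  type <- getv("type")
  n <- prod(sizes)
  endian <- getv("endian") %||% "little"
  payload <- raw[(blank + 1L):length(raw)]
  dat <- switch(type,
    double = readBin(payload, numeric(), n, size = 8, endian = endian),
    float = readBin(payload, numeric(), n, size = 4, endian = endian),
    stop("unsupported NRRD type: ", type))
  if (length(dat) != n) stop("truncated NRRD payload in ", path)
  a <- aperm(array(dat, sizes), c(2L, 3L, 4L, 1L))
  vs <- as.numeric(getv("cardiofiber:voxel_size_um") %||% "2")
  attr(a, "voxel_size_um") <- vs
  attr(a, "channels") <- strsplit(getv("cardiofiber:channels") %||% "", ",")[[1]]
  a
}

#' Write / read orientation (vector) fields as NRRD
#'
#' Three channels in (x, y, z) order, raw little-endian doubles; voxel
#' spacing and the axial sign convention are recorded in the header.
#' Round-trips are lossless.
#'
#' @param field array `[y, x, z, 3]` (an `orientation_field` works).
#' @param path file path.
#' @return `write_*`: the path invisibly; `read_*`: the field array with
#'   `valid` attribute reconstructed from finite entries.
#' @export
write_vector_field <- function(field, path) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  write_nrrd_field(unclass(field), path, c("x", "y", "z"),
                   attr(field, "voxel_size_um") %||% 2,
                   extra = list(convention = "axial: v equivalent to -v"))
}

#' @rdname write_vector_field
#' @export
read_vector_field <- function(path) {
  a <- read_nrrd_field(path)
  if (dim(a)[4] != 3L) stop("expected 3 channels, found ", dim(a)[4])
  structure(a, valid = array(is.finite(a[, , , 1]), dim(a)[1:3]),
            class = "orientation_field")
}

#' Write / read structure-tensor fields as NRRD
#'
#' Six channels in upper-triangle order (xx, xy, xz, yy, yz, zz).
#' Symmetry is exact by construction on round-trip.
#'
#' @param tf a `tensor_field` (array `[y, x, z, 6]`).
#' @param path file path.
#' @export
write_tensor_field <- function(tf, path) {
  stopifnot(length(dim(tf)) == 4L, dim(tf)[4] == 6L)
  write_nrrd_field(unclass(tf), path, c("xx", "xy", "xz", "yy", "yz", "zz"),
                   attr(tf, "voxel_size_um") %||% 2)
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  a <- read_nrrd_field(path)
  if (dim(a)[4] != 6L) stop("expected 6 channels, found ", dim(a)[4])
  structure(a, class = "tensor_field")
}

# ---- tile sets --------------------------------------------------------

#' Save / load a tile set as TIFFs plus a JSON offsets manifest
#'
#' @param ts a `tile_set`.
#' @param dir directory (created if needed).
#' @export
save_tileset <- function(ts, dir) {
  stopifnot(inherits(ts, "tile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("tile_%03d.tif", seq_along(ts$tiles))
  for (i in seq_along(ts$tiles)) write_stack(ts$tiles[[i]], file.path(dir, files[i]))
  manifest <- list(files = files,
                   offsets = lapply(seq_len(nrow(ts$offsets)),
                                    function(i) unname(as.integer(ts$offsets[i, ]))),
                   offset_order = c("y", "x", "z"),
                   tile_shape = ts$tile_shape, full_dim = ts$full_dim,
                   overlap_fraction = ts$overlap_fraction,
                   voxel_size_um = voxel_size(ts$tiles[[1]]))
  jsonlite::write_json(manifest, file.path(dir, "offsets.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_tileset
#' @export
load_tileset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "offsets.json"), simplifyVector = TRUE)
  tiles <- lapply(mf$files, function(f) read_stack(file.path(dir, f), mf$voxel_size_um))
  om <- mf$offsets
  offs <- if (is.matrix(om)) om else matrix(as.integer(unlist(om)), ncol = 3, byrow = TRUE)
  storage.mode(offs) <- "integer"
  dimnames(offs) <- list(NULL, c("y", "x", "z"))
  structure(list(tiles = tiles, offsets = offs,
                 tile_shape = as.integer(mf$tile_shape),
                 full_dim = as.integer(mf$full_dim),
                 overlap_fraction = mf$overlap_fraction),
            class = "tile_set")
}

# ---- VTK --------------------------------------------------------------

#' Export streamlines as legacy-VTK polydata
#'
#' ASCII legacy format: one POLYDATA block with LINES plus a per-line
#' scalar (the seed elevation angle phi, degrees). Coordinates are in
#' micrometres.
#'
#' @param sl a `streamline_set`.
#' @param path output `.vtk` file.
#' @export
write_vtk_streamlines <- function(sl, path) {
  stopifnot(inherits(sl, "streamline_set"))
  npts <- vapply(sl$lines, nrow, integer(1))
  total <- sum(npts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardiofiber streamlines (um; colored by phi_deg)",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", total)), con)
  allp <- do.call(rbind, sl$lines)
  writeLines(apply(allp, 1L, function(p) sprintf("%.4f %.4f %.4f", p[1], p[2], p[3])), con)
  writeLines(sprintf("LINES %d %d", length(npts), length(npts) + total), con)
  off <- 0L
  for (i in seq_along(npts)) {
    writeLines(paste(c(npts[i], off + seq_len(npts[i]) - 1L), collapse = " "), con)
    off <- off + npts[i]
  }
  writeLines(c(sprintf("CELL_DATA %d", length(npts)),
               "SCALARS phi_deg float 1", "LOOKUP_TABLE default",
               sprintf("%.4f", sl$phi_deg)), con)
  invisible(path)
}

#' Export glyphs as legacy-VTK polydata
#'
#' Each glyph becomes a short line segment centred on its voxel, length
#' the `glyph_length_um` attribute, with the phi color scalar per cell.
#'
#' @param gs a `glyph_set`.
#' @param path output `.vtk` file.
#' @export
write_vtk_glyphs <- function(gs, path) {
  stopifnot(inherits(gs, "glyph_set"))
  len <- attr(gs, "glyph_length_um") / 2
  n <- nrow(gs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardiofiber orientation glyphs (um; colored by phi_deg)",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", 2L * n)), con)
  p0 <- cbind(gs$x - len * gs$dx, gs$y - len * gs$dy, gs$z - len * gs$dz)
  p1 <- cbind(gs$x + len * gs$dx, gs$y + len * gs$dy, gs$z + len * gs$dz)
  pts <- matrix(rbind(t(p0), t(p1)), ncol = 3, byrow = TRUE)
  writeLines(apply(pts, 1L, function(p) sprintf("%.4f %.4f %.4f", p[1], p[2], p[3])), con)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  writeLines(sprintf("2 %d %d", 2L * seq_len(n) - 2L, 2L * seq_len(n) - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", n),
               "SCALARS phi_deg float 1", "LOOKUP_TABLE default",
               sprintf("%.4f", gs$phi_deg)), con)
  invisible(path)
}

#' Write transmural profiles to CSV
#'
#' Columns: `sector`, `depth_um`, `mean_alpha_deg`, `n` (degrees and
#' micrometres).
#'
#' @param profile a `transmural_profile`.
#' @param path output `.csv`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
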