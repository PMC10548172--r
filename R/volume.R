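#' 3D intensity volumes
#'
#' A `volume3d` is a plain 3D numeric array carrying a physical voxel size.
#' Volumes are stored `[y, x, z]`: the first two indices span the short-axis
#' (x-y) image plane exactly as a TIFF page is read (rows = y, columns = x),
#' and the third index walks the stack along the longitudinal z axis.
#' All direction vectors elsewhere in the package are `(x, y, z)` component
#' triples in this frame.
#'
#' @param data numeric 3D array (`[y, x, z]`), or a matrix (treated as a
#'   single-slice volume).
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return a `volume3d` object.
#' @export
as_volume <- function(data, voxel_size_um = 2) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stopifnot(is.numeric(voxel_size_um), length(voxel_size_um) == 1L, voxel_size_um > 0)
  structure(data, voxel_size_um = as.numeric(voxel_size_um), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume3d> %d x %d x %d voxels (y, x, z) @ %g um/voxel\n",
              d[1], d[2], d[3], voxel_size(x)))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel size of a volume or field
#' @param x a `volume3d` or any object with a `voxel_size_um` attribute.
#' @return voxel edge length in micrometres.
#' @export
voxel_size <- function(x) {
  v <- attr(x, "voxel_size_um")
  if (is.null(v)) stop("object carries no voxel_size_um attribute")
  v
}

# extract channel k of a [y, x, z, k] array without dropping unit dims
channel <- function(a, k) {
  d <- dim(a)
  out <- unclass(a)[, , , k, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

# strip class/attrs down to a bare array (internal)
bare_array <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size_um") <- NULL
  attr(a, "meta") <- NULL
  a
}

# run code with a temporarily-seeded RNG, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
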