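#' Grey-value image volume
#'
#' Container for a reconstructed 3D tomographic image: a numeric array in
#' `(z, y, x)` order together with the isotropic voxel size and the bit depth
#' of the acquisition. All image operations in the package consume and return
#' this class.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param voxel_size isotropic voxel size in micrometres; must be positive.
#' @param bit_depth integer bit depth of the grey scale (8, 16 or 32).
#' @param provenance free-text provenance (phantom spec hash or file path).
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_size, bit_depth = 16L, provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array ordered (z, y, x)")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (micrometres)")
  }
  if (!bit_depth %in% c(8L, 16L, 32L)) stop("`bit_depth` must be 8, 16 or 32")
  structure(
    list(
      data = data,
      voxel_size = as.numeric(voxel_size),
      bit_depth = as.integer(bit_depth),
      provenance = provenance
    ),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume> %d x %d x %d voxels (z,y,x), %.3g um/voxel, %d-bit\n",
    d[1], d[2], d[3], x$voxel_size, x$bit_depth
  ))
  cat(sprintf(
    "  grey range: [%.1f, %.1f]%s\n",
    min(x$data), max(x$data),
    if (nzchar(x$provenance)) paste0("  (", x$provenance, ")") else ""
  ))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

grey_max <- function(v) 2^v$bit_depth - 1

#' Extract a transverse slice
#'
#' @param v a [volume()].
#' @param k slice index along z.
#' @return A `(ny, nx)` numeric matrix.
#' @export
volume_slice <- function(v, k) {
  stopifnot(inherits(v, "volume"))
  nz <- dim(v$data)[1]
  if (k < 1 || k > nz) stop("slice index out of range")
  v$data[k, , ]
}

#' Write a volume as a multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per z-slice (16-bit by default) and a JSON file holding the
#' voxel size, bit depth and provenance so the volume can be reconstructed
#' faithfully on read.
#'
#' @param v a [volume()].
#' @param path output TIFF path; the sidecar gets the same path with
#'   extension `.json`.
#' @param extra named list merged into the sidecar (e.g. phase table, seed,
#'   achieved volume fractions).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, extra = list()) {
  stopifnot(inherits(v, "volume"))
  gmax <- grey_max(v)
  pages <- lapply(seq_len(dim(v$data)[1]), function(k) {
    m <- v$data[k, , ]
    pmin(pmax(m / gmax, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = min(v$bit_depth, 16L))
  sidecar <- utils::modifyList(
    list(
      voxel_size_um = v$voxel_size,
      bit_depth = v$bit_depth,
      provenance = v$provenance,
      shape_zyx = dim(v$data)
    ),
    extra
  )
  jsonlite::write_json(sidecar, sidecar_path(path),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[Tt][Ii][Ff]+$", ".json", path)

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path with an accompanying JSON sidecar.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  gmax <- 2^meta$bit_depth - 1
  nz <- length(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(nz, d[1], d[2]))
  for (k in seq_len(nz)) arr[k, , ] <- pages[[k]] * gmax
  volume(arr, meta$voxel_size_um, as.integer(meta$bit_depth),
    provenance = meta$provenance %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
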