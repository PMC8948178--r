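#' 3D scalar volumes
#'
#' A `volume` carries a 3D scalar grid, a 4x4 voxel-index-to-world-mm
#' affine (NIfTI convention: 0-based voxel indices, centre-of-voxel), and
#' a modality tag. CT data are expected in Hounsfield units (air -1000,
#' water 0); MR intensities are arbitrary.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix (mm).
#' @param modality one of `"CT"`, `"T1w"`, `"T2w"`, `"LABEL"`.
#' @param units intensity units; defaults to `"HU"` for CT and
#'   `"arbitrary"` otherwise.
#' @return An object of class `volume`.
#' @export
volume <- function(data, affine, modality = c("CT", "T1w", "T2w", "LABEL"),
                   units = NULL) {
  modality <- match.arg(modality)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("each axis needs at least one voxel")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular")
  if (is.null(units)) units <- if (modality == "CT") "HU" else "arbitrary"
  structure(list(data = data, affine = affine, modality = modality,
                 units = units), class = "volume")
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' @export
print.volume <- function(x, ...) {
  vs <- voxel_size(x)
  cat(sprintf("volume [%s, %s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$modality, x$units, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume
#' @param v a `volume`.
#' @export
voxel_size <- function(v) sqrt(colSums(v$affine[1:3, 1:3]^2))

#' Voxel/world coordinate conversion
#'
#' Voxel indices are 1-based on the R side and converted to the NIfTI
#' 0-based convention internally. `voxel_to_world` accepts an `n x 3`
#' matrix of (possibly fractional) voxel indices.
#'
#' @param v a `volume`.
#' @param ijk `n x 3` voxel indices (1-based) or a single index triple.
#' @param xyz `n x 3` world coordinates (mm) or a single point.
#' @return Matrix (or vector) of converted coordinates.
#' @export
voxel_to_world <- function(v, ijk) {
  vec <- is.null(dim(ijk))
  m <- if (vec) matrix(ijk, ncol = 3) else as.matrix(ijk)
  out <- cbind(m - 1, 1) %*% t(v$affine)
  out <- out[, 1:3, drop = FALSE]
  if (vec) as.vector(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, xyz) {
  vec <- is.null(dim(xyz))
  m <- if (vec) matrix(xyz, ncol = 3) else as.matrix(xyz)
  out <- cbind(m, 1) %*% t(solve(v$affine))
  out <- out[, 1:3, drop = FALSE] + 1
  if (vec) as.vector(out) else out
}

# ---- NIfTI-1 serialisation -------------------------------------------------
# Minimal self-contained NIfTI-1 support (single-file .nii / .nii.gz,
# sform or qform affine, datatypes uint8/int16/int32/float32/float64/uint16).

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L))

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 (`.nii`, `.nii.gz`). The world mapping is
#' taken from the sform when `sform_code > 0`, else from the qform; a file
#' with neither (or with a singular affine) is rejected. Intensity
#' scaling (`scl_slope`/`scl_inter`) is applied when present.
#'
#' @param path file path.
#' @param modality modality tag for the returned [volume()]; default
#'   guesses `"CT"` only when the file minimum is close to -1000.
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = NULL) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header)")
  endian <- "little"
  rd <- function(what, n, size, off, signed = TRUE) {
    readBin(hdr_raw[(off + 1):length(hdr_raw)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  if (rd("integer", 1, 4, 0) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  dim8 <- rd("integer", 8, 2, 40)
  ndim <- dim8[1]
  if (ndim < 3L) stop("need a 3D volume")
  dims <- pmax(dim8[2:4], 1L)
  if (ndim > 3L && any(dim8[5:(1 + ndim)] > 1L))
    stop("4D+ volumes are not supported")
  datatype <- rd("integer", 1, 2, 70)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd("double", 8, 4, 76)
  vox_offset <- rd("double", 1, 4, 108)
  scl_slope <- rd("double", 1, 4, 112)
  scl_inter <- rd("double", 1, 4, 116)
  qform_code <- rd("integer", 1, 2, 252)
  sform_code <- rd("integer", 1, 2, 254)
  affine <- NULL
  if (sform_code > 0L) {
    srow <- rbind(rd("double", 4, 4, 280), rd("double", 4, 4, 296),
                  rd("double", 4, 4, 312))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rd("double", 1, 4, 256); c_ <- rd("double", 1, 4, 260)
    d <- rd("double", 1, 4, 264)
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ + a * d),
                  2 * (b * d - a * c_),
                  2 * (b * c_ - a * d), a^2 + c_^2 - b^2 - d^2,
                  2 * (c_ * d + a * b),
                  2 * (b * d + a * c_), 2 * (c_ * d - a * b),
                  a^2 + d^2 - b^2 - c_^2), 3, 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    off <- c(rd("double", 1, 4, 268), rd("double", 1, 4, 272),
             rd("double", 1, 4, 276))
    affine <- rbind(cbind(S, off), c(0, 0, 0, 1))
  } else {
    stop("NIfTI file carries neither sform nor qform affine")
  }
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("NIfTI affine is singular")
  # skip up to the data offset, then read the whole grid
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("NIfTI data truncated")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(as.double(vals), dim = dims)
  if (is.null(modality))
    modality <- if (min(data) < -900) "CT" else "T2w"
  volume(data, affine, modality = modality)
}

#' Write a NIfTI-1 volume
#'
#' Writes single-file NIfTI-1 with the sform affine set (and qform code
#' 0). Continuous data are stored as float32; `LABEL` volumes as uint8
#' when all labels fit, else uint16.
#'
#' @param v a [volume()].
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  if (v$modality == "LABEL") {
    if (any(v$data < 0) || any(v$data != round(v$data)))
      stop("LABEL volumes must hold non-negative integers")
    datatype <- if (max(v$data) <= 255) 2L else 512L
  } else datatype <- 16L
  dt <- .nifti_dtypes[[as.character(datatype)]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(nbytes) writeBin(raw(nbytes), con)
  dims <- dim(v$data)
  vs <- voxel_size(v)
  wb(348L, 4)                                   # sizeof_hdr
  pad(10 + 18 + 4 + 2 + 1 + 1)                  # data_type..dim_info
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2)  # dim
  wb(c(0, 0, 0), 4)                             # intent_p1..p3
  wb(0L, 2)                                     # intent_code
  wb(as.integer(datatype), 2)                   # datatype
  wb(as.integer(dt$bitpix), 2)                  # bitpix
  wb(0L, 2)                                     # slice_start
  wb(c(1, vs, 0, 0, 0, 0), 4)                   # pixdim (qfac = 1)
  wb(352, 4)                                    # vox_offset
  wb(1, 4); wb(0, 4)                            # scl_slope, scl_inter
  wb(0L, 2); pad(1 + 1)                         # slice_end, slice_code, xyzt
  wb(c(0, 0, 0, 0), 4)                          # cal_max..toffset
  wb(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw(sprintf("marmoreg %s volume", v$modality))
  writeBin(c(desc, raw(80 - length(desc))), con)
  pad(24)                                       # aux_file
  wb(0L, 2); wb(1L, 2)                          # qform_code, sform_code
  wb(c(0, 0, 0, 0, 0, 0), 4)                    # quatern/qoffset
  wb(as.double(t(v$affine[1:3, , drop = FALSE])), 4)  # srow_x/y/z
  pad(16)                                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  pad(4)                                        # extension flag
  if (dt$what == "integer") {
    wb(as.integer(v$data), dt$size)
  } else {
    wb(as.double(v$data), dt$size)
  }
  invisible(path)
}

#' Binary threshold mask
#'
#' Returns a binary `LABEL` volume marking voxels with intensity in
#' `[lo, hi)`. A CT threshold of -250 keeps soft tissue and bone while
#' excluding air; 1000 isolates bone.
#'
#' @param v a [volume()].
#' @param lo lower bound (inclusive).
#' @param hi upper bound (exclusive), default `Inf`.
#' @return A `LABEL` [volume()] of 0/1 on the same grid.
#' @export
threshold_mask <- function(v, lo, hi = Inf) {
  stopifnot(is_volume(v))
  if (lo >= hi) stop("threshold_mask: lo must be < hi")
  volume(array(as.double(v$data >= lo & v$data < hi), dim(v$data)),
         v$affine, modality = "LABEL", units = "binary")
}
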