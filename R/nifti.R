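## Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, little- or big-endian
## read, little-endian write).  Covers exactly what the pipeline needs:
## 3D/4D volumes, integer or float storage, a diagonal-scale sform affine.

.nifti_dtypes <- data.frame(
  name   = c("uint8", "int16", "int32", "float32", "float64"),
  code   = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' @param img numeric or integer array, 3 or 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxdim voxel size in mm (length 3); the affine is the identity
#'   scaled by `voxdim` (synthetic volumes are generated already aligned).
#' @param datatype storage type; default `"float32"`, or `"int32"` when
#'   `img` is an integer array (atlas labels round-trip exactly).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxdim = c(1, 1, 1),
                        datatype = if (is.integer(img)) "int32" else "float32") {
  stopifnot(is.array(img), length(dim(img)) %in% c(3L, 4L))
  dt <- .nifti_dtypes[.nifti_dtypes$name == datatype, ]
  if (nrow(dt) != 1L) stop("unsupported datatype: ", datatype)
  nd <- length(dim(img))
  dims <- c(nd, dim(img), rep(1L, 7L - nd))
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                              # sizeof_hdr
  w_raw(36L)                               # data_type, db_name, extents, ...
  w_i16(dims)                              # dim[8]
  w_raw(14L)                               # intent_p1..p3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix)         # datatype, bitpix
  w_i16(0L)                                # slice_start
  w_f32(c(1, voxdim, rep(1, 4)))           # pixdim[8] (qfac = 1)
  w_f32(352)                               # vox_offset
  w_f32(c(1, 0))                           # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                     # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                     # cal_max/min, slice_duration, toffset
  w_i32(c(0L, 0L))                         # glmax, glmin
  w_raw(80L + 24L)                         # descrip, aux_file
  w_i16(c(0L, 1L))                         # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                         # quatern b,c,d + qoffset x,y,z
  w_f32(c(voxdim[1], 0, 0, 0))             # srow_x
  w_f32(c(0, voxdim[2], 0, 0))             # srow_y
  w_f32(c(0, 0, voxdim[3], 0))             # srow_z
  w_raw(16L)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                                # extension flag

  vals <- as.vector(img)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(vals)), con, size = dt$bitpix / 8L,
             endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array; integer when stored integral and
#'   unscaled), `affine` (4x4), `voxdim` (length 3) and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  read_all <- function(endian) {
    con <- .nifti_open(path, "rb")
    on.exit(close(con))
    hdr_raw <- readBin(con, "raw", 348L)
    if (length(hdr_raw) < 348L) stop("malformed NIfTI header: truncated file")
    at <- function(off, what, n, size) {
      readBin(hdr_raw[(off + 1L):length(hdr_raw)], what, n = n, size = size,
              endian = endian, signed = size > 1L)
    }
    sizeof_hdr <- at(0L, "integer", 1L, 4L)
    if (sizeof_hdr != 348L) return(NULL)
    dims <- at(40L, "integer", 8L, 2L)
    code <- at(70L, "integer", 1L, 2L)
    pixdim <- at(76L, "numeric", 8L, 4L)
    vox_offset <- at(108L, "numeric", 1L, 4L)
    scl_slope <- at(112L, "numeric", 1L, 4L)
    scl_inter <- at(116L, "numeric", 1L, 4L)
    srow <- matrix(at(280L, "numeric", 12L, 4L), nrow = 3L, byrow = TRUE)
    magic <- rawToChar(hdr_raw[345:347])
    if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header: magic")
    dt <- .nifti_dtypes[.nifti_dtypes$code == code, ]
    if (nrow(dt) != 1L)
      stop("malformed NIfTI header: unsupported datatype code ", code)
    nd <- dims[1L]
    if (!nd %in% c(2L, 3L, 4L)) stop("malformed NIfTI header: dim[0] = ", nd)
    shape <- dims[2:(1L + nd)]
    n <- prod(shape)
    # re-open and skip to vox_offset (gz connections cannot seek reliably)
    con2 <- .nifti_open(path, "rb")
    on.exit(close(con2), add = TRUE)
    readBin(con2, "raw", max(vox_offset, 352))
    vals <- if (dt$name %in% c("float32", "float64")) {
      readBin(con2, "numeric", n, size = dt$bitpix / 8L, endian = endian)
    } else {
      readBin(con2, "integer", n, size = dt$bitpix / 8L, endian = endian,
              signed = dt$name != "uint8")
    }
    if (length(vals) < n) stop("malformed NIfTI file: data shorter than dim")
    if (is.finite(scl_slope) && scl_slope != 0 &&
        !(scl_slope == 1 && scl_inter == 0)) {
      vals <- vals * scl_slope + scl_inter
    }
    affine <- rbind(srow, c(0, 0, 0, 1))
    list(data = array(vals, dim = shape), affine = affine,
         voxdim = pixdim[2:4], datatype = dt$name)
  }
  out <- read_all("little")
  if (is.null(out)) out <- read_all("big")
  if (is.null(out)) stop("malformed NIfTI header: sizeof_hdr is not 348")
  out
}
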