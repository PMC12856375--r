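#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single 3-D volumes in NIfTI-1 format (`.nii` or
#' `.nii.gz`), little-endian, storing data as float32 — the conventional
#' storage type for seed-correlation maps. This is a deliberately small
#' subset of the standard: one 3-D image per file, no extensions, affine
#' limited to voxel spacing on the diagonal. It exists because the target
#' installations carry no neuroimaging I/O package; files written here are
#' readable by nibabel/FSL and vice versa for plain 3-D images.
#'
#' @param x numeric 3-D array.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param voxel_size numeric length-3 voxel spacing in mm.
#' @return `write_nifti()` returns `path` invisibly; `read_nifti()` returns
#'   a numeric 3-D array with attribute `voxel_size`.
#' @name nifti_io
NULL

.nifti_datatypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                         `4` = list(what = "integer", size = 2, signed = TRUE),
                         `8` = list(what = "integer", size = 4, signed = TRUE),
                         `16` = list(what = "double", size = 4, signed = TRUE),
                         `64` = list(what = "double", size = 8, signed = TRUE))

.open_raw <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
write_nifti <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("write_nifti() expects a 3-D array", call. = FALSE)
  }
  con <- .open_raw(path, "wb")
  on.exit(close(con))
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    b <- utf8ToInt(s)
    writeBin(as.raw(c(b, rep(0L, n - length(b)))), con)
  }

  w_i32(348)                              # sizeof_hdr
  w_raw(36)                               # data_type, db_name, extents, ...
  w_i16(c(3L, dim(x), 1L, 1L, 1L, 1L))    # dim[8]
  w_raw(14)                               # intent_p1..3, intent_code
  w_i16(16)                               # datatype: float32
  w_i16(32)                               # bitpix
  w_i16(0)                                # slice_start
  w_f32(c(0, voxel_size, 1, 1, 1, 1))     # pixdim[8]
  w_f32(352)                              # vox_offset
  w_f32(1); w_f32(0)                      # scl_slope, scl_inter
  w_i16(0); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0))                          # cal_max, cal_min
  w_f32(c(0, 0)); w_i32(c(0, 0))          # slice_duration, toffset, glmax, glmin
  w_chr("dmnfuse synthetic correlation map", 80)  # descrip
  w_raw(24)                               # aux_file
  w_i16(c(0, 1))                          # qform_code 0, sform_code 1
  w_f32(rep(0, 6))                        # quatern b,c,d, qoffset x,y,z
  w_f32(c(voxel_size[1], 0, 0, 0))        # srow_x
  w_f32(c(0, voxel_size[2], 0, 0))        # srow_y
  w_f32(c(0, 0, voxel_size[3], 0))        # srow_z
  w_raw(16)                               # intent_name
  w_chr("n+1", 4)                         # magic
  w_raw(4)                                # extension flag
  w_f32(as.double(x))
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .open_raw(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path, call. = FALSE)
  rd <- function(off, what, n, size, signed = TRUE, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian = "little") != 348L) {
    if (rd(0, "integer", 1, 4, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  dims <- rd(40, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3-D NIfTI volume: ", path, call. = FALSE)
  shape <- dims[2:(1 + ndim)]
  if (ndim > 3L && any(shape[4:ndim] != 1L)) {
    stop("only single 3-D volumes are supported: ", path, call. = FALSE)
  }
  shape <- shape[1:3]
  datatype <- rd(70, "integer", 1, 2, endian = endian)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- rd(76, "double", 8, 4, endian = endian)
  vox_offset <- rd(108, "double", 1, 4, endian = endian)
  scl_slope <- rd(112, "double", 1, 4, endian = endian)
  scl_inter <- rd(116, "double", 1, 4, endian = endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(as.double(vals), dim = shape)
  attr(out, "voxel_size") <- pixdim[2:4]
  out
}
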