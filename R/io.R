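#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii` / `.nii.gz`) with up
#' to 4 dimensions, covering the needs of this package: integer label
#' volumes, boolean masks, 3D scalar maps and 4D diffusion series. The codec
#' supports datatypes uint8, int16, int32, float32 and float64, applies
#' `scl_slope`/`scl_inter` on read, and writes an identity-orientation sform
#' scaled by the voxel spacing (RAS, 0-based voxel indices, axis order
#' (W,H,D)). It is not a general NIfTI implementation: orientation handling
#' beyond a diagonal sform, extensions, and NIfTI-2 are out of scope.
#'
#' @param path file path; gzip compression is inferred from a `.gz` suffix.
#' @return `read_nifti()`: list with `data` (numeric array), `spacing`
#'   (voxel sizes, mm, one per spatial dimension), `datatype` (NIfTI code).
#' @name nifti_io
NULL

.nifti_dt <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
.nifti_bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "': ", path, call. = FALSE)
  i16 <- function(off, n = 1L) readBin(hdr_raw[(off + 1):(off + 2 * n)], "integer",
                                       n = n, size = 2, endian = endian)
  f32 <- function(off, n = 1L) readBin(hdr_raw[(off + 1):(off + 4 * n)], "numeric",
                                       n = n, size = 4, endian = endian)
  dim0 <- i16(40, 8)
  ndim <- dim0[1]
  if (ndim < 1 || ndim > 4)
    stop(sprintf("unsupported dimensionality %d (1-4 supported)", ndim), call. = FALSE)
  dims <- dim0[2:(1 + ndim)]
  datatype <- i16(70)
  pixdim <- f32(76, 8)
  vox_offset <- f32(108)
  scl_slope <- f32(112); scl_inter <- f32(116)
  n_vox <- prod(dims)
  # skip to data
  to_skip <- max(vox_offset, 352) - 348
  if (to_skip > 0) readBin(con, "raw", n = to_skip)
  data <- switch(as.character(datatype),
    `2`  = as.numeric(readBin(con, "integer", n = n_vox, size = 1, signed = FALSE, endian = endian)),
    `4`  = as.numeric(readBin(con, "integer", n = n_vox, size = 2, endian = endian)),
    `8`  = as.numeric(readBin(con, "integer", n = n_vox, size = 4, endian = endian)),
    `16` = readBin(con, "numeric", n = n_vox, size = 4, endian = endian),
    `64` = readBin(con, "numeric", n = n_vox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  )
  if (length(data) != n_vox) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = dims),
       spacing = pixdim[2:(1 + min(ndim, 3))],
       datatype = datatype)
}

#' @param data numeric/integer/logical array, 1-4 dimensions.
#' @param spacing voxel size(s) in mm; recycled over the spatial dimensions.
#' @param datatype one of `"float64"`, `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"`.
#' @rdname nifti_io
#' @export
write_nifti <- function(data, path, spacing = 1, datatype = "float64") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (is.null(dim(data))) dim(data) <- length(data)
  dims <- dim(data)
  if (length(dims) > 4L) stop("at most 4 dimensions supported", call. = FALSE)
  dt <- .nifti_dt[[datatype]]
  if (is.null(dt)) stop("unsupported datatype '", datatype, "'", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), min(length(dims), 3L))
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:(1 + length(spacing))] <- spacing
  if (length(dims) == 4L) pixdim[5] <- 1
  dim8 <- integer(8); dim8[1] <- length(dims); dim8[2:(1 + length(dims))] <- dims
  dim8[dim8 == 0L] <- 1L
  sp3 <- rep_len(spacing, 3)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                      # sizeof_hdr
  wraw(35)                         # data_type, db_name, extents, session_error, regular
  wraw(1)                          # dim_info
  wi(dim8, 2)                      # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(dt, 2)                        # datatype
  wi(.nifti_bitpix[[as.character(dt)]], 2)  # bitpix
  wi(0L, 2)                        # slice_start
  wf(pixdim)                       # pixdim[8]
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2); wraw(2)               # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wraw(80 + 24)                    # descrip, aux_file
  wi(c(0L, 1L), 2)                 # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))          # quatern_b/c/d, qoffset_x/y/z
  wf(c(sp3[1], 0, 0, 0))           # srow_x
  wf(c(0, sp3[2], 0, 0))           # srow_y
  wf(c(0, 0, sp3[3], 0))           # srow_z
  wraw(16)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                          # extension flag
  vals <- as.vector(data)
  switch(datatype,
    uint8   = wi(vals, 1),
    int16   = wi(vals, 2),
    int32   = wi(vals, 4),
    float32 = writeBin(as.numeric(vals), con, size = 4, endian = "little"),
    float64 = writeBin(as.numeric(vals), con, size = 8, endian = "little")
  )
  invisible(path)
}

#' Read / write volumes with content checks
#'
#' Thin wrappers over the NIfTI codec that enforce the package's volume
#' contracts: label volumes must hold integer values, and paired volumes must
#' agree in shape and voxel spacing.
#'
#' @param path NIfTI file path.
#' @param labels if `TRUE`, reject files containing non-integer values and
#'   return an integer array.
#' @return list with `data` and `spacing`.
#' @export
read_volume <- function(path, labels = FALSE) {
  v <- read_nifti(path)
  if (labels) {
    if (any(v$data != round(v$data)))
      stop("label volume contains non-integer values: ", path, call. = FALSE)
    v$data <- array(as.integer(v$data), dim = dim(v$data))
  }
  v[c("data", "spacing")]
}

#' @param data array to write.
#' @param spacing voxel spacing (mm).
#' @param labels write as integer labels (int32) instead of float64.
#' @rdname read_volume
#' @export
write_volume <- function(data, path, spacing = 1, labels = FALSE) {
  if (labels) {
    if (any(data != round(data)))
      stop("refusing to write non-integer data as a label volume", call. = FALSE)
    write_nifti(data, path, spacing = spacing, datatype = "int32")
  } else {
    write_nifti(data, path, spacing = spacing, datatype = "float64")
  }
}

# shape/spacing agreement between paired volumes; names used in the message
check_alignment <- function(a, b, name_a = "volume A", name_b = "volume B") {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  if (!identical(da, db))
    stop(sprintf("alignment error: %s has shape %s but %s has shape %s",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x")), call. = FALSE)
  sa <- rep_len(a$spacing, 3); sb <- rep_len(b$spacing, 3)
  if (max(abs(sa - sb)) > 1e-4)
    stop(sprintf("alignment error: %s and %s differ in voxel spacing", name_a, name_b),
         call. = FALSE)
  invisible(TRUE)
}

# DWI 4th dimension must match the gradient table length
check_dwi_scheme <- function(dwi_data, scheme) {
  n4 <- if (length(dim(dwi_data)) == 4L) dim(dwi_data)[4] else 1L
  if (n4 != scheme$M)
    stop(sprintf("alignment error: DWI series has %d volumes but gradient table has %d",
                 n4, scheme$M), call. = FALSE)
  invisible(TRUE)
}
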