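#' 3-D image volume
#'
#' A scalar intensity grid on a Cartesian lattice with physical voxel
#' spacing. Grid axes map to the anatomical left-right (LR),
#' anterior-posterior (AP) and superior-inferior (SI) directions; the
#' default mapping is axis 1 = LR, axis 2 = AP, axis 3 = SI. `origin` is the
#' physical position (mm) of the centre of voxel (1, 1, 1).
#'
#' @param intensities a finite numeric 3-D array with at least 2 samples per
#'   axis.
#' @param spacing voxel size in mm per axis (length 3, all positive).
#' @param origin position of the first voxel centre in mm (length 3).
#' @param axis_labels anatomical direction of each grid axis.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing, origin = c(0, 0, 0),
                     axis_labels = c("LR", "AP", "SI")) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    se_stop("se_invalid_argument", "intensities must be a 3-D array")
  if (any(dim(intensities) < 2))
    se_stop("se_invalid_argument", "volume needs >= 2 samples per axis")
  if (!all(is.finite(intensities)))
    se_stop("se_invalid_argument", "volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    se_stop("se_invalid_argument", "spacing must be 3 positive values in mm")
  if (!setequal(axis_labels, c("LR", "AP", "SI")))
    se_stop("se_invalid_argument", "axis_labels must be a permutation of LR/AP/SI")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin), axis_labels = axis_labels),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d> %d x %d x %d voxels (%s), spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], paste(x$axis_labels, collapse = "/"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read or write a volume
#'
#' NIfTI (`.nii` / `.nii.gz`) IO is delegated to RNifti; spacing and origin
#' are taken from (written into) the header sform. NRRD (`.nrrd`) files are
#' supported for `raw` and `ascii` encodings of 3-D scalar data.
#'
#' @param path file path; format is chosen by extension.
#' @param vol a [volume3d()] (for writing).
#' @return `read_volume` returns a [volume3d()]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) se_stop("se_io_error", "expected a 3-D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # RNifti xforms are RAS-signed; we only rely on our own written volumes
  # having an axis-aligned positive-diagonal sform
  volume3d(arr, spacing = abs(sp), origin = origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(write_nrrd(vol, path))
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  m[1, 1] <- vol$spacing[1]; m[2, 2] <- vol$spacing[2]; m[3, 3] <- vol$spacing[3]
  m[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal NRRD IO (3-D scalar, raw/ascii encodings) ----

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) se_stop("se_io_error", "not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3) se_stop("se_io_error", "only 3-D NRRD volumes are supported")
  n <- prod(sizes)
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  if (enc == "raw") {
    what <- switch(type,
      "double" = "double", "float" = "double",
      "short" = "integer", "int" = "integer",
      "unsigned char" = "integer", "uchar" = "integer",
      se_stop("se_io_error", "unsupported NRRD type: %s", type))
    size <- switch(type, "double" = 8L, "float" = 4L, "short" = 2L,
                   "int" = 4L, "unsigned char" = 1L, "uchar" = 1L)
    signed <- !type %in% c("unsigned char", "uchar")
    vals <- readBin(con, what = what, n = n, size = size, signed = signed,
                    endian = "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    se_stop("se_io_error", "unsupported NRRD encoding: %s", enc)
  }
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dm <- t(vapply(dirs, function(d)
      as.numeric(strsplit(gsub("[()]", "", d), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(dm^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  volume3d(array(as.double(vals), dim = sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$intensities)
  hdr <- c(
    "NRRD0004",
    "# stackedellipse volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%g,%g,%g)", vol$origin[1], vol$origin[2], vol$origin[3]),
    "")
  writeLines(hdr, con)
  writeBin(as.double(vol$intensities), con, size = 8, endian = "little")
  invisible(path)
}
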