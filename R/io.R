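#' Read a binary segmentation volume from NRRD or NIfTI
#'
#' Reads a 3D mask, binarizes it at `binarize_threshold` and normalizes the
#' geometry metadata. The format is chosen from the file extension
#' (`.nrrd`/`.nhdr` vs `.nii`/`.nii.gz`). Only axis-aligned grids are
#' accepted: an NRRD `space directions` or NIfTI affine with off-diagonal
#' rotation/shear is rejected rather than silently resampled, because
#' segmentation masks on oblique grids would need an interpolation policy the
#' caller should choose explicitly.
#'
#' Missing spacing or origin metadata falls back to unit spacing / zero origin
#' with a warning.
#'
#' @param path path to a `.nrrd`, `.nhdr`, `.nii` or `.nii.gz` file.
#' @param binarize_threshold stored values strictly greater than this map to
#'   1, the rest to 0. Default 0.5, which leaves already-binary masks
#'   unchanged.
#' @return A [binary_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, binarize_threshold = 0.5) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", lower)) {
    vol <- read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- read_nifti_mask(path)
  } else {
    stop("unrecognized volume format for ", path,
         " (expected .nrrd, .nhdr, .nii or .nii.gz)", call. = FALSE)
  }
  if (length(dim(vol$data)) != 3L)
    stop("expected a 3D volume in ", path, ", got ",
         length(dim(vol$data)), " dimensions", call. = FALSE)
  binary_volume(array(vol$data > binarize_threshold, dim(vol$data)),
                spacing = vol$spacing, origin = vol$origin)
}

#' Write a binary volume to NRRD or NIfTI
#'
#' The written file round-trips through [read_volume()] to an identical
#' volume (voxelwise-equal data; spacing and origin within float tolerance).
#' NRRD files are written as NRRD0004, `unsigned char`, gzip encoding;
#' NIfTI as uint8 with the grid geometry in the qform.
#'
#' @param vol a [binary_volume()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stop_if_not_volume(vol, "vol")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    write_nrrd(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti_mask(vol, path)
  } else {
    stop("unrecognized output format for ", path, call. = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# NRRD. Minimal NRRD0004 support for 3D masks: raw / gzip / ascii (txt)
# encodings, scalar integer and float types, axis-aligned space directions.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "int8_t" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "uint8_t" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "int16_t" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "uint16_t" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "int32_t" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "numeric", size = 4, signed = TRUE),
  "double" = list(what = "numeric", size = 8, signed = TRUE)
)

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("not an NRRD file (bad magic): ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("truncated NRRD header in ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  if (is.null(fields$dimension) || is.null(fields$sizes) ||
      is.null(fields$type) || is.null(fields$encoding))
    stop("NRRD header missing required fields in ", path, call. = FALSE)
  ndim <- as.integer(fields$dimension)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (ndim != 3L || length(sizes) != 3L)
    stop("expected a 3D NRRD volume in ", path, ", got dimension ",
         ndim, call. = FALSE)
  type <- nrrd_types[[tolower(fields$type)]]
  if (is.null(type))
    stop("unsupported NRRD type '", fields$type, "' in ", path, call. = FALSE)
  endian <- if (!is.null(fields$endian) && fields$endian == "big")
    "big" else "little"

  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (enc %in% c("raw", "gzip", "gz")) {
    if (enc != "raw") payload <- memDecompress(payload, type = "gzip")
    if (length(payload) < n * type$size)
      stop("NRRD payload shorter than promised by header in ", path,
           call. = FALSE)
    vals <- readBin(payload, what = type$what, n = n, size = type$size,
                    signed = if (type$size <= 2) type$signed else TRUE,
                    endian = endian)
  } else if (enc %in% c("ascii", "txt", "text")) {
    vals <- as.numeric(scan(text = rawToChar(payload), quiet = TRUE))
    if (length(vals) < n)
      stop("NRRD ascii payload shorter than promised by header in ", path,
           call. = FALSE)
    vals <- vals[seq_len(n)]
  } else {
    stop("unsupported NRRD encoding '", fields$encoding, "' in ", path,
         call. = FALSE)
  }

  spacing <- NULL
  origin <- NULL
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)|none", fields[["space directions"]]))[[1]]
    dirs <- toks[toks != "none"]
    if (length(dirs) == 3L) {
      mat <- t(vapply(dirs, parse_nrrd_vector, numeric(3)))
      offdiag <- mat - diag(diag(mat))
      if (any(abs(offdiag) > 1e-9 * max(abs(mat))))
        stop("non-axis-aligned NRRD space directions in ", path,
             "; resample the mask to an axis-aligned grid first",
             call. = FALSE)
      if (any(diag(mat) < 0))
        stop("negative NRRD space directions in ", path,
             " (flipped axes are not supported)", call. = FALSE)
      spacing <- diag(mat)
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vector(fields[["space origin"]])
  if (is.null(spacing)) {
    warning("no spacing metadata in ", path, "; assuming 1 mm isotropic",
            call. = FALSE)
    spacing <- c(1, 1, 1)
  }
  if (is.null(origin)) origin <- c(0, 0, 0)
  # NRRD stores the first (fastest) axis first, matching R's column-major
  # array layout, so the values fill the array directly.
  list(data = array(as.numeric(vals), sizes), spacing = spacing,
       origin = origin)
}

write_nrrd <- function(vol, path) {
  header <- c(
    "NRRD0004",
    "# written by craniossm",
    "type: unsigned char",
    "dimension: 3",
    "space dimension: 3",
    paste("sizes:", paste(dim(vol$data), collapse = " ")),
    paste0("space directions: ",
           paste(sprintf("(%.17g,%.17g,%.17g)",
                         c(vol$spacing[1], 0, 0),
                         c(0, vol$spacing[2], 0),
                         c(0, 0, vol$spacing[3])), collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  payload <- memCompress(as.raw(as.vector(vol$data)), type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# NIfTI via RNifti. Geometry is taken from the stored xform; only diagonal,
# non-negative affines are accepted (see read_volume).

read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  xf <- try(RNifti::xform(img), silent = TRUE)
  spacing <- NULL
  origin <- NULL
  if (!inherits(xf, "try-error") && !is.null(attr(xf, "code")) &&
      attr(xf, "code") > 0) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot - diag(diag(rot))
    if (any(abs(offdiag) > 1e-6 * max(abs(rot))))
      stop("non-axis-aligned NIfTI affine in ", path,
           "; resample the mask to an axis-aligned grid first", call. = FALSE)
    if (any(diag(rot) < 0))
      stop("negative NIfTI affine diagonal in ", path,
           " (flipped axes are not supported)", call. = FALSE)
    spacing <- diag(rot)
    origin <- xf[1:3, 4]
  }
  if (is.null(spacing)) {
    pd <- RNifti::pixdim(img)[1:3]
    if (all(is.finite(pd)) && all(pd > 0)) {
      spacing <- pd
      origin <- c(0, 0, 0)
    } else {
      warning("no usable geometry in ", path,
              "; assuming 1 mm isotropic spacing, zero origin", call. = FALSE)
      spacing <- c(1, 1, 1)
      origin <- c(0, 0, 0)
    }
  }
  list(data = array(as.numeric(arr), dim(arr)), spacing = spacing,
       origin = origin)
}

write_nifti_mask <- function(vol, path) {
  img <- RNifti::asNifti(array(as.double(vol$data), dim(vol$data)),
                         reference = list(pixdim = c(1, vol$spacing, 1, 0, 0, 0)),
                         datatype = "uint8")
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
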