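# Image stack container plus MRC2014 / TIFF readers and writers.
#
# MRC support is implemented directly against the MRC2014 header layout
# (modes 0, 1, 2, 6); the pixel-size header field stores Angstrom, so
# nanometre voxel sizes are written as nm * 10 and read back as /10.

#' Construct an image stack
#'
#' The universal 3D currency of the pipeline: a z-ordered grayscale volume
#' with a physical voxel size.
#'
#' @param data 3D numeric array indexed `[z, y, x]` (a 2D matrix is
#'   promoted to a single-slice stack with a warning)
#' @param voxel_size_nm numeric length-3 `(x, y, z)` voxel size in nm
#' @param origin_label free-text provenance tag
#' @return an `image_stack` object
#' @export
image_stack <- function(data, voxel_size_nm = c(1, 1, 1), origin_label = "") {
  if (is.matrix(data)) {
    warning("image_stack: 2D input promoted to a single-slice stack")
    data <- array(data, dim = c(1, dim(data)))
  }
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(dim(data) < 1)) stop("image_stack: all dimensions must be >= 1")
  if (length(voxel_size_nm) == 1) voxel_size_nm <- rep(voxel_size_nm, 3)
  stopifnot(length(voxel_size_nm) == 3, all(voxel_size_nm > 0))
  if (!all(is.finite(data))) stop("image_stack: non-finite intensity values")
  structure(
    list(
      data = data,
      voxel_size_nm = as.numeric(voxel_size_nm),
      origin_label = as.character(origin_label)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack %d x %d x %d (z,y,x), voxel %.4g x %.4g x %.4g nm%s>\n",
    d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
    x$voxel_size_nm[3],
    if (nzchar(x$origin_label)) paste0(", ", x$origin_label) else ""
  ))
  invisible(x)
}

#' Stack dimensions
#' @param stack an `image_stack`
#' @return integer `(z, y, x)` extents
#' @export
stack_dim <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$data)
}

#' Extract one z-slice as a matrix
#' @param stack an `image_stack`
#' @param z 1-based slice index
#' @return numeric matrix `[y, x]`
#' @export
stack_slice <- function(stack, z) {
  stopifnot(inherits(stack, "image_stack"))
  matrix(stack$data[z, , ], dim(stack$data)[2], dim(stack$data)[3])
}

# ---- MRC2014 ----------------------------------------------------------

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported MRC mode: ", mode)
  )
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  mxyz <- hdr_ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little") # cellb
  readBin(con, "integer", n = 3, size = 4, endian = "little") # mapc/r/s
  readBin(con, "numeric", n = 3, size = 4, endian = "little") # dmin/max/mean
  readBin(con, "integer", n = 1, size = 4, endian = "little") # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 208)
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  if (!(substr(map_tag, 1, 3) == "MAP")) {
    stop("not an MRC2014 file (missing MAP tag): ", path)
  }
  if (nx < 1 || ny < 1 || nz < 1) stop("MRC with empty dimensions: ", path)
  info <- mrc_mode_info(mode)
  seek(con, 1024 + max(0, nsymbt))
  n <- as.double(nx) * ny * nz
  v <- readBin(con, info$what, n = n, size = info$size,
               signed = info$signed, endian = "little")
  if (length(v) != n) stop("truncated MRC data: ", path)
  storage.mode(v) <- "double"
  vol <- aperm(array(v, dim = c(nx, ny, nz)), c(3, 2, 1))
  voxel_a <- ifelse(mxyz > 0, cella / mxyz, 0)
  list(data = vol, voxel_size_nm = voxel_a / 10, mode = mode)
}

write_mrc <- function(stack, path, mode = 2L) {
  d <- dim(stack$data)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  info <- mrc_mode_info(mode)
  if (info$what == "integer") {
    lim <- switch(as.character(mode),
                  "0" = c(-128, 127), "1" = c(-32768, 32767),
                  "6" = c(0, 65535))
    rng <- range(stack$data)
    if (rng[1] < lim[1] || rng[2] > lim[2]) {
      stop("write_stack: data range [", rng[1], ", ", rng[2],
           "] does not fit MRC mode ", mode)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  cella <- c(nx, ny, nz) * stack$voxel_size_nm * 10 # nm -> Angstrom
  writeBin(as.integer(c(nx, ny, nz, mode, 0, 0, 0, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(cella), con, size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(stack$data), max(stack$data), mean(stack$data))),
           con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 0)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con) # extra words 26-50 (incl. exttyp/nversion, zeroed)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian machst
  writeBin(as.numeric(sd(stack$data)), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con)
  v <- as.vector(aperm(stack$data, c(3, 2, 1)))
  if (info$what == "integer") {
    v <- as.integer(round(v))
    writeBin(v, con, size = info$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- TIFF -------------------------------------------------------------

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # grayscale from multichannel
    p
  })
  d <- dim(pages[[1]])
  vol <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
  vol
}

write_tiff_stack <- function(stack, path) {
  v <- stack$data
  mx <- max(v)
  if (any(v < 0)) stop("write_stack: TIFF output requires nonnegative values")
  is_int <- max(abs(v - round(v))) < 1e-9
  if (is_int && mx <= 255) {
    bits <- 8L
  } else if (is_int && mx <= 65535) {
    bits <- 16L
  } else if (mx <= 1) {
    bits <- 0L # already normalised float; store as 32-bit float
  } else {
    stop("write_stack: TIFF supports 8/16-bit integer or [0,1] float data; ",
         "use MRC for general float volumes")
  }
  pages <- lapply(seq_len(dim(v)[1]), function(z) {
    m <- matrix(v[z, , ], dim(v)[2], dim(v)[3])
    if (bits == 8L) m / 255 else if (bits == 16L) m / 65535 else m
  })
  if (bits == 0L) {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  }
  invisible(path)
}

# ---- public API -------------------------------------------------------

#' Read an image stack from MRC2014 or TIFF
#'
#' @param path file path
#' @param format_hint optional `"mrc"` or `"tiff"`; inferred from the file
#'   extension (and MRC magic) when omitted
#' @param voxel_size_nm fallback voxel size when the file carries none
#' @return an `image_stack` with `(z, y, x)` axis order
#' @export
read_stack <- function(path, format_hint = NULL, voxel_size_nm = NULL) {
  if (!file.exists(path)) stop("read_stack: file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("mrc", "map", "rec", "st")) "mrc"
           else if (ext %in% c("tif", "tiff")) "tiff"
           else "mrc"
  }
  if (fmt == "mrc") {
    r <- tryCatch(read_mrc(path), error = function(e) {
      stop("read_stack: cannot parse MRC file ", path, ": ",
           conditionMessage(e))
    })
    vox <- r$voxel_size_nm
    if (any(vox <= 0)) {
      if (!is.null(voxel_size_nm)) {
        vox <- rep(voxel_size_nm, length.out = 3)
      } else {
        warning("read_stack: no voxel size in header; assuming 1 nm")
        vox <- c(1, 1, 1)
      }
    }
    return(image_stack(r$data, vox, origin_label = basename(path)))
  }
  if (fmt == "tiff") {
    vol <- tryCatch(read_tiff_stack(path), error = function(e) {
      stop("read_stack: cannot parse TIFF file ", path, ": ",
           conditionMessage(e))
    })
    vox <- if (!is.null(voxel_size_nm)) rep(voxel_size_nm, length.out = 3) else {
      warning("read_stack: TIFF carries no voxel size; assuming 1 nm")
      c(1, 1, 1)
    }
    return(image_stack(vol, vox, origin_label = basename(path)))
  }
  stop("read_stack: unknown format: ", fmt)
}

#' Write an image stack to MRC2014 or TIFF
#'
#' MRC output stores the voxel size in the standard cell/grid header fields
#' (nm written as Angstrom, i.e. nm x 10). Mode 2 (float32) is the default;
#' integer data fitting modes 0/1/6 can be requested.
#'
#' @param stack an `image_stack`
#' @param path output path
#' @param format `"mrc"` or `"tiff"`
#' @param mrc_mode MRC data mode (0, 1, 2 or 6)
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, format = c("mrc", "tiff"), mrc_mode = 2L) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "image_stack"))
  if (any(dim(stack$data) < 1)) stop("write_stack: empty stack")
  ok <- tryCatch({
    if (format == "mrc") write_mrc(stack, path, mode = mrc_mode)
    else write_tiff_stack(stack, path)
    TRUE
  }, error = function(e) {
    stop("write_stack: cannot write ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

# ---- sidecar metadata -------------------------------------------------

#' Read per-section metadata from a YAML/JSON sidecar
#'
#' Each record needs `section_index`, `cut_thickness_nm`, `et_slice_count`
#' and `voxel_size_nm`. A cutting thickness smaller than the reconstructed
#' ET thickness is reported as an attribute, never silently clipped.
#'
#' @param path YAML or JSON file holding a list of section records
#' @return `data.frame` sorted by `section_index` (class `section_meta`)
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop("read_sidecar: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (length(recs) == 0) {
    return(structure(
      data.frame(
        section_index = integer(0), cut_thickness_nm = numeric(0),
        et_slice_count = integer(0), voxel_size_nm = numeric(0)
      ),
      class = c("section_meta", "data.frame")
    ))
  }
  required <- c("section_index", "cut_thickness_nm", "et_slice_count",
                "voxel_size_nm")
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    missing_f <- setdiff(required, names(r))
    if (length(missing_f) > 0) {
      stop("read_sidecar: record ", i, " is missing field(s): ",
           paste(missing_f, collapse = ", "))
    }
    data.frame(
      section_index = as.integer(r$section_index),
      cut_thickness_nm = as.numeric(r$cut_thickness_nm),
      et_slice_count = as.integer(r$et_slice_count),
      voxel_size_nm = as.numeric(r$voxel_size_nm)
    )
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$section_index)) {
    stop("read_sidecar: duplicate section_index values")
  }
  if (any(df$section_index < 1)) stop("read_sidecar: section_index must be >= 1")
  if (any(df$cut_thickness_nm <= 0) || any(df$voxel_size_nm <= 0) ||
      any(df$et_slice_count < 1)) {
    stop("read_sidecar: thicknesses and voxel sizes must be positive")
  }
  df <- df[order(df$section_index), , drop = FALSE]
  rownames(df) <- NULL
  thin <- df$cut_thickness_nm < df$et_slice_count * df$voxel_size_nm
  structure(df, class = c("section_meta", "data.frame"),
            thicker_than_cut = df$section_index[thin])
}

#' Persist a pipeline stage artifact
#'
#' Stage artifacts (chained affines, deformation fields, gap estimates) are
#' stored as a single self-describing RDS container with named entries
#' (e.g. `field$dx`, `field$dy`, `gaps$top`, `gaps$bot`) plus a JSON
#' summary of scalar metadata alongside.
#'
#' @param artifact named list
#' @param path output `.rds` path
#' @return `path`, invisibly
#' @export
write_stage_artifact <- function(artifact, path) {
  stopifnot(is.list(artifact))
  saveRDS(artifact, path)
  summarise <- function(x) {
    if (is.numeric(x) && length(x) <= 16) x
    else if (is.character(x) && length(x) == 1) x
    else if (is.list(x)) lapply(x, summarise)
    else paste0("<", paste(class(x)[1]), " ", paste(dim2(x), collapse = "x"), ">")
  }
  jsonlite::write_json(lapply(artifact, summarise),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Load a pipeline stage artifact written by [write_stage_artifact()]
#' @param path `.rds` path
#' @return the artifact list
#' @export
read_stage_artifact <- function(path) {
  if (!file.exists(path)) stop("read_stage_artifact: file not found: ", path)
  readRDS(path)
}
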