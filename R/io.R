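#' Read and write point clouds as PLY
#'
#' Minimal PLY support for `x`, `y`, `z` float vertex clouds: ASCII and
#' binary little-endian files are read; ASCII is written. Coordinates are
#' meters in the camera frame.
#'
#' @param path File path.
#' @param points A point cloud tibble (columns `x`, `y`, `z`).
#' @return `read_ply()` returns a point-cloud tibble; `write_ply()` returns
#'   `path` invisibly.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!identical(trimws(header[1]), "ply")) stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY header missing format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  vert_line <- grep("^element vertex ", header, value = TRUE)
  if (!length(vert_line)) stop("PLY header missing vertex element")
  n <- as.integer(strsplit(trimws(vert_line[1]), "\\s+")[[1]][3])
  # property lines of the vertex element (assume vertex is the only element)
  props <- strsplit(trimws(grep("^property ", header, value = TRUE)), "\\s+")
  types <- vapply(props, `[`, "", 2L)
  names(types) <- vapply(props, `[`, "", 3L)
  if (!all(c("x", "y", "z") %in% names(types))) {
    stop("PLY vertex element lacks x/y/z properties")
  }
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int = 4L, uint = 4L, int32 = 4L)
  if (identical(fmt, "ascii")) {
    if (n == 0) {
      vals <- matrix(numeric(0), 0, length(types))
    } else {
      txt <- readLines(con, n = n)
      vals <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
                     nrow = n, byrow = TRUE)
    }
  } else if (identical(fmt, "binary_little_endian")) {
    sz <- sizes[types]
    if (anyNA(sz)) stop("unsupported PLY property type")
    rec <- sum(sz)
    raw <- readBin(con, "raw", n = n * rec)
    vals <- matrix(NA_real_, n, length(types))
    off <- 0L
    for (j in seq_along(types)) {
      what <- if (types[j] %in% c("float", "float32", "double", "float64")) "double" else "integer"
      byte_idx <- as.vector(outer(seq_len(sz[j]), (seq_len(n) - 1L) * rec + off, `+`))
      vals[, j] <- readBin(raw[byte_idx], what, n = n, size = sz[j], endian = "little")
      off <- off + sz[j]
    }
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  colnames(vals) <- names(types)
  as_point_cloud(tibble::as_tibble(vals[, c("x", "y", "z"), drop = FALSE]))
}

#' @rdname read_ply
#' @export
write_ply <- function(points, path) {
  pts <- as_point_cloud(points)
  header <- c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(pts)),
    "property float x", "property float y", "property float z",
    "end_header"
  )
  body <- sprintf("%.9g %.9g %.9g", pts$x, pts$y, pts$z)
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- PNG depth I/O ---------------------------------------------------------
# Depth images are stored as 16-bit grayscale PNG with pixel value = depth in
# millimeters and 0 = background/invalid. png::readPNG decodes 16-bit files,
# but no pre-installed writer emits them, so the encoder below assembles the
# PNG container directly (memCompress produces the zlib stream PNG expects).

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320 as signed 32-bit
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

uint32_be <- function(x) {
  # x may exceed .Machine$integer.max only as a signed crc; handle both
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  c(uint32_be(length(data)), payload, uint32_be(crc32(payload)))
}

#' Read and write 16-bit depth PNG images
#'
#' Depth images travel as 16-bit grayscale PNG with pixel value = depth in
#' millimeters and 0 = background/invalid; camera intrinsics live in a
#' sidecar config (see [read_intrinsics()]).
#'
#' @param depth A `depth_image` (meters) or numeric matrix.
#' @param path PNG file path.
#' @param cam Optional [camera_intrinsics()]; defaults to the `cam`
#'   attribute of `depth`. Used only to re-attach intrinsics on read.
#' @return `read_depth_png()` returns a `depth_image` in meters;
#'   `write_depth_png()` returns `path` invisibly.
#' @export
write_depth_png <- function(depth, path) {
  m <- unclass(depth)
  stopifnot(is.matrix(m))
  mm <- round(m * 1000)
  if (any(mm < 0)) stop("negative depth cannot be encoded")
  if (any(mm > 65535)) stop("depth exceeds the 16-bit millimeter range (65.535 m)")
  h <- nrow(m); w <- ncol(m)
  hi <- mm %/% 256L; lo <- mm %% 256L
  sl <- matrix(0L, h, 2L * w + 1L)  # leading filter byte 0 per scanline
  sl[, seq(2L, 2L * w, by = 2L)] <- hi
  sl[, seq(3L, 2L * w + 1L, by = 2L)] <- lo
  raw_data <- as.raw(as.vector(t(sl)))
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  out <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(raw_data, "gzip")),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

#' @rdname write_depth_png
#' @export
read_depth_png <- function(path, cam = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  new_depth_image(img * 65.535, cam)  # value/65535 * 65535 mm -> m
}

#' Export / import a model input as PNG plus JSON sidecar
#'
#' The 8-bit gray image is written with [png::writePNG()]; the crop
#' transform and depth-normalization record go into a JSON sidecar beside
#' it so original-image coordinates can be reconstructed later.
#'
#' @param input A `model_input` (see [crop_and_scale()]).
#' @param path PNG path; the sidecar is `path` with extension `.json`.
#' @return `write_model_input()` returns `path` invisibly;
#'   `read_model_input()` returns a `model_input`.
#' @export
write_model_input <- function(input, path) {
  stopifnot(inherits(input, "model_input"))
  png::writePNG(input$image / 255, path)
  sidecar <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(
    list(transform = unclass(input$transform), norm = input$norm),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_input
#' @export
read_model_input <- function(path) {
  img <- round(png::readPNG(path) * 255)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  sidecar <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tr <- do.call(crop_transform, as.list(meta$transform))
  new_model_input(img, tr, meta$norm)
}

#' Serialize a heatmap stack
#'
#' Stores the stack as a compressed array container (R serialization) with
#' the keypoint-name index carried in the dimnames.
#'
#' @param stack A `heatmap_stack`.
#' @param path Output file path.
#' @return `write_heatmaps()` returns `path` invisibly; `read_heatmaps()`
#'   returns a `heatmap_stack`.
#' @export
write_heatmaps <- function(stack, path) {
  stopifnot(inherits(stack, "heatmap_stack"))
  saveRDS(stack, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_heatmaps
#' @export
read_heatmaps <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "heatmap_stack")) stop("file does not hold a heatmap stack")
  x
}
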