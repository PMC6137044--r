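# Minimal multi-page TIFF codec.
#
# No TIFF package is available in the target R stack, so the package carries
# its own baseline codec: little-endian, uncompressed, single-sample grayscale,
# one strip per page. The writer emits 16-bit unsigned data when every pixel is
# integral and within [0, 65535], and 64-bit IEEE floats otherwise, so that
# write/read round trips are bit-exact in both cases. The reader additionally
# accepts uint8/uint16/uint32 and float32/float64 uncompressed TIFFs with
# multiple strips, in either byte order. Acquisition metadata travels as a JSON
# string in the ImageDescription tag of the first page.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `11` = 4L, `12` = 8L)

#' Write an image stack as a multi-page TIFF
#'
#' Uncompressed grayscale TIFF, one page per frame. Pixel data are stored as
#' 16-bit unsigned integers when all values are integral and in
#' `[0, 65535]`, and as 64-bit floats otherwise; either way the round trip
#' through [read_stack()] is bit-exact. `pixel_size_nm` and
#' `frame_interval_s` are stored as JSON in the ImageDescription tag.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @param metadata Logical; write the metadata tag (default `TRUE`).
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, metadata = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- stack$frames
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]]); n <- length(frames)
  all_vals_ok <- all(vapply(frames, function(f) {
    all(is.finite(f)) && all(f >= 0) && all(f <= 65535) && all(f == round(f))
  }, logical(1)))
  if (all_vals_ok) {
    bits <- 16L; fmt <- 1L   # uint16
  } else {
    bits <- 64L; fmt <- 3L   # float64
  }
  bytes_per_px <- bits %/% 8L
  frame_bytes <- h * w * bytes_per_px

  desc_raw <- raw(0)
  if (metadata) {
    desc <- jsonlite::toJSON(
      list(pixel_size_nm = stack$pixel_size_nm,
           frame_interval_s = stack$frame_interval_s),
      auto_unbox = TRUE, digits = NA)
    desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  desc_off <- 8L
  data_off0 <- desc_off + length(desc_raw)
  ifd0_off <- data_off0 + n * frame_bytes
  if (ifd0_off %% 2L == 1L) ifd0_off <- ifd0_off + 1L
  n_entries <- function(k) if (k == 1L && metadata) 11L else 10L
  ifd_size <- function(k) 2L + 12L * n_entries(k) + 4L
  ifd_offs <- integer(n)
  off <- ifd0_off
  for (k in seq_len(n)) { ifd_offs[k] <- off; off <- off + ifd_size(k) }

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wr16(42L)
  wr32(ifd0_off)
  if (length(desc_raw)) writeBin(desc_raw, con)
  # pixel data, rows sequential
  for (k in seq_len(n)) {
    v <- as.vector(t(frames[[k]]))
    if (bits == 16L) {
      writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 8L, endian = "little")
    }
  }
  if ((data_off0 + n * frame_bytes) %% 2L == 1L) writeBin(as.raw(0L), con)
  # IFDs
  entry <- function(tag, type, count, value) {
    wr16(tag); wr16(type); wr32(count)
    if (type == 3L && count == 1L) { wr16(value); wr16(0L) } else wr32(value)
  }
  for (k in seq_len(n)) {
    wr16(n_entries(k))
    entry(256L, 4L, 1L, w)                       # ImageWidth
    entry(257L, 4L, 1L, h)                       # ImageLength
    entry(258L, 3L, 1L, bits)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    if (k == 1L && metadata) {
      entry(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    }
    entry(273L, 4L, 1L, data_off0 + (k - 1L) * frame_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, 1L, h)                       # RowsPerStrip
    entry(279L, 4L, 1L, frame_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, fmt)                     # SampleFormat
    wr32(if (k < n) ifd_offs[k + 1L] else 0L)    # next IFD
  }
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Supports uncompressed single-sample grayscale TIFFs (uint8/16/32,
#' float32/64, either byte order, any strip layout). Metadata written by
#' [write_stack()] is recovered from the ImageDescription tag; if absent, the
#' documented defaults (pixel size 80 nm, interval 0.1 s) are applied with a
#' warning.
#'
#' @param path Path to a TIFF file.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path, call. = FALSE)
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path, call. = FALSE)
  rd <- function(idx, size, what = "integer", signed = TRUE) {
    readBin(raw[idx:(idx + size - 1L)], what, n = 1L, size = size,
            endian = endian, signed = signed)
  }
  u16 <- function(i) rd(i, 2L, signed = FALSE)
  u32 <- function(i) { v <- rd(i, 4L); if (v < 0) v + 2^32 else v }
  if (u16(3L) != 42L) stop("not a TIFF file (bad magic): ", path, call. = FALSE)

  read_values <- function(type, count, field_off) {
    size <- TIFF_TYPE_SIZES[[as.character(type)]]
    total <- size * count
    off <- if (total <= 4L) field_off else u32(field_off) + 1L
    if (type == 2L) {
      return(rawToChar(raw[off:(off + count - 1L)][raw[off:(off + count - 1L)] != as.raw(0L)]))
    }
    vapply(seq_len(count), function(j) {
      i <- off + (j - 1L) * size
      switch(as.character(type),
             `1` = as.numeric(rd(i, 1L, signed = FALSE)),
             `3` = as.numeric(u16(i)),
             `4` = u32(i),
             `5` = u32(i) / u32(i + 4L),
             `11` = rd(i, 4L, what = "numeric"),
             `12` = rd(i, 8L, what = "numeric"),
             stop("unsupported TIFF field type ", type))
    }, numeric(1))
  }

  frames <- list(); desc <- NULL
  ifd_off <- u32(5L)
  while (ifd_off != 0) {
    base <- ifd_off + 1L  # raw[] is 1-based
    ne <- u16(base)
    tags <- list()
    for (e in seq_len(ne)) {
      eb <- base + 2L + (e - 1L) * 12L
      tag <- u16(eb); type <- u16(eb + 2L); count <- u32(eb + 4L)
      if (!as.character(type) %in% names(TIFF_TYPE_SIZES)) next
      tags[[as.character(tag)]] <- read_values(type, count, eb + 8L)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("malformed TIFF (missing tag ", tag, "): ",
                                   path, call. = FALSE)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 1L)[1]
    if (need(259L, 1L) != 1L) stop("unsupported TIFF compression in ", path, call. = FALSE)
    if (need(277L, 1L) != 1L) stop("only single-sample grayscale TIFF supported: ",
                                   path, call. = FALSE)
    fmt <- need(339L, 1L)
    offs <- need(273L); cnts <- need(279L)
    data <- unlist(lapply(seq_along(offs), function(s) {
      i0 <- offs[s] + 1L
      chunk <- raw[i0:(i0 + cnts[s] - 1L)]
      nval <- cnts[s] %/% (bits %/% 8L)
      if (fmt == 3L) {
        readBin(chunk, "numeric", n = nval, size = bits %/% 8L, endian = endian)
      } else if (bits == 32L) {
        v <- readBin(chunk, "integer", n = nval, size = 4L, endian = endian)
        ifelse(v < 0, v + 2^32, as.numeric(v))
      } else {
        as.numeric(readBin(chunk, "integer", n = nval, size = bits %/% 8L,
                           endian = endian, signed = FALSE))
      }
    }))
    if (length(data) != h * w) stop("malformed TIFF (pixel count mismatch): ",
                                    path, call. = FALSE)
    frames[[length(frames) + 1L]] <- matrix(data, nrow = h, byrow = TRUE)
    if (is.null(desc) && !is.null(tags[["270"]])) desc <- tags[["270"]]
    ifd_off <- u32(base + 2L + ne * 12L)
  }
  if (!length(frames)) stop("malformed TIFF (no pages): ", path, call. = FALSE)

  meta <- NULL
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  }
  if (is.null(meta) || is.null(meta$pixel_size_nm)) {
    warning("TIFF carries no acquisition metadata; applying defaults ",
            "(pixel_size_nm = 80, frame_interval_s = 0.1)", call. = FALSE)
    meta <- list(pixel_size_nm = 80, frame_interval_s = 0.1)
  }
  image_stack(frames,
              pixel_size_nm = meta$pixel_size_nm,
              frame_interval_s = meta$frame_interval_s)
}
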