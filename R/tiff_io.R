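## Minimal multi-page baseline TIFF I/O.
##
## The pre-installed R stack has no TIFF package, so the package carries its
## own reader/writer restricted to what AOSLO video interchange needs:
## little-endian, uncompressed, single-sample grayscale, 8 or 16 bits per
## pixel, one strip per page.  The writer emits exactly that layout; the
## reader additionally accepts multiple strips per page.  Round-trips are
## validated in the test suite against an independent TIFF implementation.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L)

#' Write an AOSLO video stack as a multi-page TIFF with JSON sidecar
#'
#' Each frame becomes one grayscale TIFF page (uncompressed, little-endian);
#' intensities in [0, 1] are scaled to the full integer range.  Acquisition
#' metadata (fps, field size, axial length, and any extras) go to a sidecar
#' JSON file next to the TIFF.
#'
#' @param stack a \code{video_stack}.
#' @param path output TIFF path; the sidecar is written to
#'   \code{sub("\\\\.tiff?$", ".json", path)} unless \code{meta_path} is given.
#' @param bits 8 or 16 bits per pixel.
#' @param meta_path optional explicit sidecar path.
#' @return invisibly, the TIFF path.
#' @export
write_video_tiff <- function(stack, path, bits = 16L, meta_path = NULL) {
  stopifnot(inherits(stack, "video_stack"), bits %in% c(8L, 16L))
  d <- dim(stack$frames)
  n <- d[1]; H <- d[2]; W <- d[3]
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  bytes_pp <- bits / 8
  frame_bytes <- H * W * bytes_pp
  data_start <- 8
  ifd_start <- data_start + n * frame_bytes
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  # pixel data, row-major
  for (f in seq_len(n)) {
    v <- as.integer(round(pmin(pmax(t(stack$frames[f, , ]), 0), 1) * maxval))
    writeBin(as.vector(v), con, size = bytes_pp, endian = "little")
  }
  # IFDs
  ifd_len <- 2 + 12 * length(TIFF_TAGS) + 4
  for (f in seq_len(n)) {
    entry <- function(tag, type, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(1L, con, size = 4, endian = "little")
      if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(as.integer(length(TIFF_TAGS)), con, size = 2, endian = "little")
    entry(256, 3, W)
    entry(257, 3, H)
    entry(258, 3, bits)
    entry(259, 3, 1)           # no compression
    entry(262, 3, 1)           # BlackIsZero
    entry(273, 4, data_start + (f - 1) * frame_bytes)
    entry(277, 3, 1)
    entry(278, 3, H)
    entry(279, 4, frame_bytes)
    nxt <- if (f < n) ifd_start + f * ifd_len else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  meta <- list(fps = stack$fps, field_deg = stack$field_deg,
               axial_length_mm = stack$axial_length_mm,
               px_per_deg = stack$px_per_deg, bits = bits)
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF video with JSON sidecar
#'
#' Supports uncompressed single-sample 8/16-bit little- or big-endian TIFFs
#' (the format written by [write_video_tiff()] and by common scientific
#' writers with compression disabled).
#'
#' @param path TIFF path.
#' @param meta_path sidecar JSON path; defaults to the TIFF path with a
#'   \code{.json} extension.  Required fields: \code{fps},
#'   \code{field_deg}, \code{axial_length_mm}.
#' @return a \code{video_stack} with intensities rescaled to [0, 1].
#' @export
read_video_tiff <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(meta_path)) stopf("sidecar metadata %s not found", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("not a TIFF file")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stopf("not a TIFF file")
  u <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = FALSE, endian = endian)
  u4 <- function(off, n = 1)  # 32-bit unsigned; values here fit in int
    readBin(raw[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
            signed = TRUE, endian = endian)
  if (u(2, 2) != 42L) stopf("bad TIFF magic")
  ifd <- u4(4)
  pages <- list()
  while (ifd != 0L) {
    n_ent <- u(ifd, 2)
    tags <- list()
    for (k in seq_len(n_ent)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- u(e, 2); type <- u(e + 2, 2); cnt <- u4(e + 4)
      val_off <- e + 8
      size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      vals <- if (cnt * size <= 4) {
        if (type == 3L) u(val_off, 2, cnt) else u4(val_off, cnt)
      } else {
        off <- u4(val_off)
        if (type == 3L) u(off, 2, cnt) else u4(off, cnt)
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1]] <- tags
    ifd <- u4(ifd + 2 + n_ent * 12)
  }
  if (!length(pages)) stopf("TIFF contains no pages")
  first <- pages[[1]]
  W <- first[["256"]]; H <- first[["257"]]
  bits <- first[["258"]][1]
  if (!(bits %in% c(8L, 16L))) stopf("unsupported bit depth %d", bits)
  comp <- if (is.null(first[["259"]])) 1L else first[["259"]]
  if (comp != 1L) stopf("compressed TIFF not supported")
  maxval <- 2^bits - 1
  frames <- array(0, dim = c(length(pages), H, W))
  for (f in seq_along(pages)) {
    tg <- pages[[f]]
    offs <- tg[["273"]]; cnts <- tg[["279"]]
    buf <- unlist(lapply(seq_along(offs), function(i)
      u(offs[i], bits / 8, cnts[i] / (bits / 8))))
    frames[f, , ] <- matrix(buf / maxval, H, W, byrow = TRUE)
  }
  structure(list(frames = frames, fps = meta$fps,
                 field_deg = as.numeric(meta$field_deg),
                 axial_length_mm = meta$axial_length_mm,
                 px_per_deg = if (is.null(meta$px_per_deg))
                   W / as.numeric(meta$field_deg)[2] else meta$px_per_deg),
            class = "video_stack")
}

#' Serialise / deserialise a 24-2 visual-field test as JSON
#'
#' The 54 pattern-deviation categories are stored in the fixed point order
#' of [vf_grid_242()].
#'
#' @param vf a \code{vf_test}.
#' @param path file path.
#' @return \code{read_vf_json} returns a \code{vf_test}.
#' @export
write_vf_json <- function(vf, path) {
  stopifnot(inherits(vf, "vf_test"))
  jsonlite::write_json(unclass(vf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vf_json
#' @export
read_vf_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pd_prob <- as.integer(x$pd_prob)
  structure(x, class = "vf_test")
}
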