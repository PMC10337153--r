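# TIFF I/O for volume stacks.
#
# Reading goes through tiff::readTIFF (handles baseline and LZW files,
# integer and IEEE-float samples, and exposes the ImageDescription tag).
# Writing uses a purpose-built minimal writer below: the installed writer
# cannot emit an ImageDescription tag (needed for ImageJ hyperstack
# dimension metadata) nor true IEEE-float samples, both of which this
# package requires. Output files are uncompressed, grayscale, multi-page,
# little-endian baseline TIFF.

#' Read a TIFF z-stack or hyperstack
#'
#' Reads a single- or multi-page grayscale TIFF into a [volume_stack()].
#' ImageJ hyperstack metadata (`channels`, `slices`, `frames` in the
#' ImageDescription tag) is honoured when present; pages are assumed to be
#' ordered channel-fastest, then z, then time (the ImageJ convention).
#' Without metadata a multi-page file is interpreted as a single-channel,
#' single-frame z-stack unless `axis_hint` says otherwise.
#'
#' @param path path to a TIFF file.
#' @param axis_hint optional named vector factorizing the page count when no
#'   hyperstack metadata is present, e.g. `c(z = 50, t = 2)`. Axes may be
#'   `z`, `c`, `t`; omitted axes default to 1. The product must equal the
#'   number of pages, otherwise an "ambiguous axes" error is raised (the
#'   reader never silently guesses a factorization).
#' @return A [volume_stack()] whose dtype reflects the file (8-bit, 16-bit
#'   integer, or 32-bit float samples).
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, axis_hint = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) {
      if (grepl("as.is", conditionMessage(e), fixed = TRUE)) {
        # float samples are returned unscaled, as.is only applies to integers
        tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
          error = function(e2) stop(sprintf("cannot read '%s': %s", path, conditionMessage(e2)), call. = FALSE))
      } else {
        stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)), call. = FALSE)
      }
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent page shapes in TIFF: ", paste(unique(shapes), collapse = ", "), call. = FALSE)
  }
  if (length(dim(pages[[1L]])) != 2L) {
    stop("only single-sample (grayscale) TIFF pages are supported", call. = FALSE)
  }
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])

  a <- attributes(pages[[1L]])
  bits <- a$bits.per.sample
  fmt <- if (is.null(a$sample.format)) "uint" else a$sample.format
  dtype <- if (bits == 8L && fmt != "float") "uint8"
  else if (bits == 16L && fmt != "float") "uint16"
  else if (bits == 32L && fmt == "float") "float"
  else stop(sprintf("unsupported sample layout: %d-bit %s", bits, fmt), call. = FALSE)

  meta <- parse_imagej_description(a$description)
  if (!is.null(meta)) {
    cc <- meta["channels"]; zz <- meta["slices"]; tt <- meta["frames"]
    if (cc * zz * tt != n) {
      stop(sprintf("hyperstack metadata declares %d pages but file has %d", cc * zz * tt, n), call. = FALSE)
    }
  } else if (!is.null(axis_hint)) {
    hint <- unlist(axis_hint)
    bad <- setdiff(names(hint), c("z", "c", "t"))
    if (length(bad)) stop("unknown axes in axis_hint: ", paste(bad, collapse = ", "), call. = FALSE)
    get <- function(ax) if (ax %in% names(hint)) as.integer(hint[[ax]]) else 1L
    cc <- get("c"); zz <- get("z"); tt <- get("t")
    if (cc * zz * tt != n) {
      stop(sprintf("ambiguous axes: hint (c=%d, z=%d, t=%d) does not factorize %d pages", cc, zz, tt, n), call. = FALSE)
    }
  } else {
    cc <- 1L; zz <- n; tt <- 1L
  }

  arr <- array(0, c(w, h, zz, cc, tt))
  for (p in seq_len(n)) {
    ci <- (p - 1L) %% cc + 1L
    zi <- ((p - 1L) %/% cc) %% zz + 1L
    ti <- (p - 1L) %/% (cc * zz) + 1L
    arr[, , zi, ci, ti] <- t(unclass(pages[[p]]))
  }
  volume_stack(arr, dtype = dtype)
}

#' Write a volume stack as a multi-page TIFF
#'
#' Writes one uncompressed grayscale page per (channel, z, frame) triple in
#' ImageJ order (channel fastest). Multi-channel or multi-frame stacks carry
#' ImageJ-style hyperstack metadata in the ImageDescription tag so they
#' round-trip through [read_stack()] and open correctly in ImageJ/FIJI.
#' `uint8`/`uint16` stacks are stored at their native bit depth; `float`
#' stacks as 32-bit IEEE float samples.
#'
#' @param volume a [volume_stack()].
#' @param path output path; the parent directory must exist and be writable.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "volume_stack"))
  dm <- stack_dims(volume)
  desc <- NULL
  if (dm["c"] > 1L || dm["t"] > 1L) {
    desc <- paste0(
      "ImageJ=1.53t\nimages=", dm["c"] * dm["d"] * dm["t"],
      "\nchannels=", dm["c"], "\nslices=", dm["d"], "\nframes=", dm["t"],
      "\nhyperstack=true\nmode=grayscale\n"
    )
  }
  pages <- vector("list", dm["c"] * dm["d"] * dm["t"])
  p <- 1L
  for (ti in seq_len(dm["t"])) {
    for (zi in seq_len(dm["d"])) {
      for (ci in seq_len(dm["c"])) {
        pg <- volume$data[, , zi, ci, ti]
        dim(pg) <- dm[1:2]
        pages[[p]] <- pg
        p <- p + 1L
      }
    }
  }
  write_tiff_pages(pages, path, dtype = volume$dtype, description = desc)
  invisible(path)
}

parse_imagej_description <- function(desc) {
  if (is.null(desc) || !grepl("ImageJ=", desc, fixed = TRUE)) return(NULL)
  get <- function(key, default = 1L) {
    m <- regmatches(desc, regexec(paste0(key, "=([0-9]+)"), desc))[[1L]]
    if (length(m) == 2L) as.integer(m[2L]) else default
  }
  c(channels = get("channels"), slices = get("slices"), frames = get("frames"))
}

# ---- minimal baseline TIFF writer (little-endian, uncompressed, gray) ----

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}
# one 12-byte IFD entry; value4 is the raw 4-byte value/offset field
ifd_entry <- function(tag, type, count, value4) {
  c(u16le(tag), u16le(type), u32le(count), value4)
}
short_val <- function(x) c(u16le(x), as.raw(c(0L, 0L)))

encode_page <- function(m, dtype) {
  v <- as.vector(m)  # x fastest within each y row, matching TIFF row-major
  switch(dtype,
    uint8 = as.raw(v),
    uint16 = {
      r <- raw(2L * length(v))
      r[seq(1L, length(r), 2L)] <- as.raw(v %% 256L)
      r[seq(2L, length(r), 2L)] <- as.raw(v %/% 256L)
      r
    },
    float = writeBin(as.double(v), raw(), size = 4L, endian = "little")
  )
}

write_tiff_pages <- function(pages, path, dtype, description = NULL) {
  w <- nrow(pages[[1L]]); h <- ncol(pages[[1L]])
  n <- length(pages)
  bps <- switch(dtype, uint8 = 8L, uint16 = 16L, float = 32L)
  sfmt <- if (dtype == "float") 3L else 1L
  page_bytes <- w * h * (bps %/% 8L)

  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  data_offsets <- 8 + (seq_len(n) - 1) * page_bytes
  desc_offset <- 8 + n * page_bytes
  ifd0_offset <- desc_offset + length(desc_raw)
  n_entries <- c(if (!is.null(desc_raw)) 11L else 10L, rep(10L, n - 1L))
  ifd_sizes <- 2L + 12L * n_entries + 4L
  ifd_offsets <- ifd0_offset + cumsum(c(0L, ifd_sizes[-n]))

  con <- tryCatch(file(path, "wb"),
    error = function(e) stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)), call. = FALSE),
    warning = function(e) stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)), call. = FALSE)
  )
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(ifd_offsets[1L])), con)
  for (p in seq_len(n)) writeBin(encode_page(pages[[p]], dtype), con)
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (p in seq_len(n)) {
    entries <- list(
      ifd_entry(256L, 4L, 1L, u32le(w)),           # ImageWidth
      ifd_entry(257L, 4L, 1L, u32le(h)),           # ImageLength
      ifd_entry(258L, 3L, 1L, short_val(bps)),     # BitsPerSample
      ifd_entry(259L, 3L, 1L, short_val(1L)),      # Compression: none
      ifd_entry(262L, 3L, 1L, short_val(1L))       # Photometric: black-is-zero
    )
    if (p == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(ifd_entry(270L, 2L, length(desc_raw), u32le(desc_offset))))
    }
    entries <- c(entries, list(
      ifd_entry(273L, 4L, 1L, u32le(data_offsets[p])),  # StripOffsets
      ifd_entry(277L, 3L, 1L, short_val(1L)),           # SamplesPerPixel
      ifd_entry(278L, 4L, 1L, u32le(h)),                # RowsPerStrip
      ifd_entry(279L, 4L, 1L, u32le(page_bytes)),       # StripByteCounts
      ifd_entry(339L, 3L, 1L, short_val(sfmt))          # SampleFormat
    ))
    next_off <- if (p < n) ifd_offsets[p + 1L] else 0L
    writeBin(c(u16le(length(entries)), unlist(entries), u32le(next_off)), con)
  }
  invisible(path)
}
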