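#' Read and write grayscale PGM images
#'
#' Minimal portable graymap support for the image-encoding pipeline: binary
#' (`P5`) and ASCII (`P2`) variants, 8-bit depth. Images are numeric matrices
#' of gray values 0-255, row-major with origin at the top-left, following the
#' format's convention.
#'
#' @param path File path.
#' @param image Numeric matrix with values in `[0, 255]`.
#' @param ascii Write the ASCII (`P2`) variant instead of binary `P5`?
#' @return `read_pgm()` returns a numeric matrix; `write_pgm()` returns
#'   `path` invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  }
  tokens <- character(0)
  # header: width, height, maxval; '#' comments allowed
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") {
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 %in% c("\n", "\r")) break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        c2raw <- readBin(con, "raw", 1L)
        c2 <- rawToChar(c2raw)
        if (!grepl("[0-9]", c2)) break
        tok <- paste0(tok, c2)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  matrix(vals * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  if (!is.matrix(image) || any(image < 0) || any(image > 255)) {
    stop("`image` must be a matrix with values in [0, 255]", call. = FALSE)
  }
  vals <- as.integer(round(t(image))) # row-major scan order
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
    write(vals, con, ncolumns = 16L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con,
              eos = NULL)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read or write a grayscale image as PNG
#'
#' Thin wrappers over the `png` package (values rescaled between the 0-255
#' gray convention used throughout this package and PNG's 0-1 range).
#'
#' @param path File path.
#' @param image Numeric matrix with values in `[0, 255]`.
#' @return `read_gray_png()` returns a numeric matrix of gray values 0-255.
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required to read PNG images", call. = FALSE)
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a * 255
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required to write PNG images", call. = FALSE)
  }
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read an IDX-format array (MNIST container format)
#'
#' Parses the big-endian IDX files in which the MNIST digit set is
#' distributed: magic `0x00000803` for image tensors and `0x00000801` for
#' label vectors. No data is downloaded; the user supplies the files.
#'
#' @param path Path to an uncompressed IDX file.
#' @return For image files, a numeric array `n x rows x cols` (gray values
#'   0-255); for label files, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (magic == 2051L) {
    dims <- readBin(con, "integer", 3L, size = 4L, endian = "big")
    vals <- readBin(con, "integer", prod(dims), size = 1L, signed = FALSE)
    aperm(array(vals, dim = rev(dims)), c(3L, 2L, 1L))
  } else if (magic == 2049L) {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "integer", n, size = 1L, signed = FALSE)
  } else {
    stop("unrecognized IDX magic number: ", magic, call. = FALSE)
  }
}

#' Write or read a spike volume as bit-packed binary plus JSON sidecar
#'
#' `H x W x T` binary spike tensors are large; on disk they are stored
#' bit-packed (8 spikes per byte) next to a small JSON sidecar recording
#' shape, pulse duration, mode, the thresholding current and the program
#' seed, so a volume is fully reconstructible.
#'
#' @param vol A [encode_image()] spike volume.
#' @param path Path for the binary payload; the sidecar is `<path>.json`.
#' @return `write_spike_volume()` returns `path` invisibly;
#'   `read_spike_volume()` returns a list with the logical spike array and
#'   the sidecar metadata.
#' @export
write_spike_volume <- function(vol, path) {
  stopifnot(inherits(vol, "spike_volume"))
  bits <- as.logical(vol$spikes)
  pad <- (-length(bits)) %% 8L
  writeBin(packBits(c(bits, rep(FALSE, pad))), path)
  meta <- list(
    version = as.character(utils::packageVersion("spikecoder")),
    shape = dim(vol$spikes), t_p = vol$t_p, mode = vol$mode,
    n_pulses = vol$n_pulses, n_trials = vol$n_trials,
    i_st = vol$i_st, seed = vol$program$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_volume
#' @export
read_spike_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  raw <- readBin(path, "raw", ceiling(n / 8))
  bits <- as.logical(rawToBits(raw))[seq_len(n)]
  list(spikes = array(bits, dim = meta$shape), meta = meta)
}
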