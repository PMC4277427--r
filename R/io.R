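# Grayscale image I/O (PGM P2/P5, PNG), the preprocessing chain
# (crop -> bilinear rescale -> histogram equalization), dataset manifests,
# and the versioned model container.

MODEL_FORMAT_VERSION <- 1L

# ---- images -----------------------------------------------------------------

# Tokenizer for PGM headers: whitespace-separated tokens, '#' comments run to
# end of line. Works on the raw bytes so P5 pixel data can follow directly.
pgm_header <- function(raw) {
  tokens <- character(0)
  i <- 1L; n <- length(raw)
  while (length(tokens) < 4L && i <= n) {
    b <- raw[i]
    if (b == charToRaw("#")) {
      while (i <= n && raw[i] != as.raw(10L)) i <- i + 1L
    } else if (b %in% as.raw(c(9L, 10L, 13L, 32L))) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(raw[j] %in% as.raw(c(9L, 10L, 13L, 32L, 35L)))) j <- j + 1L
      tokens <- c(tokens, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(tokens) < 4L) stop("corrupt PGM header")
  list(magic = tokens[1], width = as.integer(tokens[2]),
       height = as.integer(tokens[3]), maxval = as.integer(tokens[4]),
       data_at = i + 1L)  # P5 pixel data starts after one whitespace byte
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdr <- pgm_header(raw)
  if (any(is.na(c(hdr$width, hdr$height, hdr$maxval))) ||
      hdr$width < 1 || hdr$height < 1 || hdr$maxval < 1 || hdr$maxval > 255) {
    stop("corrupt PGM header")
  }
  n_px <- hdr$width * hdr$height
  if (hdr$magic == "P2") {
    txt <- rawToChar(raw[(hdr$data_at - 1L):length(raw)])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < n_px || anyNA(vals[seq_len(n_px)])) stop("corrupt P2 pixel data")
    vals <- vals[seq_len(n_px)]
  } else if (hdr$magic == "P5") {
    bytes <- raw[hdr$data_at:length(raw)]
    if (length(bytes) < n_px) stop("truncated P5 pixel data")
    vals <- as.integer(bytes[seq_len(n_px)])
  } else {
    stop(sprintf("unsupported PGM magic '%s'", hdr$magic))
  }
  # PGM stores row-major, top row first
  matrix(vals, hdr$height, hdr$width, byrow = TRUE) / hdr$maxval
}

quantize255 <- function(image) {
  v <- floor(pmin(pmax(image, 0), 1) * 255 + 0.5)  # round half up
  storage.mode(v) <- "integer"
  v
}

write_pgm <- function(image, path, ascii = FALSE) {
  q <- quantize255(image)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "255"), con)
    write(t(q), con, ncolumns = ncol(q))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(q), nrow(q)), con, eos = NULL)
    writeBin(as.raw(as.vector(t(q))), con)
  }
  invisible(path)
}

#' Read a grayscale image
#'
#' Supports 8-bit PGM (both the ASCII `P2` and binary `P5` dialects) and
#' grayscale PNG. Intensities are mapped to `[0, 1]` by dividing by the
#' maximum pixel value.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return A numeric H x W matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  magic <- readBin(path, "raw", 2L)
  if (identical(rawToChar(magic), "P2") || identical(rawToChar(magic), "P5")) {
    return(read_pgm(path))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      ch <- dim(a)[3]
      gray <- a[, , 1]
      for (k in seq_len(min(ch, 3L))[-1]) {
        if (max(abs(a[, , k] - gray)) > 1e-9) stop("color PNG not supported")
      }
      a <- gray
    }
    return(a)
  }
  stop(sprintf("unsupported image format: %s", path))
}

#' Write a grayscale image
#'
#' Quantizes to 8 bits with round-half-up and writes PGM (`.pgm`, binary P5
#' by default, ASCII P2 with `ascii = TRUE`) or grayscale PNG (`.png`).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Destination path; the extension selects the format.
#' @param ascii For PGM, write the ASCII `P2` dialect instead of binary `P5`.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, ascii = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(quantize255(image) / 255, path)
  } else {
    write_pgm(image, path, ascii = ascii)
  }
  invisible(path)
}

# ---- preprocessing ----------------------------------------------------------

# Textbook 256-bin histogram equalization on the 8-bit quantization of the
# image. A constant (single-bin) image is returned unchanged rather than
# dividing by zero.
hist_equalize <- function(image) {
  q <- quantize255(image)
  counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(q)
  cdf_min <- min(cdf[counts > 0])
  if (cdf_min == n) return(image)
  mapped <- (cdf - cdf_min) / (n - cdf_min)
  matrix(mapped[q + 1L], nrow(q), ncol(q))
}

#' Preprocess an image (crop, rescale, equalize)
#'
#' The class-independent preprocessing chain applied before training or
#' classification: optional crop to a [region()], bilinear rescale to the
#' target size, and optional 256-bin histogram equalization.
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param crop_box A [region()] inside the image, or `NULL` for no crop.
#' @param out_height,out_width Output dimensions; `NULL` keeps the
#'   (post-crop) size.
#' @param equalize Apply histogram equalization after rescaling.
#' @return The preprocessed image matrix.
#' @export
preprocess <- function(image, crop_box = NULL, out_height = NULL,
                       out_width = NULL, equalize = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.null(crop_box)) {
    stopifnot(inherits(crop_box, "canet_region"))
    if (crop_box$r1 > nrow(image) || crop_box$c1 > ncol(image)) {
      stop("crop box exceeds the image bounds")
    }
    image <- image[(crop_box$r0 + 1L):crop_box$r1,
                   (crop_box$c0 + 1L):crop_box$c1, drop = FALSE]
  }
  if (is.null(out_height)) out_height <- nrow(image)
  if (is.null(out_width)) out_width <- ncol(image)
  stopifnot(out_height >= 1, out_width >= 1)
  if (nrow(image) != out_height || ncol(image) != out_width) {
    # EBImage uses x = columns as the first dimension, hence the transposes
    img <- EBImage::Image(t(image))
    out <- EBImage::resize(img, w = out_width, h = out_height,
                           filter = "bilinear")
    image <- t(EBImage::imageData(out))
    image <- pmin(pmax(image, 0), 1)
  }
  if (equalize) image <- hist_equalize(image)
  image
}

# ---- manifests --------------------------------------------------------------

#' Read a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header `path,label,split` listing one image
#' per row; `split` must be `train` or `test`, paths must be unique and
#' labels non-empty. Validation errors name the offending line (header =
#' line 1).
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `path`, `label`, `split`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), c("path", "label", "split"))) {
    stop("manifest header must be exactly 'path,label,split'")
  }
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    if (!nzchar(df$path[i])) stop(sprintf("manifest line %d: empty path", line))
    if (!nzchar(df$label[i])) stop(sprintf("manifest line %d: empty label", line))
    if (!df$split[i] %in% c("train", "test")) {
      stop(sprintf("manifest line %d: unknown split tag '%s'", line, df$split[i]))
    }
    if (df$path[i] %in% df$path[seq_len(i - 1L)]) {
      stop(sprintf("manifest line %d: duplicate path '%s'", line, df$path[i]))
    }
  }
  df
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with columns `path`, `label`, `split`.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "label", "split") %in% names(manifest)))
  write.csv(manifest[, c("path", "label", "split")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- model container --------------------------------------------------------

# Doubles are stored as "%.17g" strings so that save/load round-trips are
# bitwise exact (plain JSON numbers lose the last bits).
num_out <- function(x) sprintf("%.17g", x)
num_in <- function(s) as.numeric(s)

#' Save a CANet model
#'
#' Writes a single-file, versioned JSON container holding the dimensions,
#' inhibition configuration, hidden-neuron table, input weights (stored
#' column-major), retained-output mask and training metadata (including the
#' initialization seed). Floating-point values are encoded so that
#' [load_model()] reproduces the model bitwise.
#'
#' @param model A `canet_model`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "canet_model"))
  hid <- model$hidden
  obj <- list(
    format = "canet-model",
    version = MODEL_FORMAT_VERSION,
    height = model$height, width = model$width,
    activation = model$activation,
    inhibition = list(I = model$inhibition$I, A = num_out(model$inhibition$A),
                      enabled = model$inhibition$enabled),
    hidden = list(id = hid$id, r0 = hid$r0, c0 = hid$c0, r1 = hid$r1,
                  c1 = hid$c1, parent_r = hid$parent_r, parent_c = hid$parent_c,
                  out_weight = num_out(hid$out_weight),
                  bias = num_out(hid$bias), frozen = hid$frozen),
    input_weights = num_out(as.vector(model$input_weights)),
    retained_mask = as.integer(as.vector(model$retained_mask)),
    meta = model$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Load a CANet model
#'
#' @param path Path to a file written by [save_model()].
#' @return The reconstructed `canet_model`, bitwise identical to the saved
#'   one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop(sprintf("truncated or invalid model file: %s",
                                                   conditionMessage(e))))
  if (!identical(obj$format, "canet-model")) stop("not a CANet model container")
  if (!identical(as.integer(obj$version), MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model container version %s (this build reads version %d)",
                 obj$version, MODEL_FORMAT_VERSION))
  }
  H <- as.integer(obj$height); W <- as.integer(obj$width)
  hid <- obj$hidden
  model <- structure(list(
    height = H, width = W,
    input_weights = matrix(num_in(obj$input_weights), H, W),
    hidden = data.frame(
      id = as.integer(hid$id), r0 = as.integer(hid$r0), c0 = as.integer(hid$c0),
      r1 = as.integer(hid$r1), c1 = as.integer(hid$c1),
      parent_r = as.integer(hid$parent_r), parent_c = as.integer(hid$parent_c),
      out_weight = num_in(hid$out_weight), bias = num_in(hid$bias),
      frozen = as.logical(hid$frozen)
    ),
    inhibition = inhibition_config(I = as.integer(obj$inhibition$I),
                                   A = num_in(obj$inhibition$A),
                                   enabled = as.logical(obj$inhibition$enabled)),
    retained_mask = matrix(as.logical(obj$retained_mask), H, W),
    activation = obj$activation,
    meta = as.list(obj$meta)
  ), class = "canet_model")
  model
}
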