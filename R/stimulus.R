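# Luminance/contrast equalization of grayscale stimuli (affine
# matching of pixel mean and SD, with post-hoc clipping to [0, 255]).

#' Match a grayscale image's mean luminance and contrast
#'
#' Applies the affine map
#' `clip(target_mean + (pixels - mean) * target_sd / sd, 0, 255)`
#' so that, when no clipping occurs, the output has exactly the target
#' mean pixel intensity and target SD (contrast). When values are
#' clipped the achieved moments can deviate slightly; [match_set()]
#' reports them. SD is the sample standard deviation over all pixels.
#'
#' @param image numeric matrix of pixel intensities in [0, 255].
#' @param target_mean target mean pixel intensity (default 128).
#' @param target_sd target pixel-intensity SD (default 40).
#' @return Matched image (same dimensions). A constant (zero-variance)
#'   image cannot attain a positive contrast: it is returned as a
#'   constant image at `target_mean` with a warning.
#' @examples
#' img <- matrix(runif(64 * 64, 90, 160), 64)
#' out <- lum_match(img)
#' c(mean(out), sd(out))
#' @export
lum_match <- function(image, target_mean = 128, target_sd = 40) {
  stopifnot(is.numeric(image), length(image) > 0, target_sd >= 0)
  if (any(is.na(image)) || min(image) < 0 || max(image) > 255)
    stop("image must contain values in [0, 255] with no missing entries")
  s <- stats::sd(image)
  if (s == 0 || is.na(s)) {
    if (target_sd > 0)
      warning("input image has zero variance; target contrast is ",
              "unattainable, returning a constant image at target_mean")
    out <- image
    out[] <- target_mean
    return(out)
  }
  out <- target_mean + (image - mean(image)) * (target_sd / s)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Match a set of stimulus images
#'
#' Applies [lum_match()] to every image and attaches a per-image report
#' of the achieved mean and SD (attribute `"report"`), which differ
#' from the targets only when clipping occurred.
#'
#' @param images non-empty (optionally named) list of numeric matrices.
#' @inheritParams lum_match
#' @return List of matched images; `attr(, "report")` is a data frame
#'   with columns `id`, `mean`, `sd`, `clipped` (fraction of clipped
#'   pixels).
#' @export
match_set <- function(images, target_mean = 128, target_sd = 40) {
  if (!is.list(images) || length(images) == 0)
    stop("images must be a non-empty list of matrices")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(images))
  out <- lapply(images, lum_match,
                target_mean = target_mean, target_sd = target_sd)
  report <- data.frame(
    id = ids,
    mean = vapply(out, mean, numeric(1)),
    sd = vapply(out, stats::sd, numeric(1)),
    clipped = vapply(out, function(m) mean(m <= 0 | m >= 255), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "report") <- report
  out
}

#' Generate a synthetic stimulus set
#'
#' Builds the 27 grayscale images of a saccadic-choice stimulus set (3
#' categories x 3 identities x 3 orientations) as smooth random
#' textures: low-frequency cosine gratings whose phases/frequencies
#' depend on identity and orientation, plus pixel noise. These are
#' stand-ins with the same ID structure and intensity statistics as
#' photographic stimuli, intended for exercising [match_set()] and the
#' simulation pipeline.
#'
#' @param size image side length in px.
#' @param seed integer seed.
#' @return Named list of 27 matrices with values in [0, 255].
#' @export
synthetic_stimulus_set <- function(size = 64, seed = 1) {
  set.seed(as.integer(seed))
  ids <- unlist(lapply(SACC_CATEGORIES, image_ids))
  g <- seq(0, 2 * pi, length.out = size)
  out <- lapply(seq_along(ids), function(i) {
    fx <- sample(1:4, 1); fy <- sample(1:4, 1)
    ph <- stats::runif(2, 0, 2 * pi)
    base <- outer(cos(fx * g + ph[1]), cos(fy * g + ph[2]))
    img <- 120 + 45 * base + matrix(stats::rnorm(size^2, 0, 12), size)
    img[img < 0] <- 0; img[img > 255] <- 255
    img
  })
  names(out) <- ids
  out
}

#' Read a grayscale image (PNG or PGM)
#'
#' PNG files are read with the \pkg{png} package; colour images are
#' converted to grayscale by the Rec.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B). PGM supports the plain (P2) and
#' binary (P5, 8-bit) variants.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return Numeric matrix with intensities in [0, 255].
#' @export
read_stimulus <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      ch <- dim(a)[3]
      a <- if (ch >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
           else a[, , 1]
    }
    return(a * 255)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext)
}

#' Write a grayscale image (PNG or PGM)
#'
#' @param image numeric matrix in [0, 255].
#' @param path destination ending in `.png` or `.pgm` (plain P2).
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  header <- integer(0)
  while (length(header) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    header <- c(header, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
  }
  w <- header[1]; h <- header[2]; maxval <- header[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    if (maxval > 255) stop("16-bit PGM not supported")
    vals <- as.integer(readBin(con, "raw", n = w * h))
  }
  matrix(vals * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path) {
  vals <- as.integer(round(pmin(pmax(image, 0), 255)))
  m <- matrix(vals, nrow = nrow(image))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(m, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
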