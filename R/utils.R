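#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed}, so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the stream alone.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quantize an intensity matrix to 8-bit storage values
#'
#' @param x numeric matrix on the 0--255 scale.
#' @return matrix of integers 0..255 (stored as doubles).
#' @export
quantize8 <- function(x) {
  round(clamp(x, 0, 255))
}

#' Rescale a real-valued image to the full 0--255 range and quantize
#'
#' Used at storage boundaries after background subtraction, mirroring the
#' usual 8-bit TIFF export of corrected micrographs.
#' @param x numeric matrix.
#' @return matrix of integers 0..255.
#' @export
rescale8 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(matrix(0, nrow(x), ncol(x)))
  quantize8((x - rng[1]) / diff(rng) * 255)
}

#' Write / read an 8-bit grayscale image (TIFF or PNG by extension)
#'
#' Images are matrices on the 0--255 scale; files store them as 8-bit
#' grayscale. 16-bit TIFF is used for integer label images.
#' @param x matrix (0--255 for \code{bits = 8}, 0--65535 for \code{bits = 16}).
#' @param path output file, extension .tif/.tiff or .png.
#' @param bits 8 or 16.
#' @export
write_gray <- function(x, path, bits = 8) {
  maxv <- 2^bits - 1
  img <- clamp(round(x), 0, maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bits)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_gray
#' @export
read_gray <- function(path, bits = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * (2^bits - 1))
}

# matrix <-> EBImage helpers; EBImage uses x = columns convention, so the
# matrix is transposed going in and out.
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

stopifnot_named <- function(x, what) {
  if (!all(what %in% names(x)))
    stop("missing fields: ", paste(setdiff(what, names(x)), collapse = ", "))
}
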