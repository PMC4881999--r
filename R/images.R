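#' Convert an image to a grayscale intensity matrix
#'
#' Accepts a numeric matrix (already grayscale) or a 3-d array with the
#' third dimension holding R, G, B channels. Colour images are converted
#' with the standard luma weights 0.299, 0.587, 0.114. Intensities are
#' expected in \[0, 1\].
#'
#' @param img numeric matrix or height x width x 3 array in \[0, 1\].
#' @return numeric matrix of intensities in \[0, 1\].
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) {
    gray <- img
  } else if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      gray <- img[, , 1]
    } else {
      gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
  } else {
    stop("img must be a matrix or a 3-d array", call. = FALSE)
  }
  if (!all(is.finite(gray))) stop("image contains non-finite values", call. = FALSE)
  if (min(gray) < -1e-9 || max(gray) > 1 + 1e-9) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(gray, 0), 1)
}

#' Read an image file as a normalized array
#'
#' Reads PNG, TIFF or JPEG and returns intensities normalized to \[0, 1\],
#' as a matrix (grayscale) or height x width x channels array (colour).
#'
#' @param path file path.
#' @return numeric matrix or array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)
  # EBImage stores x (column) as the first index; transpose to row = y
  if (length(dim(dat)) == 2L) {
    out <- t(dat)
  } else {
    out <- aperm(dat, c(2L, 1L, 3L))
  }
  pmin(pmax(out, 0), 1)
}

#' Write an image matrix or array to file
#'
#' @param img numeric matrix (grayscale) or height x width x 3 array in \[0, 1\].
#' @param path output path; format from the extension (png, tiff, jpeg).
#' @param bits bit depth for PNG/TIFF output (8 or 16).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  dat <- if (is.matrix(img)) t(img) else aperm(img, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(pmin(pmax(dat, 0), 1),
                                     colormode = if (is.matrix(img)) "Grayscale" else "Color"),
                      path, bits.per.sample = bits)
  invisible(path)
}

#' Complex image gradient field
#'
#' Computes per-pixel intensity gradients of a grayscale image and stores
#' them as complex numbers dx + i*dy, where x is the column direction and
#' y the row direction (origin top-left, y increasing downward). Central
#' differences are used in the interior and one-sided differences at the
#' borders.
#'
#' @param image numeric matrix of intensities in \[0, 1\], at least 3 x 3.
#' @return complex matrix of the same dimensions.
#' @export
compute_gradient_field <- function(image) {
  image <- as_gray(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("image must be at least 3 x 3", call. = FALSE)
  dx <- matrix(0, nr, nc)
  dy <- matrix(0, nr, nc)
  dx[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  dx[, 1] <- image[, 2] - image[, 1]
  dx[, nc] <- image[, nc] - image[, nc - 1]
  dy[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  dy[1, ] <- image[2, ] - image[1, ]
  dy[nr, ] <- image[nr, ] - image[nr - 1, ]
  matrix(complex(real = dx, imaginary = dy), nr, nc)
}
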