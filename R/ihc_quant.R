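#' Immunohistochemistry stain quantification by color deconvolution
#'
#' Stains absorb light multiplicatively, so they add linearly in optical
#' density (OD = -log10 of transmitted/incident intensity). An RGB image is
#' converted channel-wise to OD and unmixed by solving, per pixel,
#' `OD = densities %*% S` for a 3x3 matrix `S` of unit-norm stain OD
#' vectors. The mean density of the target stain (e.g. DAB) over
#' tissue-masked pixels quantifies antibody staining per image.
#'
#' @name ihc-quant
NULL

#' Stain matrix constructor
#'
#' Rows are OD vectors (R, G, B) of stain 1, stain 2, and a residual
#' channel; rows are normalized to unit length. When only two stains are
#' given, the residual row is their normalized cross product.
#'
#' @param stain1,stain2 length-3 OD vectors
#' @param residual optional length-3 OD vector for the third channel
#' @param names row names (stain labels)
#' @return 3x3 `stain_matrix` with unit-norm rows
#' @export
stain_matrix <- function(stain1, stain2, residual = NULL,
                         names = c("stain1", "stain2", "residual")) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("zero-length stain vector", call. = FALSE)
    v / n
  }
  s1 <- unit(stain1); s2 <- unit(stain2)
  if (is.null(residual)) {
    residual <- c(s1[2] * s2[3] - s1[3] * s2[2],
                  s1[3] * s2[1] - s1[1] * s2[3],
                  s1[1] * s2[2] - s1[2] * s2[1])
    if (sqrt(sum(residual^2)) < 1e-8) {
      stop("stain matrix is singular (collinear stain vectors)",
           call. = FALSE)
    }
  }
  S <- rbind(s1, s2, unit(residual))
  rownames(S) <- names
  colnames(S) <- c("R", "G", "B")
  if (abs(det(S)) < 1e-8) {
    stop("stain matrix is singular (collinear stain vectors)", call. = FALSE)
  }
  structure(S, class = c("stain_matrix", "matrix", "array"))
}

#' Default hematoxylin + DAB stain matrix
#'
#' The published optical-density vectors for hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.268, 0.570, 0.776), with the residual
#' channel as their normalized cross product. Override by constructing a
#' [stain_matrix()] from measured vectors.
#'
#' @return a `stain_matrix` with rows hematoxylin, DAB, residual
#' @export
default_stain_matrix <- function() {
  stain_matrix(c(0.650, 0.704, 0.286), c(0.268, 0.570, 0.776),
               names = c("hematoxylin", "DAB", "residual"))
}

check_rgb <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop("expected 8-bit intensities in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

#' Convert an 8-bit RGB image to optical density
#'
#' Per channel `OD = max(0, -log10((I + 1) / 255))`; the +1 avoids log(0)
#' at black pixels and the clip keeps white pixels at exactly zero density.
#'
#' @param img H x W x 3 array of intensities in \[0, 255\]
#' @return H x W x 3 array of optical densities (>= 0)
#' @export
rgb_to_od <- function(img) {
  check_rgb(img)
  od <- -log10((img + 1) / 255)
  od[od < 0] <- 0
  od
}

#' Convert optical density back to 8-bit intensity
#'
#' Inverse of [rgb_to_od()] up to the clip: `I = 255 * 10^-OD - 1`.
#'
#' @param od array of optical densities
#' @return array of intensities in \[0, 255\]
#' @export
od_to_rgb <- function(od) {
  x <- 255 * 10^(-od) - 1
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Unmix an OD image into per-stain density maps
#'
#' Solves `OD = densities %*% S` per pixel. Negative densities (noise
#' pushing a pixel outside the stain simplex) are clipped to 0 and the
#' clipped fraction is reported.
#'
#' @param od H x W x 3 OD array (from [rgb_to_od()])
#' @param stains a [stain_matrix()]
#' @return list with `density` (H x W x 3 array, stains in the third
#'   dimension, named by stain) and `fraction_clipped`
#' @export
color_deconvolve <- function(od, stains = default_stain_matrix()) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("expected an H x W x 3 OD array", call. = FALSE)
  }
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)            # pixels x 3
  dens <- flat %*% solve(stains)           # pixels x 3 stain densities
  clipped <- mean(dens < -1e-12)
  dens[dens < 0] <- 0
  out <- array(dens, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  list(density = out, fraction_clipped = clipped)
}

#' Tissue mask from total optical density
#'
#' Background glass transmits nearly all light; pixels whose total OD
#' (sum over channels) exceeds `threshold` are considered tissue.
#'
#' @param od H x W x 3 OD array
#' @param threshold total-OD cutoff (default 0.15)
#' @return H x W logical matrix
#' @export
tissue_mask <- function(od, threshold = 0.15) {
  apply(od, c(1, 2), sum) > threshold
}

#' Mean stain intensity over a mask
#'
#' @param density H x W density map of the target stain (one slice of the
#'   [color_deconvolve()] output)
#' @param mask H x W logical tissue mask (default: all pixels)
#' @return a `stain_quant` list: `mean_density`, `n_pixels`, `mask_fraction`
#' @export
mean_stain_intensity <- function(density, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(density), ncol(density))
  if (!any(mask)) stop("empty tissue mask", call. = FALSE)
  structure(list(mean_density = mean(density[mask]),
                 n_pixels = sum(mask),
                 mask_fraction = mean(mask)),
            class = "stain_quant")
}

#' @export
print.stain_quant <- function(x, ...) {
  cat("stain_quant: mean density ", round(x$mean_density, 4), " over ",
      x$n_pixels, " pixels\n", sep = "")
  invisible(x)
}

#' Read an 8-bit RGB PNG image
#' @param path PNG file path
#' @return H x W x 3 array of intensities in \[0, 255\]
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]    # drop alpha
  }
  check_rgb(img * 255)
}

#' Write an RGB array to PNG
#' @param img H x W x 3 array of intensities in \[0, 255\]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rgb_png <- function(img, path) {
  check_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
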