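#' Binarize a punctate fluorescence micrograph
#'
#' Foreground = pixels strictly above a threshold. The default threshold is
#' Otsu's between-class-variance criterion (via EBImage); a fixed value can
#' be supplied instead. A uniform image yields an empty foreground with a
#' warning.
#'
#' @param img Numeric matrix of intensities in [0, 1] (single channel).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"`.
#' @return Logical matrix of the same shape.
#' @export
binarize_image <- function(img, method = c("otsu", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  img <- as.matrix(img)
  if (length(img) == 0L) stop("image is empty")
  if (diff(range(img)) == 0) {
    warning("uniform image: empty foreground")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  thr <- if (method == "fixed") {
    stopifnot_scalar(threshold, "threshold")
  } else {
    EBImage::otsu(img, range = range(img))
  }
  img > thr
}

#' Label connected components (8-connectivity)
#'
#' Breadth-first labelling of the foreground, with diagonally touching
#' pixels in the same component, matching the binarize-then-count puncta
#' procedure (touching puncta count once).
#'
#' @param fg Logical matrix (foreground mask).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(fg) {
  fg <- as.matrix(fg)
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  drs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dcs <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  for (seed in which(fg)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    stack <- seed
    lab[seed] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- r + drs[k]; c2 <- cc + dcs[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (fg[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Puncta density within a region mask
#'
#' Counts 8-connected foreground components that intersect the region mask
#' and whose pixel area lies within a size gate derived from the expected
#' punctum radius, then divides by the mask area in square micrometres.
#'
#' @param fg Logical foreground matrix (from [binarize_image()]).
#' @param mask Logical region mask, same shape, nonempty.
#' @param pixel_size Pixel edge length in micrometres.
#' @param punctum_radius Expected punctum radius in pixels; sets the size
#'   gate `[max(2, 0.2*pi*r^2), 6*pi*r^2]` that rejects single-pixel noise
#'   and merged blobs. `NULL` disables gating.
#' @param region Optional region label carried through.
#' @return List of class `"density_result"`: `puncta_count`,
#'   `region_area_um2`, `density` (count / um^2), `region`.
#' @export
puncta_density <- function(fg, mask, pixel_size = 0.1,
                           punctum_radius = NULL, region = NA_character_) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("region mask is empty")
  if (!all(dim(mask) == dim(fg))) stop("mask and image shapes differ")
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  lab <- label_components(fg)
  ids <- setdiff(unique(lab[mask]), 0L)
  if (length(ids) && !is.null(punctum_radius)) {
    area_px <- tabulate(lab, nbins = max(lab))
    gate <- c(max(2, 0.2 * pi * punctum_radius^2),
              6 * pi * punctum_radius^2)
    ids <- ids[area_px[ids] >= gate[1] & area_px[ids] <= gate[2]]
  }
  area_um2 <- sum(mask) * pixel_size^2
  structure(list(puncta_count = length(ids), region_area_um2 = area_um2,
                 density = length(ids) / area_um2, region = region),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %s: %d puncta / %.0f um^2 = %.5f /um^2\n",
              x$region, x$puncta_count, x$region_area_um2, x$density))
  invisible(x)
}

#' Normalize a target-region density by a reference region
#'
#' Ratio of the target density to the reference density (e.g. SNc puncta
#' density divided by the density in the intermediate layer of the lateral
#' SC of the same animal). Units cancel, so the result is independent of
#' `pixel_size`. A zero reference density leaves the ratio undefined
#' (`NA`), never 0.
#'
#' @param target,reference `"density_result"` objects.
#' @return Unitless normalized density, or `NA_real_`.
#' @export
normalize_density <- function(target, reference) {
  if (reference$density <= 0) return(NA_real_)
  target$density / reference$density
}

#' Foreground area fraction within a mask
#'
#' Alternative density readout (area mode): the fraction of mask pixels
#' that are foreground.
#'
#' @inheritParams puncta_density
#' @return Numeric fraction in [0, 1].
#' @export
area_fraction <- function(fg, mask) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("region mask is empty")
  mean(fg[mask])
}
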