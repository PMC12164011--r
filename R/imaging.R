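#' Select the most focused slice of a z-stack
#'
#' Picks, from a 7-slice fluorescence z-stack, the slice with the highest
#' total pixel intensity; ties break toward the lowest index. This is the
#' focus criterion used for all downstream per-cell quantification.
#'
#' @param stack Numeric array `H x W x 7` of pixel intensities.
#' @return 1-based slice index.
#' @export
select_focused_slice <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be an H x W x n_slices array", call. = FALSE)
  }
  if (dim(stack)[3] != 7L) {
    stop("stack must have exactly 7 z slices", call. = FALSE)
  }
  sums <- apply(stack, 3, sum)
  which.max(sums)  # which.max returns the first (lowest) index on ties
}

#' Subtract a smooth background from a fluorescence image
#'
#' Estimates the smooth background of a 2-D image by grayscale
#' morphological opening with a disc structuring element and subtracts it,
#' flooring at zero. Bright structures smaller than the disc (fluorescent
#' cells, foci) are preserved; slowly varying background is removed.
#'
#' @param image Numeric matrix.
#' @param radius_px Disc radius in pixels (>= 1); the structuring element
#'   is a disc of diameter `2 * radius_px + 1`.
#' @return Background-subtracted matrix, same dimensions, all values
#'   `>= 0`.
#' @export
subtract_background <- function(image, radius_px = 5) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix", call. = FALSE)
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  scale <- max(image, 1)  # EBImage expects intensities in [0, 1]
  bg <- EBImage::opening(EBImage::Image(image / scale), brush)
  out <- image - as.matrix(bg) * scale
  out[out < 0] <- 0
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    di <- dd[1]; dj <- dd[2]
    ii <- seq_len(H - 1L)
    jj <- if (dj > 0) seq_len(W - 1L) else 2L:W
    a <- lab[ii, jj, drop = FALSE]
    b <- lab[ii + di, jj + dj, drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment fluorescent particles and measure integrated density
#'
#' Thresholds a background-subtracted image (Otsu by default), labels
#' 8-connected components, discards components below a minimum area, and
#' reports each particle's area, raw integrated density (sum of pixel
#' intensities over the particle on the input image), and centroid.
#'
#' @param image Background-subtracted numeric matrix.
#' @param threshold Either `"otsu"` or a numeric intensity cutoff.
#' @param min_area_px Minimum particle area in pixels (default 4).
#' @return Data frame with columns `particle`, `area`,
#'   `raw_integrated_density`, `centroid_row`, `centroid_col`; zero rows
#'   for a blank image.
#' @export
segment_particles <- function(image, threshold = "otsu", min_area_px = 4) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix", call. = FALSE)
  empty <- data.frame(particle = integer(0), area = integer(0),
                      raw_integrated_density = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (all(image <= 0)) return(empty)
  if (identical(threshold, "otsu")) {
    scale <- max(image)
    cutoff <- EBImage::otsu(EBImage::Image(image / scale),
                            range = c(0, 1)) * scale
  } else {
    cutoff <- as.numeric(threshold)
  }
  mask <- image > cutoff
  if (!any(mask)) return(empty)
  lab <- label8(mask)
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_area_px) return(NULL)
    data.frame(particle = id, area = nrow(px),
               raw_integrated_density = sum(image[px]),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$particle <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean raw integrated density of a sample
#'
#' The per-sample fluorescence summary: arithmetic mean of the raw
#' integrated density over all segmented particles.
#'
#' @param particles A [segment_particles()] table.
#' @return Mean raw integrated density; `NA` with a warning when the
#'   sample has no particles.
#' @export
sample_mean_intensity <- function(particles) {
  if (nrow(particles) == 0L) {
    warning("sample has no particles; mean intensity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(particles$raw_integrated_density)
}

#' Relative fluorescence intensity
#'
#' Rescales a sample's mean fluorescence intensity between the
#' negative-control population mean (no DSB, no roadblock; maps to 0) and
#' the DSB-reference population mean (DSB, no roadblock near the break;
#' maps to 1):
#'
#' \deqn{\mathrm{relative\ I} = \frac{I - \bar I_{NC}}
#'   {\bar I_{DSB} - \bar I_{NC}}}
#'
#' The statistic is invariant to affine rescaling of all intensities.
#'
#' @param I Sample mean fluorescence intensity.
#' @param mean_nc Mean intensity of the negative-control population.
#' @param mean_dsb Mean intensity of the DSB-reference population.
#' @return Dimensionless relative intensity.
#' @export
relative_intensity <- function(I, mean_nc, mean_dsb) {
  if (!is.finite(mean_dsb) || !is.finite(mean_nc) || mean_dsb == mean_nc) {
    stop("relative intensity undefined when reference means coincide",
         call. = FALSE)
  }
  (I - mean_nc) / (mean_dsb - mean_nc)
}

#' Quantify one z-stack end to end
#'
#' Convenience wrapper chaining the stated imaging workflow: pick the most
#' focused of the 7 slices, subtract the smooth background, segment
#' particles, and return the particle table together with the sample mean
#' intensity.
#'
#' @param stack `H x W x 7` array.
#' @param radius_px Background disc radius (default 5).
#' @param threshold,min_area_px Passed to [segment_particles()].
#' @return List with `slice` (chosen index), `particles`, and
#'   `mean_intensity`.
#' @export
quantify_stack <- function(stack, radius_px = 5, threshold = "otsu",
                           min_area_px = 4) {
  k <- select_focused_slice(stack)
  img <- subtract_background(stack[, , k], radius_px = radius_px)
  particles <- segment_particles(img, threshold = threshold,
                                 min_area_px = min_area_px)
  list(slice = k, particles = particles,
       mean_intensity = sample_mean_intensity(particles))
}
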