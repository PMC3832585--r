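# Otsu threshold on a numeric matrix (EBImage works on [0,1] grey levels)
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  th * diff(rng) + rng[1]
}

#' Estimate and subtract the average background level
#'
#' The background level is the mean of the non-object pixels, i.e. of all
#' pixels below an automatic global (Otsu) threshold; corrected intensities
#' are clipped at zero. A constant image is all background.
#'
#' @param image numeric matrix of pixel intensities (counts).
#' @param threshold optional threshold overriding the automatic one; pixels
#'   strictly below it are treated as background.
#' @return list with `image` (corrected matrix) and `background` (the
#'   estimated level).
#' @export
subtract_background <- function(image, threshold = NULL) {
  if (!is.matrix(image) || length(image) == 0L || !is.numeric(image))
    stop("subtract_background(): 'image' must be a non-empty numeric matrix", call. = FALSE)
  if (diff(range(image)) == 0)
    return(list(image = array(0, dim(image)), background = image[1]))
  th <- if (is.null(threshold)) otsu_threshold(image) else threshold
  bgpix <- image < th
  if (!any(bgpix))
    stop("subtract_background(): no background pixels below the threshold (saturated image?)",
         call. = FALSE)
  bg <- mean(image[bgpix])
  list(image = pmax(image - bg, 0), background = bg)
}

# binary mask of the background-corrected marker image
marker_mask <- function(corrected, threshold = NULL) {
  if (max(corrected) == 0) return(array(FALSE, dim(corrected)))
  th <- if (is.null(threshold)) otsu_threshold(corrected) else threshold
  corrected > th
}

#' Morphometric totals of one microscopic field
#'
#' Implements the field-level measurement concept of the screen: the
#' neuronal-marker image is background-corrected, thresholded and binarized;
#' the mask is partitioned into cell bodies (thick, compact objects retained
#' by a morphological opening at the soma scale) and neurites (the thin
#' remainder); total neurite length is the weighted skeleton length of the
#' neurite mask, total cell-body area the pixel count of the body mask, and
#' marker/reporter intensities are integrated after background correction.
#'
#' @param marker numeric matrix, neuronal marker channel (e.g. beta-III
#'   tubulin).
#' @param reporter numeric matrix, transfection-reporter channel (e.g. EGFP);
#'   must have the same shape as `marker`.
#' @param soma_radius radius (pixels) of the disc structuring element that
#'   separates cell bodies from neurites.
#' @param threshold optional fixed threshold (counts above background) for
#'   the marker mask, overriding the automatic Otsu choice.
#' @return one-row data.frame with `neurite_length` (px),
#'   `cell_body_area` (px), `marker_intensity` and `reporter_intensity`
#'   (background-corrected counts).
#' @export
measure_field <- function(marker, reporter, soma_radius = 6, threshold = NULL) {
  if (!identical(dim(marker), dim(reporter)))
    stop("measure_field(): marker and reporter images have different shapes", call. = FALSE)
  mk <- subtract_background(marker)
  rp <- subtract_background(reporter)
  mask <- marker_mask(mk$image, threshold)
  if (!any(mask)) {
    return(data.frame(neurite_length = 0, cell_body_area = 0,
                      marker_intensity = 0, reporter_intensity = 0))
  }
  brush <- EBImage::makeBrush(2L * as.integer(soma_radius) + 1L, shape = "disc")
  body <- EBImage::opening(mask * 1, brush) > 0.5
  neurite <- mask & !body
  skel <- thin_mask(neurite)
  data.frame(neurite_length = skeleton_length(skel),
             cell_body_area = sum(body),
             marker_intensity = sum(mk$image),
             reporter_intensity = sum(rp$image))
}

#' Mean signal intensity within the neuronal-marker mask
#'
#' Builds a mask by thresholding and binarizing the (background-corrected)
#' marker image, applies it to the signal image of interest, and returns the
#' arithmetic mean of the signal pixels inside the mask.
#'
#' @param signal numeric matrix, fluorescence channel of interest.
#' @param marker numeric matrix, neuronal marker channel (same shape).
#' @param threshold optional fixed mask threshold (counts above background).
#' @return mean signal intensity within the mask (scalar).
#' @export
masked_mean_intensity <- function(signal, marker, threshold = NULL) {
  if (!identical(dim(signal), dim(marker)))
    stop("masked_mean_intensity(): signal and marker images have different shapes",
         call. = FALSE)
  mk <- subtract_background(marker)
  mask <- marker_mask(mk$image, threshold)
  if (!any(mask))
    stop("masked_mean_intensity(): marker mask is empty", call. = FALSE)
  mean(signal[mask])
}

# zero-padded matrix shift; dr/dc > 0 moves content down/right
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- array(0L, dim(m))
  rs <- seq_len(nr - abs(dr)); cs <- seq_len(nc - abs(dc))
  out[rs + max(dr, 0), cs + max(dc, 0)] <- m[rs + max(-dr, 0), cs + max(-dc, 0)]
  out
}

#' Topological thinning (skeletonization) of a binary mask
#'
#' Zhang-Suen iterative thinning, vectorized over whole-image shifts. The
#' result is an 8-connected, one-pixel-wide skeleton.
#'
#' @param mask logical (or 0/1) matrix.
#' @return logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  p <- array(as.integer(as.logical(mask)), dim(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north
      n2 <- shift_mat(p, 1, 0);  n3 <- shift_mat(p, 1, -1)
      n4 <- shift_mat(p, 0, -1); n5 <- shift_mat(p, -1, -1)
      n6 <- shift_mat(p, -1, 0); n7 <- shift_mat(p, -1, 1)
      n8 <- shift_mat(p, 0, 1);  n9 <- shift_mat(p, 1, 1)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (n2 == 0 & n3 == 1) + (n3 == 0 & n4 == 1) + (n4 == 0 & n5 == 1) +
        (n5 == 0 & n6 == 1) + (n6 == 0 & n7 == 1) + (n7 == 0 & n8 == 1) +
        (n8 == 0 & n9 == 1) + (n9 == 0 & n2 == 1)
      if (step == 1) {
        cond <- n2 * n4 * n6 == 0 & n4 * n6 * n8 == 0
      } else {
        cond <- n2 * n4 * n8 == 0 & n2 * n6 * n8 == 0
      }
      del <- p == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        p[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1L
}

#' Length of a skeletonized structure
#'
#' Counts links between 8-adjacent skeleton pixels: horizontal and vertical
#' links weigh 1 pixel, diagonal links weigh sqrt(2). A diagonal link is
#' skipped when the two pixels are already connected through an orthogonal
#' neighbour, which keeps straight lines at arbitrary angles unbiased.
#'
#' @param skeleton logical matrix, e.g. from [thin_mask()].
#' @return total length in pixel units.
#' @export
skeleton_length <- function(skeleton) {
  s <- array(as.integer(as.logical(skeleton)), dim(skeleton))
  if (sum(s) == 0) return(0)
  right <- s == 1 & shift_mat(s, 0, -1) == 1  # link to the pixel at (r, c+1)
  down <- s == 1 & shift_mat(s, -1, 0) == 1   # link to (r+1, c)
  dr <- s == 1 & shift_mat(s, -1, -1) == 1    # link to (r+1, c+1)
  dl <- s == 1 & shift_mat(s, -1, 1) == 1     # link to (r+1, c-1)
  # orthogonal companions of each diagonal link
  dr_red <- dr & (shift_mat(s, 0, -1) == 1 | shift_mat(s, -1, 0) == 1)
  dl_red <- dl & (shift_mat(s, 0, 1) == 1 | shift_mat(s, -1, 0) == 1)
  sum(right) + sum(down) + sqrt(2) * (sum(dr & !dr_red) + sum(dl & !dl_red))
}
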