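#' Euclidean length of a polyline
#'
#' @param points two-column matrix of (row, col) vertex coordinates.
#' @return total length in pixel units.
#' @export
polyline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

# logical disc mask; returns the rasterized pixel set
rasterize_disc <- function(dim, center, radius) {
  r <- seq_len(dim[1]); c <- seq_len(dim[2])
  outer((r - center[1])^2, (c - center[2])^2, "+") <= radius^2
}

# logical mask of a polyline drawn with the given stroke width
rasterize_polyline <- function(dim, points, width = 2) {
  mask <- array(FALSE, dim)
  points <- as.matrix(points)
  half <- width / 2
  for (i in seq_len(nrow(points) - 1L)) {
    p0 <- points[i, ]; p1 <- points[i + 1L, ]
    lo <- pmax(floor(pmin(p0, p1) - half), 1)
    hi <- pmin(ceiling(pmax(p0, p1) + half), dim)
    rs <- lo[1]:hi[1]; cs <- lo[2]:hi[2]
    v <- p1 - p0
    len2 <- sum(v^2)
    rr <- matrix(rs, length(rs), length(cs))
    cc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    if (len2 == 0) {
      d2 <- (rr - p0[1])^2 + (cc - p0[2])^2
    } else {
      t <- pmin(pmax(((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / len2, 0), 1)
      d2 <- (rr - (p0[1] + t * v[1]))^2 + (cc - (p0[2] + t * v[2]))^2
    }
    mask[rs, cs] <- mask[rs, cs] | d2 <= half^2
  }
  mask
}

#' Describe one synthetic cell for image rendering
#'
#' @param soma_center (row, col) coordinates of the soma center in pixels.
#' @param soma_radius soma radius in pixels.
#' @param neurites list of two-column (row, col) matrices, one polyline per
#'   neurite; may be empty.
#' @param neurite_width stroke width of drawn neurites (1-3 px).
#' @return a `field_cell` list.
#' @export
field_cell <- function(soma_center, soma_radius, neurites = list(), neurite_width = 2) {
  stopifnot(length(soma_center) == 2, soma_radius > 0)
  if (is.matrix(neurites)) neurites <- list(neurites)
  structure(list(soma_center = as.numeric(soma_center),
                 soma_radius = as.numeric(soma_radius),
                 neurites = lapply(neurites, as.matrix),
                 neurite_width = neurite_width),
            class = "field_cell")
}

check_cell_bounds <- function(cells, dim) {
  bad <- vapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    lo <- cl$soma_center - cl$soma_radius
    hi <- cl$soma_center + cl$soma_radius
    out <- any(lo < 1) || any(hi > dim)
    for (nv in cl$neurites) {
      m <- cl$neurite_width / 2 + 1
      if (nrow(nv) > 0 &&
          (any(nv < 1 + m) || any(nv[, 1] > dim[1] - m) || any(nv[, 2] > dim[2] - m)))
        out <- TRUE
    }
    out
  }, logical(1))
  if (any(bad))
    stop("generate_field_images(): geometry out of image bounds for cell(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
}

#' Render synthetic fluorescence channel images of one field
#'
#' Draws somata as filled discs and neurites as 1-3 px wide curves on a
#' constant background, for a neuronal-marker channel, a transfection
#' reporter channel and a nuclei channel, and emits the exact drawn ground
#' truth alongside: rasterized soma pixel counts, Euclidean centerline
#' lengths of the drawn neurites and integrated above-background intensity
#' per channel.
#'
#' @param cells list of [field_cell()] objects (may be empty).
#' @param dim image dimensions (rows, cols).
#' @param background constant background level (counts).
#' @param noise_sd Gaussian read-noise SD in counts (0 for noise-free).
#' @param marker_level,reporter_level,nuclei_level above-background amplitude
#'   of each channel on its object mask; the marker paints soma + neurites,
#'   the reporter paints the whole cell (cytosolic), nuclei paints a disc of
#'   half the soma radius.
#' @param seed optional seed for the noise draw.
#' @return list of class `field_images` with `images` (named list of numeric
#'   matrices `marker`, `reporter`, `nuclei`) and `truth` (per-cell soma
#'   areas and neurite lengths, per-channel integrated intensities).
#' @examples
#' cell <- field_cell(c(60, 60), 10, list(cbind(60, 70:110)))
#' fi <- generate_field_images(list(cell), dim = c(128, 128))
#' fi$truth$neurite_length
#' @export
generate_field_images <- function(cells, dim = c(256, 256), background = 100,
                                  noise_sd = 0, marker_level = 1000,
                                  reporter_level = 600, nuclei_level = 800,
                                  seed = NULL) {
  dim <- as.integer(dim)
  if (any(c(marker_level, reporter_level, nuclei_level, background) < 0))
    stop("generate_field_images(): intensities must be non-negative", call. = FALSE)
  check_cell_bounds(cells, dim)
  soma <- array(FALSE, dim); neur <- array(FALSE, dim); nucl <- array(FALSE, dim)
  soma_area <- numeric(length(cells))
  neur_len <- numeric(length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    d <- rasterize_disc(dim, cl$soma_center, cl$soma_radius)
    soma_area[i] <- sum(d)  # truth is what the rasterizer drew
    soma <- soma | d
    nucl <- nucl | rasterize_disc(dim, cl$soma_center, cl$soma_radius / 2)
    for (nv in cl$neurites) {
      neur_len[i] <- neur_len[i] + polyline_length(nv)
      neur <- neur | rasterize_polyline(dim, nv, cl$neurite_width)
    }
  }
  cellmask <- soma | neur
  imgs <- list(marker = background + marker_level * cellmask,
               reporter = background + reporter_level * cellmask,
               nuclei = background + nuclei_level * nucl)
  truth <- list(soma_area = soma_area,
                neurite_length = neur_len,
                total_intensity = c(marker = marker_level * sum(cellmask),
                                    reporter = reporter_level * sum(cellmask),
                                    nuclei = nuclei_level * sum(nucl)),
                background = background)
  if (noise_sd > 0) {
    addnoise <- function(m) m + array(stats::rnorm(length(m), sd = noise_sd), dim(m))
    imgs <- if (is.null(seed)) lapply(imgs, addnoise)
            else with_seed(seed, lapply(imgs, addnoise))
    imgs <- lapply(imgs, function(m) pmax(m, 0))
  }
  structure(list(images = imgs, truth = truth, dim = dim), class = "field_images")
}

#' Write field images as 16-bit TIFF with a ground-truth JSON sidecar
#'
#' @param field a `field_images` object.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_field_images <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "field_images"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$images)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    m <- pmin(pmax(round(field$images[[ch]]), 0), 65535)
    tiff::writeTIFF(m / 65535, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, sprintf("%s_truth.json", prefix))
  jsonlite::write_json(field$truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}

#' Read a single-channel 8/16-bit TIFF as a count matrix
#'
#' @param path TIFF file path.
#' @return numeric matrix of pixel counts.
#' @export
read_field_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}
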