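#' Synthetic haematoxylin-style histology image
#'
#' Renders a grayscale field of dark elliptical nuclei on a lighter tissue
#' background (slide background lighter still), with
#' `true_count = round(cellularity * field_area / 1000)` nuclei. Placement
#' uses a jittered grid, so nuclei are non-overlapping by default; a small
#' fraction of touching pairs can be requested to exercise watershed
#' splitting.
#'
#' @param cellularity Cells per 1000 um^2 (> 0).
#' @param field_area Tissue area in um^2 (default 1e6, a 1 mm^2 field).
#' @param seed Integer seed.
#' @param um_per_pixel Pixel size (default 1 um).
#' @param tissue_fraction Fraction of the frame covered by tissue (default 1).
#' @param touching_fraction Fraction of nuclei placed as touching pairs
#'   (default 0).
#' @param nucleus_axes Mean semi-axes of the elliptical nuclei in um.
#' @return A list: `image` (matrix in `[0, 1]`), `true_count`,
#'   `um_per_pixel`, `tissue_area` (um^2 of rendered tissue).
#' @export
#' @examples
#' h <- makeHistologyImage(0.5, field_area = 250000, seed = 1)
#' h$true_count  # 125
makeHistologyImage <- function(cellularity, field_area = 1e6, seed = 1L,
                               um_per_pixel = 1, tissue_fraction = 1,
                               touching_fraction = 0,
                               nucleus_axes = c(4.2, 3)) {
  if (cellularity <= 0 || field_area <= 0)
    stop("makeHistologyImage: cellularity and field_area must be positive")
  set.seed(as.integer(seed))
  frame_area <- field_area / tissue_fraction
  side <- ceiling(sqrt(frame_area) / um_per_pixel)
  img <- matrix(0.95, side, side)             # slide background
  tis_rows <- seq_len(round(side * tissue_fraction))
  img[tis_rows, ] <- 0.70                     # tissue
  true_count <- max(1L, round(cellularity * field_area / 1000))

  # jittered-grid placement inside the tissue region
  ncell <- ceiling(sqrt(true_count / tissue_fraction))
  gx <- side / ncell
  if (gx < 2.2 * max(nucleus_axes) / um_per_pixel && touching_fraction == 0)
    stop("makeHistologyImage: requested count exceeds packable positions")
  cells <- expand.grid(i = seq_len(ncell), j = seq_len(ncell))
  cells <- cells[(cells$i - 0.5) * gx <= max(tis_rows), ]
  if (nrow(cells) < true_count)
    stop("makeHistologyImage: requested count exceeds packable positions")
  pick <- cells[sample.int(nrow(cells), true_count), ]
  jit <- max(gx / 2 - max(nucleus_axes) / um_per_pixel - 1, 0)
  cx <- (pick$i - 0.5) * gx + stats::runif(true_count, -jit, jit)
  cy <- (pick$j - 0.5) * gx + stats::runif(true_count, -jit, jit)

  a <- pmax(stats::rnorm(true_count, nucleus_axes[1], 0.3), 2.5) / um_per_pixel
  b <- pmax(stats::rnorm(true_count, nucleus_axes[2], 0.3), 2.0) / um_per_pixel
  th <- stats::runif(true_count, 0, pi)

  n_touch <- round(touching_fraction * true_count / 2)
  if (n_touch > 0) {  # convert pairs into side-by-side touching twins
    idx <- sample.int(true_count - 1L, n_touch)
    twin <- idx + 1L
    th[idx] <- pi / 2; th[twin] <- pi / 2   # minor axes along the join
    cx[twin] <- cx[idx] + 0.98 * (b[idx] + b[twin])
    cy[twin] <- cy[idx]
  }
  for (k in seq_len(true_count)) {
    r <- ceiling(a[k])
    xs <- max(1, round(cx[k]) - r):min(side, round(cx[k]) + r)
    ys <- max(1, round(cy[k]) - r):min(side, round(cy[k]) + r)
    dx <- outer(xs - cx[k], rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy[k])
    u <- (dx * cos(th[k]) + dy * sin(th[k])) / a[k]
    v <- (-dx * sin(th[k]) + dy * cos(th[k])) / b[k]
    sub <- img[xs, ys]
    sub[u^2 + v^2 <= 1] <- 0.20               # nucleus
    img[xs, ys] <- sub
  }
  img <- img + matrix(stats::rnorm(side^2, 0, 0.015), side, side)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, true_count = true_count, um_per_pixel = um_per_pixel,
       tissue_area = length(tis_rows) * side * um_per_pixel^2)
}

# two-threshold (3-class) Otsu on a numeric sample: exhaustive maximisation
# of the between-class variance over a 96-bin histogram
.otsu2 <- function(vals, nbins = 96L) {
  rng <- range(vals)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  h <- tabulate(pmin(pmax(1L, as.integer((vals - rng[1]) / diff(rng) * nbins) + 1L),
                     nbins), nbins)
  p <- h / sum(h)
  P <- cumsum(p)
  M <- cumsum(p * seq_len(nbins))
  best <- -Inf; th <- c(1L, 2L)
  for (i in seq_len(nbins - 2L)) {
    w1 <- P[i]; m1 <- M[i]
    if (w1 == 0) next
    for (j in (i + 1L):(nbins - 1L)) {
      w2 <- P[j] - P[i]; w3 <- 1 - P[j]
      if (w2 == 0 || w3 == 0) next
      m2 <- M[j] - M[i]; m3 <- M[nbins] - M[j]
      v <- m1^2 / w1 + m2^2 / w2 + m3^2 / w3
      if (v > best) { best <- v; th <- c(i, j) }
    }
  }
  rng[1] + th / nbins * diff(rng)
}

# Otsu threshold on a numeric sample (maximises between-class variance on a
# 256-bin histogram); adaptive, hence invariant to linear intensity rescaling
.otsu <- function(vals, nbins = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(1L, as.integer((vals - rng[1]) / diff(rng) * nbins) + 1L),
                     nbins), nbins)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  bc <- (mu_t * om - mu)^2 / (om * (1 - om))
  bc[!is.finite(bc)] <- 0
  k <- which.max(bc)
  rng[1] + k / nbins * diff(rng)
}

#' Segment tissue from slide background
#'
#' Foreground (tissue) segmentation by adaptive intensity thresholding.
#' The darkest class (nuclei) is first separated by an Otsu threshold; a
#' second Otsu split of the remaining pixels distinguishes tissue from the
#' brighter slide background, and is accepted only when the two classes are
#' clearly separated relative to their within-class spread (otherwise no
#' slide is present and the whole frame is tissue). Holes (nuclei) are
#' filled. Area is the mask pixel count times the pixel area. All decisions
#' are made on relative intensities, so segmentation is invariant to global
#' linear intensity rescaling.
#'
#' @param image Grayscale matrix.
#' @param pixel_size_um Pixel size in um (> 0).
#' @return A list: `mask` (logical matrix), `area_um2`.
#' @export
segmentTissue <- function(image, pixel_size_um) {
  if (pixel_size_um <= 0) stop("segmentTissue: pixel_size_um must be positive")
  th <- .otsu2(as.vector(image))             # (nuclei | tissue | slide?)
  mid <- image[image >= th[1] & image < th[2]]
  hi <- image[image >= th[2]]
  slide <- length(mid) > 10 && length(hi) > 10 &&
    (mean(hi) - mean(mid)) > 3 * sqrt((stats::var(mid) + stats::var(hi)) / 2)
  mask <- if (slide) image < th[2] else matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("segmentTissue: empty foreground")
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  list(mask = mask, area_um2 = sum(mask) * pixel_size_um^2)
}

#' Count cell nuclei
#'
#' Dark-object detection inside the tissue mask: nuclei are pixels darker
#' than `median - k * MAD` of the tissue intensities (a robust adaptive
#' threshold that works at any nucleus density and is invariant to global
#' linear intensity rescaling), split where touching by a distance-transform
#' watershed, then size-filtered to the plausible nucleus area range.
#'
#' @param image Grayscale matrix.
#' @param tissue_mask Logical matrix from [segmentTissue()].
#' @param pixel_size_um Pixel size in um.
#' @param min_area,max_area Nucleus area gates in um^2 (defaults 20 and 400).
#' @param k Robustness factor of the dark-object threshold (default 6).
#' @return A list: `n_cells`, `label` (integer matrix of nucleus labels).
#' @export
countCells <- function(image, tissue_mask, pixel_size_um = 1,
                       min_area = 20, max_area = 400, k = 6) {
  if (!any(tissue_mask)) stop("countCells: empty tissue mask")
  v <- image[tissue_mask]
  th <- stats::median(v) - k * stats::mad(v)
  nuc <- (image < th) & tissue_mask
  if (!any(nuc)) return(list(n_cells = 0L, label = matrix(0L, nrow(image), ncol(image))))
  dm <- EBImage::distmap(EBImage::Image(nuc * 1))
  lab <- EBImage::watershed(dm, tolerance = 0.5, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  areas <- tabulate(lab[lab > 0]) * pixel_size_um^2
  keep <- which(areas >= min_area & areas <= max_area)
  lab[!(lab %in% keep)] <- 0L
  list(n_cells = length(keep), label = lab)
}

#' Cellularity from count and area
#'
#' `rho_c = N / A * 1000`: cells per 1000 um^2.
#'
#' @param n Cell count.
#' @param area Tissue area in um^2 (> 0).
#' @return Cellularity in cells per 1000 um^2.
#' @export
#' @examples
#' cellularity(2000, 4e5)  # 5
cellularity <- function(n, area) {
  if (area <= 0) stop("cellularity: area must be positive")
  1000 * n / area
}

#' Write / read a histology image with its pixel-size sidecar
#'
#' 8-bit grayscale PNG plus a JSON sidecar carrying `um_per_pixel`.
#'
#' @param histo A list as returned by [makeHistologyImage()].
#' @param path Output PNG path (sidecar gets `.json` appended).
#' @return `writeHistologyImage` returns `path` invisibly;
#'   `readHistologyImage` returns a list with `image` and `um_per_pixel`.
#' @export
writeHistologyImage <- function(histo, path) {
  EBImage::writeImage(EBImage::Image(histo$image), path, type = "png", bits.per.sample = 8L)
  jsonlite::write_json(list(um_per_pixel = histo$um_per_pixel),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeHistologyImage
#' @export
readHistologyImage <- function(path) {
  img <- EBImage::readImage(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  list(image = matrix(as.numeric(EBImage::imageData(img)), dim(img)[1], dim(img)[2]),
       um_per_pixel = meta$um_per_pixel)
}
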