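#' Smooth a mask for perimeter measurement
#'
#' Morphological opening followed by closing with a digital disk of radius
#' `round(detail_um / 2 / pixel_size_um)` pixels (minimum 1), which removes
#' protrusions and indentations narrower than `detail_um`. The perimeter is
#' measured on the smoothed mask so that it is not inflated by small
#' surface details; the unsmoothed mask continues to define inside/outside
#' and boundary distances. Idempotent.
#'
#' @param mask A [spheroid_mask()].
#' @param detail_um Smallest surface detail (micrometers) to be preserved;
#'   default 15.
#' @return The smoothed [spheroid_mask()].
#' @export
smooth_mask <- function(mask, detail_um = 15) {
  stopifnot(inherits(mask, "spheroid_mask"))
  if (detail_um <= 0) stop("detail_um must be > 0")
  if (!any(mask$grid)) return(mask)
  r <- max(1L, as.integer(round(detail_um / 2 / mask$pixel_size_um)))
  k <- disk_kernel(r)
  m <- matrix(as.numeric(mask$grid), nrow(mask$grid))
  m <- EBImage::closing(EBImage::opening(m, k), k)
  spheroid_mask(m > 0, mask$mode, mask$pixel_size_um,
                threshold_used = mask$threshold_used,
                target_area_px = mask$target_area_px)
}

# Traced perimeter (pixel units) of a binary grid: outer Moore contours of
# all 8-connected foreground components plus, as inner boundaries, the
# contours of enclosed holes (4-connected background components that do not
# touch the image border). Axial steps count 1, diagonal steps sqrt(2).
perimeter_px <- function(grid) {
  lab <- cpp_label_components(grid)
  n <- max(lab)
  if (n == 0L) return(0)
  total <- sum(cpp_trace_perimeter(lab, n))
  # holes: 4-connected background not reaching the border
  bg <- !grid
  if (any(bg)) {
    # 4-connectivity via labeling with diagonal moves suppressed: label the
    # background with an 8-connected pass would merge diagonal leaks, so
    # flood with a 4-neighbor structuring rule instead.
    hl <- label4(bg)
    if (max(hl) > 0L) {
      border_labels <- unique(c(hl[1L, ], hl[nrow(hl), ],
                                hl[, 1L], hl[, ncol(hl)]))
      holes <- setdiff(seq_len(max(hl)), c(0L, border_labels))
      if (length(holes)) {
        hgrid <- matrix(hl %in% holes, nrow(hl))
        hlab <- cpp_label_components(hgrid)
        total <- total + sum(cpp_trace_perimeter(hlab, max(hlab)))
      }
    }
  }
  total
}

# 4-connected labeling in plain R (row/column flood via equivalence over
# runs would be overkill; a BFS on the 4-neighborhood is fast enough for
# the hole sizes encountered here).
label4 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(bin & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- c + d[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (bin[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

#' Perimeter of a spheroid mask
#'
#' Length of the mask boundary obtained by 8-connected Moore contour
#' tracing: axial steps between consecutive boundary pixels count 1 pixel,
#' diagonal steps \eqn{\sqrt 2}. Outer contours of all components and the
#' contours of enclosed holes are summed, and the total is converted to
#' micrometers. A single-pixel component has no steps to trace and
#' contributes 0. The mask is traced as given; pass it through
#' [smooth_mask()] first when the smoothed perimeter is wanted.
#'
#' @param mask A [spheroid_mask()].
#' @return Perimeter in micrometers; 0 with a warning for an empty mask.
#' @export
mask_perimeter <- function(mask) {
  stopifnot(inherits(mask, "spheroid_mask"))
  if (!any(mask$grid)) {
    warning("mask is empty; perimeter is 0")
    return(0)
  }
  perimeter_px(mask$grid) * mask$pixel_size_um
}

# Coordinates (row, col) of the mask's boundary pixels (mask pixels with at
# least one 4-neighbor outside the mask; out-of-image counts as outside).
boundary_coords <- function(grid) {
  which(mask_boundary(grid), arr.ind = TRUE)
}

#' Distance from a detected object to the spheroid boundary
#'
#' Euclidean distance to the nearest mask boundary pixel (a mask pixel with
#' at least one background 4-neighbor), in micrometers. The reference point
#' on the object is its centroid (default) or, with
#' `distance_from = "edge"`, its nearest own pixel. Measuring from the
#' boundary of the arbitrarily shaped mask (rather than from its centroid)
#' keeps the distance meaningful for irregular, elongated or lobed cores.
#'
#' @param object A `detected_object`.
#' @param mask A non-empty [spheroid_mask()].
#' @param distance_from `"centroid"` or `"edge"`.
#' @return Distance in micrometers.
#' @export
distance_to_boundary <- function(object, mask,
                                 distance_from = c("centroid", "edge")) {
  stopifnot(inherits(object, "detected_object"),
            inherits(mask, "spheroid_mask"))
  distance_from <- match.arg(distance_from)
  if (!any(mask$grid)) stop("mask is empty: no boundary to measure from")
  bd <- boundary_coords(mask$grid)
  px <- object$pixels
  if (distance_from == "centroid") {
    ctr <- colMeans(px)
    d2 <- (bd[, 1L] - ctr[1L])^2 + (bd[, 2L] - ctr[2L])^2
    sqrt(min(d2)) * mask$pixel_size_um
  } else {
    d2min <- Inf
    for (i in seq_len(nrow(px))) {
      d2 <- (bd[, 1L] - px[i, 1L])^2 + (bd[, 2L] - px[i, 2L])^2
      d2min <- min(d2min, d2)
    }
    sqrt(d2min) * mask$pixel_size_um
  }
}

#' Shape descriptors of a pixel set
#'
#' Standard particle-analysis descriptors:
#' \itemize{
#'   \item circularity `4 * pi * A / P^2` with `A` the pixel area and `P`
#'     the traced perimeter, capped at 1.0 (digitization can push the raw
#'     ratio above 1 for very small objects);
#'   \item roundness `4 * A / (pi * L^2)` with `L` the major-axis length of
#'     the ellipse matching the object's second-order central moments (each
#'     pixel contributes the moment of a unit square, i.e. + 1/12);
#'   \item solidity `A / A_hull`, the pixel area over the area of the convex
#'     hull of the pixel outlines (each pixel contributes its four corners).
#' }
#' A single-pixel object reports 1.0 for all three by convention.
#'
#' @param pixels Integer matrix of object pixels, one `(row, col)` per row.
#' @return Named numeric vector `c(circularity, roundness, solidity)`.
#' @export
shape_descriptors <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L)
    return(c(circularity = 1, roundness = 1, solidity = 1))
  rr <- pixels[, 1L]; cc <- pixels[, 2L]
  # perimeter of the object alone, traced on a tight crop
  crop <- matrix(FALSE, diff(range(rr)) + 1L, diff(range(cc)) + 1L)
  crop[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
  P <- perimeter_px(crop)
  circ <- if (P > 0) min(1, 4 * pi * n / P^2) else 1
  # best-fit ellipse major axis from second-order central moments
  mrr <- mean((rr - mean(rr))^2) + 1 / 12
  mcc <- mean((cc - mean(cc))^2) + 1 / 12
  mrc <- mean((rr - mean(rr)) * (cc - mean(cc)))
  lam <- (mrr + mcc) / 2 + sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  L <- 4 * sqrt(lam)
  round_ <- 4 * n / (pi * L^2)
  # convex hull over pixel corners, area by the shoelace formula
  hx <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
  hy <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
  h <- chull(hx, hy)
  x <- hx[h]; y <- hy[h]
  hull_area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  sol <- if (hull_area > 0) min(1, n / hull_area) else 1
  c(circularity = circ, roundness = round_, solidity = sol)
}

#' Fill the measurement fields of detected objects
#'
#' Computes, for every object: centroid (reported as 0-based `(x, y)` =
#' `(column, row)`), pixel and physical area, traced perimeter, shape
#' descriptors and distance to the mask boundary.
#'
#' @param objects List of `detected_object`s.
#' @param mask The [spheroid_mask()] the objects were detected against.
#' @param pixel_size_um Micrometers per pixel.
#' @param distance_from `"centroid"` or `"edge"`.
#' @return The object list with all measurement fields filled.
#' @export
measure_objects <- function(objects, mask, pixel_size_um,
                            distance_from = c("centroid", "edge")) {
  distance_from <- match.arg(distance_from)
  has_boundary <- any(mask$grid)
  lapply(objects, function(ob) {
    px <- ob$pixels
    ctr <- colMeans(px)
    ob$centroid <- c(x = unname(ctr[2L]) - 1, y = unname(ctr[1L]) - 1)
    ob$area_px <- nrow(px)
    ob$area_um2 <- nrow(px) * pixel_size_um^2
    rr <- px[, 1L]; cc <- px[, 2L]
    crop <- matrix(FALSE, diff(range(rr)) + 1L, diff(range(cc)) + 1L)
    crop[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
    ob$perimeter_um <- perimeter_px(crop) * pixel_size_um
    sd <- shape_descriptors(px)
    ob$circularity <- unname(sd["circularity"])
    ob$roundness <- unname(sd["roundness"])
    ob$solidity <- unname(sd["solidity"])
    ob$distance_um <- if (has_boundary)
      distance_to_boundary(ob, mask, distance_from) else NA_real_
    ob
  })
}

#' Detected objects as a data frame
#'
#' One row per object (excluded artifacts included, flagged), with 0-based
#' `(x, y)` centroid coordinates.
#'
#' @param objects List of measured `detected_object`s.
#' @return A data frame.
#' @export
objects_to_df <- function(objects) {
  if (length(objects) == 0L)
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      roundness = numeric(), solidity = numeric(),
                      distance_um = numeric(),
                      excluded_as_artifact = logical()))
  do.call(rbind, lapply(objects, function(ob) data.frame(
    label = ob$label, x = ob$centroid[["x"]], y = ob$centroid[["y"]],
    area_px = ob$area_px, area_um2 = ob$area_um2,
    perimeter_um = ob$perimeter_um, circularity = ob$circularity,
    roundness = ob$roundness, solidity = ob$solidity,
    distance_um = ob$distance_um,
    excluded_as_artifact = ob$excluded_as_artifact)))
}

#' Per-image summary of mask and invading objects
#'
#' One-row roll-up per timepoint: mask area, smoothed mask perimeter,
#' number of objects outside the mask (total and per millimeter of mask
#' perimeter), their total area, and the mean and median distances to the
#' nearest mask boundary pixel. Artifact-flagged objects are excluded from
#' every statistic and reported only through `n_excluded_artifacts`.
#'
#' @param mask The (unsmoothed) [spheroid_mask()].
#' @param objects Measured `detected_object`s for the same image.
#' @param timepoint_label Label echoed into the record.
#' @param detail_um Smoothing scale for the perimeter (see [smooth_mask()]).
#' @param params Optional [emax_params()] echoed into the record.
#' @return A one-row data frame (the summary record).
#' @export
summarize_image <- function(mask, objects, timepoint_label,
                            detail_um = 15, params = NULL) {
  stopifnot(inherits(mask, "spheroid_mask"))
  kept <- Filter(function(ob) !ob$excluded_as_artifact, objects)
  n <- length(kept)
  per_um <- if (any(mask$grid)) mask_perimeter(smooth_mask(mask, detail_um))
            else 0
  dists <- vapply(kept, `[[`, numeric(1), "distance_um")
  data.frame(
    timepoint_label = timepoint_label,
    mode = mask$mode,
    mask_area_um2 = mask$area_um2,
    mask_perimeter_um = per_um,
    n_objects = n,
    n_objects_per_mm = if (per_um > 0) n / (per_um / 1000) else NA_real_,
    total_object_area_um2 = if (n > 0)
      sum(vapply(kept, `[[`, numeric(1), "area_um2")) else 0,
    mean_distance_um = if (n > 0) mean(dists) else NA_real_,
    median_distance_um = if (n > 0) median(dists) else NA_real_,
    n_excluded_artifacts =
      sum(vapply(objects, `[[`, logical(1), "excluded_as_artifact")),
    threshold_used = mask$threshold_used,
    emax_dynamic = if (is.null(params)) NA_real_ else params$dynamic,
    artifact_radius_um = if (is.null(params)) NA_real_
                         else params$artifact_radius_um,
    detail_um = detail_um)
}
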