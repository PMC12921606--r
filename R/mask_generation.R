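#' Spheroid-core mask
#'
#' Boolean grid marking the compact spheroid core, with provenance of how it
#' was generated.
#'
#' @param grid Logical matrix, `TRUE` = core pixel.
#' @param mode `"compact"` or `"disintegrating"`.
#' @param pixel_size_um Micrometers per pixel.
#' @param threshold_used Intensity threshold that produced the mask, or `NA`.
#' @param target_area_px Target pixel area (disintegrating mode), or `NA`.
#' @return An object of class `spheroid_mask` with fields `grid`, `mode`,
#'   `threshold_used`, `target_area_px`, `area_px`, `area_um2` and
#'   `pixel_size_um`.
#' @export
spheroid_mask <- function(grid, mode, pixel_size_um,
                          threshold_used = NA_real_,
                          target_area_px = NA_integer_) {
  stopifnot(is.logical(grid), is.matrix(grid))
  mode <- match.arg(mode, c("compact", "disintegrating"))
  area_px <- sum(grid)
  structure(
    list(grid = grid, mode = mode,
         threshold_used = threshold_used,
         target_area_px = target_area_px,
         area_px = area_px,
         area_um2 = area_px * pixel_size_um^2,
         pixel_size_um = pixel_size_um),
    class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf(
    "spheroid_mask (%s): %d x %d px, area %d px = %.4g um^2%s\n",
    x$mode, nrow(x$grid), ncol(x$grid), x$area_px, x$area_um2,
    if (!is.na(x$threshold_used))
      sprintf(", threshold %g", x$threshold_used) else ""))
  invisible(x)
}

#' Minimum cross-entropy (Li) threshold
#'
#' Finds the intensity threshold `t` minimizing the cross-entropy between
#' the image and its binarization, computed on the intensity histogram:
#' \deqn{\eta(t) = -\sum_{g \le t} g\,h(g)\,\log\mu_b(t)
#'                -\sum_{g > t} g\,h(g)\,\log\mu_f(t)}
#' where \eqn{\mu_b,\mu_f} are the mean intensities below/above the
#' threshold. The minimum is taken over every observed intensity level that
#' leaves both classes non-empty (the criterion is piecewise constant
#' between observed levels, so this equals an exhaustive scan over all
#' levels); ties go to the smallest threshold. Foreground is defined as
#' strictly greater than `t`.
#'
#' @param image A [calibrated_image()] or numeric matrix with at least two
#'   distinct values.
#' @return The threshold intensity (scalar).
#' @export
mce_threshold <- function(image) {
  v <- if (inherits(image, "calibrated_image")) image$pixels else image
  u <- sort(unique(as.vector(v)))
  if (length(u) < 2L)
    stop("image has no contrast; cannot threshold")
  cnt <- tabulate(match(as.vector(v), u), nbins = length(u))
  w  <- cumsum(cnt)            # pixels with value <= u[i]
  s  <- cumsum(cnt * u)        # intensity sum  <= u[i]
  N  <- w[length(w)]; S <- s[length(s)]
  k  <- length(u) - 1L         # candidate thresholds u[1..k]
  wb <- w[1:k]; sb <- s[1:k]
  wf <- N - wb; sf <- S - sb
  mub <- sb / wb; muf <- sf / wf
  # 0 * log(0) := 0 -- a class whose intensity mass is zero contributes
  # nothing to the cross-entropy.
  termb <- ifelse(sb > 0, -sb * log(mub), 0)
  termf <- ifelse(sf > 0, -sf * log(muf), 0)
  eta <- termb + termf
  u[which.min(eta)]
}

#' Segment a compact spheroid by per-image thresholding
#'
#' Thresholds the image independently of any other timepoint: the mask is
#' all pixels strictly greater than the threshold, which is either supplied
#' by the user (the non-interactive equivalent of adjusting the threshold in
#' a pop-up dialog) or computed by [mce_threshold()].
#'
#' @param image A [calibrated_image()].
#' @param threshold_override Optional intensity threshold replacing the
#'   automatic one. An override above the image maximum yields an empty
#'   mask (legal; a warning is emitted).
#' @return A [spheroid_mask()] with `mode = "compact"`.
#' @export
segment_compact <- function(image, threshold_override = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  t <- if (is.null(threshold_override)) mce_threshold(image)
       else threshold_override
  grid <- image$pixels > t
  if (!any(grid))
    warning("threshold ", t, " is above the image maximum; mask is empty")
  spheroid_mask(grid, "compact", image$pixel_size_um, threshold_used = t)
}

#' Fixed-area mask covering the highest-intensity pixels
#'
#' Builds the disintegrating-mode mask for a later timepoint: the
#' `target_area_px` brightest pixels of the image. All pixels strictly
#' brighter than the cut intensity are included; pixels exactly at the cut
#' intensity are filled in deterministic raster-scan order (top-left first)
#' until the target area is reached exactly, so the result is reproducible
#' and `area_px == target_area_px` always holds.
#'
#' @param image A [calibrated_image()].
#' @param target_area_px Integer in `[0, n_pixels]`.
#' @return A [spheroid_mask()] with `mode = "disintegrating"`.
#' @export
fixed_area_mask <- function(image, target_area_px) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  n <- length(px)
  target_area_px <- as.integer(target_area_px)
  if (target_area_px < 0L || target_area_px > n)
    stop("target_area_px must be between 0 and the pixel count (", n, ")")
  grid <- matrix(FALSE, nrow(px), ncol(px))
  if (target_area_px > 0L) {
    rast <- raster_index(nrow(px), ncol(px))
    ord <- order(-as.vector(px), rast)[seq_len(target_area_px)]
    grid[ord] <- TRUE
  }
  cut <- if (target_area_px > 0L) min(px[grid]) else NA_real_
  spheroid_mask(grid, "disintegrating", image$pixel_size_um,
                threshold_used = cut, target_area_px = target_area_px)
}

#' Keep only the largest connected component of a mask
#'
#' Retains the largest 8-connected component, treating bright but detached
#' particles as separate from the core. Area ties are broken in favor of
#' the component whose first pixel comes earliest in raster order. An empty
#' mask is returned unchanged. Idempotent.
#'
#' @param mask A [spheroid_mask()].
#' @return A [spheroid_mask()] with updated area fields and unchanged
#'   provenance.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "spheroid_mask"))
  if (!any(mask$grid)) return(mask)
  lab <- cpp_label_components(mask$grid)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # first max = raster-earliest component
  spheroid_mask(lab == keep, mask$mode, mask$pixel_size_um,
                threshold_used = mask$threshold_used,
                target_area_px = mask$target_area_px)
}

#' Automatically choose the mask-generation mode
#'
#' Segments every image of the dataset independently with [mce_threshold()]
#' followed by [largest_component()], and compares core areas: if the core
#' area of any followup falls below `(1 - shrink_tol)` times the START core
#' area -- the signature of rapid disintegration -- the disintegrating mode
#' is selected; otherwise the compact mode. With no followups the compact
#' mode is returned.
#'
#' @param dataset A [spheroid_dataset()].
#' @param shrink_tol Relative shrinkage tolerated before the disintegrating
#'   mode is triggered (default 0.05).
#' @return `"compact"` or `"disintegrating"`, with the per-image probe areas
#'   (in pixels, START first) attached as attribute `"areas"`.
#' @export
auto_select_mode <- function(dataset, shrink_tol = 0.05) {
  stopifnot(inherits(dataset, "spheroid_dataset"))
  imgs <- dataset_images(dataset)
  if (length(imgs) == 1L)
    return(structure("compact", areas = largest_component(
      segment_compact(imgs[[1L]]))$area_px))
  areas <- vapply(imgs, function(im)
    largest_component(segment_compact(im))$area_px, numeric(1))
  names(areas) <- vapply(imgs, `[[`, character(1), "timepoint_label")
  mode <- if (any(areas[-1L] < (1 - shrink_tol) * areas[1L]))
    "disintegrating" else "compact"
  structure(mode, areas = areas)
}

#' Generate the spheroid-core masks for a whole dataset
#'
#' In compact mode every image is thresholded independently. In
#' disintegrating mode the START image is thresholded, its mask area is
#' recorded, and each followup receives a fixed-area mask of that size
#' covering its brightest pixels. With `keep_largest = TRUE` (the default)
#' only the largest connected component of every mask is retained after
#' generation; in disintegrating mode this intentionally breaks the
#' fixed-area property for followups, so that detached bright particles are
#' dropped from the core and counted as invading objects.
#'
#' @param dataset A [spheroid_dataset()].
#' @param mode `"compact"`, `"disintegrating"` or `"auto"` (default), the
#'   latter resolved by [auto_select_mode()].
#' @param keep_largest Apply [largest_component()] to every mask.
#' @param threshold_overrides Optional numeric vector of per-image threshold
#'   overrides (START first; `NA` = automatic), or a named vector keyed by
#'   timepoint label.
#' @param shrink_tol Passed to [auto_select_mode()] when `mode = "auto"`.
#' @return List of [spheroid_mask()] objects, START first, with the resolved
#'   mode attached as attribute `"mode"`.
#' @export
build_masks <- function(dataset, mode = c("auto", "compact", "disintegrating"),
                        keep_largest = TRUE, threshold_overrides = NULL,
                        shrink_tol = 0.05) {
  stopifnot(inherits(dataset, "spheroid_dataset"))
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- as.character(auto_select_mode(dataset, shrink_tol))
  imgs <- dataset_images(dataset)
  labels <- vapply(imgs, `[[`, character(1), "timepoint_label")
  ov <- rep(NA_real_, length(imgs))
  if (!is.null(threshold_overrides)) {
    if (!is.null(names(threshold_overrides))) {
      m <- match(names(threshold_overrides), labels)
      if (anyNA(m))
        stop("threshold override for unknown timepoint: ",
             paste(names(threshold_overrides)[is.na(m)], collapse = ", "))
      ov[m] <- threshold_overrides
    } else {
      if (length(threshold_overrides) != length(imgs))
        stop("threshold_overrides must have one entry per image")
      ov <- as.numeric(threshold_overrides)
    }
  }
  seg <- function(i) segment_compact(
    imgs[[i]], threshold_override = if (is.na(ov[i])) NULL else ov[i])
  masks <- if (mode == "compact") {
    lapply(seq_along(imgs), seg)
  } else {
    if (any(!is.na(ov[-1L])))
      warning("threshold overrides for followups are ignored in ",
              "disintegrating mode (only START is thresholded)")
    start_mask <- seg(1L)
    c(list(start_mask),
      lapply(seq_along(imgs)[-1L], function(i)
        fixed_area_mask(imgs[[i]], start_mask$area_px)))
  }
  if (keep_largest) masks <- lapply(masks, largest_component)
  names(masks) <- labels
  structure(masks, mode = mode)
}
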