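#' Specification of a synthetic spheroid time series
#'
#' Describes a renderable spheroid invasion scenario with planted ground
#' truth: a bright core disk with a soft (Gaussian-profile) edge, invading
#' cells as isotropic Gaussian spots, optional uniform bright disks acting
#' as artifacts (bubbles), a nonconstant background (base level plus a
#' linear ramp along the image columns), additive Gaussian noise, and an
#' optional disintegration phenotype (shrinking core plus detached bright
#' fragments at later timepoints). The seed fully determines the rendered
#' images.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Micrometers per pixel.
#' @param timepoint_labels Character vector, first entry is START.
#' @param core_center_px `c(row, col)` of the core center (default: image
#'   center).
#' @param core_radius_um Core radius per timepoint (same length as
#'   `timepoint_labels`).
#' @param core_intensity Plateau intensity of the core (counts).
#' @param core_edge_sigma_um Softness of the core edge (Gaussian sigma).
#' @param invaders Data frame with columns `row`, `col` (pixel centers),
#'   `peak` (amplitude in counts), `sigma_um` (spot radius) and `timepoint`
#'   (index into `timepoint_labels`, >= 2: the START image has the core
#'   only). Every center must lie at least `3 * sigma` outside the core
#'   disk of its timepoint.
#' @param artifacts Data frame with columns `row`, `col`, `radius_um`,
#'   `intensity`, `timepoint`, or `NULL`.
#' @param background_base Background level (counts).
#' @param ramp_amplitude Amplitude of the linear background ramp across the
#'   image columns (counts).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (counts).
#' @param fragmentation Add detached bright fragments around the core at
#'   followup timepoints (disintegration phenotype).
#' @param n_fragments Number of fragments per followup.
#' @param fragment_radius_um Fragment radius.
#' @param bit_depth 8 or 16; intensities are clipped to the bit range.
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(image_shape = c(400L, 400L),
                         pixel_size_um = 2.27,
                         timepoint_labels = c("START", "24h"),
                         core_center_px = NULL,
                         core_radius_um = c(180, 200),
                         core_intensity = 60000,
                         core_edge_sigma_um = 4.5,
                         invaders = NULL,
                         artifacts = NULL,
                         background_base = 500,
                         ramp_amplitude = 40,
                         noise_sd = 6,
                         fragmentation = FALSE,
                         n_fragments = 0L,
                         fragment_radius_um = 7,
                         bit_depth = 16L,
                         seed = 42L) {
  if (length(core_radius_um) != length(timepoint_labels))
    stop("core_radius_um needs one value per timepoint")
  if (is.null(core_center_px)) core_center_px <- (image_shape + 1) / 2
  spec <- structure(
    list(image_shape = as.integer(image_shape),
         pixel_size_um = pixel_size_um,
         timepoint_labels = timepoint_labels,
         core_center_px = core_center_px,
         core_radius_um = core_radius_um,
         core_intensity = core_intensity,
         core_edge_sigma_um = core_edge_sigma_um,
         invaders = invaders, artifacts = artifacts,
         background_base = background_base,
         ramp_amplitude = ramp_amplitude,
         noise_sd = noise_sd,
         fragmentation = isTRUE(fragmentation),
         n_fragments = as.integer(n_fragments),
         fragment_radius_um = fragment_radius_um,
         bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  inv <- spec$invaders
  if (is.null(inv) || nrow(inv) == 0L) return(invisible(spec))
  need <- c("row", "col", "peak", "sigma_um", "timepoint")
  if (!all(need %in% names(inv)))
    stop("invaders must have columns ", paste(need, collapse = ", "))
  if (any(inv$timepoint < 2L))
    stop("invaders cannot be planted at START (the START image has the ",
         "core only)")
  px <- spec$pixel_size_um
  d <- sqrt((inv$row - spec$core_center_px[1L])^2 +
            (inv$col - spec$core_center_px[2L])^2)
  rmin <- spec$core_radius_um[inv$timepoint] / px + 3 * inv$sigma_um / px
  if (any(d < rmin))
    stop("every invader center must lie at least 3 sigma outside the ",
         "core disk of its timepoint")
  invisible(spec)
}

# Deterministic ring placement: n points on a golden-angle spiral between
# radial distances rmin..rmax (pixels) around a center. Gives well-spread,
# reproducible positions without random draws.
ring_positions <- function(n, rmin, rmax, center, phase = 0.1) {
  k <- seq_len(n)
  ang <- phase + k * pi * (3 - sqrt(5))
  rad <- if (n == 1L) (rmin + rmax) / 2
         else rmin + (rmax - rmin) * (k - 1) / (n - 1)
  data.frame(row = round(center[1L] + rad * sin(ang)),
             col = round(center[2L] + rad * cos(ang)))
}

#' Render a synthetic fixture
#'
#' Draws the time series described by a [fixture_spec()] and returns it
#' together with its ground-truth registry. The START image contains the
#' core only; invaders, artifacts and fragmentation appear at their
#' followup timepoints. Rendering is bit-identical for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `dataset` (a [spheroid_dataset()]) and
#'   `truth` (list of data frames: `core`, `invaders`, `artifacts`,
#'   `fragments`).
#' @export
render_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  px <- spec$pixel_size_um
  cr <- spec$core_center_px[1L]; cc <- spec$core_center_px[2L]
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dcore <- sqrt((rowg - cr)^2 + (colg - cc)^2)
  ramp <- spec$ramp_amplitude * (colg - 1) / (nc - 1)
  edge_sd <- spec$core_edge_sigma_um / px
  maxval <- 2^spec$bit_depth - 1

  nt <- length(spec$timepoint_labels)
  frag_registry <- NULL
  set.seed(spec$seed)
  images <- vector("list", nt)
  for (t in seq_len(nt)) {
    r0 <- spec$core_radius_um[t] / px
    img <- spec$background_base + ramp +
      spec$core_intensity * pnorm((r0 - dcore) / edge_sd)
    inv <- spec$invaders
    if (!is.null(inv)) {
      for (i in which(inv$timepoint == t)) {
        s <- inv$sigma_um[i] / px
        d2 <- (rowg - inv$row[i])^2 + (colg - inv$col[i])^2
        img <- img + inv$peak[i] * exp(-d2 / (2 * s^2))
      }
    }
    art <- spec$artifacts
    if (!is.null(art)) {
      for (i in which(art$timepoint == t)) {
        d <- sqrt((rowg - art$row[i])^2 + (colg - art$col[i])^2)
        img <- img + art$intensity[i] *
          pnorm((art$radius_um[i] / px - d) / 1)
      }
    }
    if (spec$fragmentation && t >= 2L && spec$n_fragments > 0L) {
      # detached bright specks just outside the shrunken core rim
      off <- 14 + 5 * (seq_len(spec$n_fragments) - 1) /
        max(1L, spec$n_fragments - 1L)
      pos <- ring_positions(spec$n_fragments, r0 + min(off), r0 + max(off),
                            c(cr, cc), phase = 0.8)
      frad <- spec$fragment_radius_um / px
      for (i in seq_len(spec$n_fragments)) {
        d <- sqrt((rowg - pos$row[i])^2 + (colg - pos$col[i])^2)
        img <- img + spec$core_intensity * pnorm((frad - d) / 1)
      }
      frag_registry <- rbind(frag_registry, data.frame(
        timepoint = t, row = pos$row, col = pos$col, radius_px = frad))
    }
    img <- img + rnorm(nr * nc, sd = spec$noise_sd)
    img <- round(pmin(pmax(img, 0), maxval))
    images[[t]] <- calibrated_image(img, px, spec$timepoint_labels[t],
                                    bit_depth = spec$bit_depth)
  }

  truth_core <- data.frame(
    timepoint = seq_len(nt), timepoint_label = spec$timepoint_labels,
    center_row = cr, center_col = cc,
    radius_px = spec$core_radius_um / px,
    radius_um = spec$core_radius_um)
  truth_inv <- spec$invaders
  if (!is.null(truth_inv) && nrow(truth_inv)) {
    d <- sqrt((truth_inv$row - cr)^2 + (truth_inv$col - cc)^2)
    truth_inv$true_distance_um <-
      (d - spec$core_radius_um[truth_inv$timepoint] / px) * px
  }
  list(dataset = spheroid_dataset(images[[1L]], images[-1L]),
       truth = list(core = truth_core, invaders = truth_inv,
                    artifacts = spec$artifacts, fragments = frag_registry))
}

#' Named fixture presets mirroring typical assay phenotypes
#'
#' Four scenarios spanning the behaviors the analysis must distinguish:
#' \describe{
#'   \item{compact_growth}{A compact spheroid whose core grows
#'     monotonically over three timepoints, with a moderate number of
#'     invaders appearing later (a slowly expanding line).}
#'   \item{disintegrating_invasion}{A rapidly invading spheroid: the core
#'     shrinks to 75 % of its START radius by 24 h, sheds detached bright
#'     fragments at its rim, and 20 invaders appear in the matrix.}
#'   \item{suppressed_invasion}{A nearly static core with only 6 invaders
#'     close to the boundary (a drug-suppressed phenotype).}
#'   \item{artifact_bubble}{The suppressed scenario plus one large uniform
#'     bright disk (radius 60 um) acting as a bubble.}
#' }
#' All presets share the acquisition model: 400 x 400 px at 2.27 um/px,
#' 16-bit, core plateau 60000 counts with a 4.5 um soft edge, invader
#' spots of 200 counts peak amplitude and 10 um sigma, background 500
#' counts with a 40-count linear ramp (20 % of the invader signal) and
#' Gaussian noise of 6 counts (3 % of the invader signal).
#'
#' @param seed Integer seed stored in every preset (default 42).
#' @return Named list of [fixture_spec()] objects.
#' @export
scenario_presets <- function(seed = 42L) {
  ctr <- c(200.5, 200.5)
  spot_sigma <- 10   # um
  peak <- 200
  inv_ring <- function(n, rmin, rmax, t, phase = 0.1) {
    pos <- ring_positions(n, rmin, rmax, ctr, phase)
    data.frame(row = pos$row, col = pos$col, peak = peak,
               sigma_um = spot_sigma, timepoint = t)
  }
  list(
    compact_growth = fixture_spec(
      timepoint_labels = c("START", "24h", "48h"),
      core_radius_um = c(180, 200, 220),
      invaders = rbind(inv_ring(8, 120, 165, 2L),
                       inv_ring(10, 125, 175, 3L, phase = 1.3)),
      seed = seed),
    disintegrating_invasion = fixture_spec(
      timepoint_labels = c("START", "24h"),
      core_radius_um = c(180, 135),
      fragmentation = TRUE, n_fragments = 6L,
      invaders = inv_ring(20, 100, 185, 2L),
      seed = seed),
    suppressed_invasion = fixture_spec(
      timepoint_labels = c("START", "24h"),
      core_radius_um = c(180, 185),
      invaders = inv_ring(6, 98, 118, 2L),
      seed = seed),
    artifact_bubble = fixture_spec(
      timepoint_labels = c("START", "24h"),
      core_radius_um = c(180, 185),
      invaders = inv_ring(6, 98, 118, 2L),
      artifacts = data.frame(row = 84, col = 317, radius_um = 60,
                             intensity = 30000, timepoint = 2L),
      seed = seed))
}

#' Write a rendered fixture to disk
#'
#' Saves every timepoint as a 16-bit grayscale TIFF plus the ground-truth
#' registry as CSV sidecars, so tests, demos and command-line runs can
#' share one artifact.
#'
#' @param fixture Result of [render_fixture()].
#' @param dir Output directory (created if missing).
#' @return List with `start_path`, `followup_paths`, `pixel_size_um` and
#'   `truth_paths`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- dataset_images(fixture$dataset)
  paths <- vapply(imgs, function(im) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_",
                                    im$timepoint_label), ".tif"))
    write_image(im, p)
    p
  }, character(1))
  truth_paths <- character()
  for (nm in names(fixture$truth)) {
    tab <- fixture$truth[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0("truth_", nm, ".csv"))
    write.csv(tab, p, row.names = FALSE)
    truth_paths[nm] <- p
  }
  list(start_path = paths[1L], followup_paths = paths[-1L],
       pixel_size_um = fixture$dataset$pixel_size_um,
       truth_paths = truth_paths)
}
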