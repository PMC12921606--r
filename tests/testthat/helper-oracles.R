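# Independent reference implementations used as test oracles. These share
# no code with the package internals: reconstruction is iterated
# neighborhood dilation, labeling is a plain BFS, the cross-entropy scan
# loops over every level, and disk containment places the disk explicitly.

shift_max8 <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- g
  out <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  out
}

# reconstruction by dilation: iterate g <- min(max(g, dilate(g)), mask)
oracle_reconstruct <- function(marker, mask) {
  g <- pmin(marker, mask)
  repeat {
    g2 <- pmin(pmax(g, shift_max8(g)), mask)
    if (identical(g2, g)) return(g)
    g <- g2
  }
}

# regional maxima via the delta characterization: maxima are where
# reconstructing (g - delta) under g loses height.
oracle_regional_maxima <- function(g) {
  u <- sort(unique(as.vector(g)))
  if (length(u) < 2L) return(matrix(TRUE, nrow(g), ncol(g)))
  delta <- min(diff(u)) / 2
  rec <- oracle_reconstruct(g - delta, g)
  (g - rec) > delta / 2
}

oracle_label8 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!bin[r0, c0] || lab[r0, c0]) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            bin[rr, cc] && !lab[rr, cc]) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: list of sorted pixel-index sets, ordered by
# their smallest member (label numbering conventions drop out)
canonical_components <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, min, numeric(1)))]
}

# extended maxima straight from the definition, using only oracle pieces
oracle_emax_components <- function(px, dynamic) {
  rng <- max(px) - min(px)
  if (rng == 0) return(list())
  h <- dynamic * rng
  hm <- oracle_reconstruct(px - h, px)
  lab <- oracle_label8(oracle_regional_maxima(hm))
  sets <- canonical_components(lab)
  Filter(function(s) length(s) < length(px), sets)
}

# per-level exhaustive scan of the Li cross-entropy objective
oracle_mce <- function(v, levels = as.numeric(0:255)) {
  v <- as.vector(v)
  best_t <- NA_real_; best <- Inf
  for (t in levels) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    mb <- mean(lo); mf <- mean(hi)
    eta <- (if (sum(lo) > 0) -sum(lo) * log(mb) else 0) +
           (if (sum(hi) > 0) -sum(hi) * log(mf) else 0)
    if (eta < best) { best <- eta; best_t <- t }
  }
  best_t
}

# can the pixel set contain a disk of radius r? try every placement
oracle_contains_disk <- function(pixels, r_px) {
  off <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  off <- off[off$dr^2 + off$dc^2 <= r_px^2, ]
  key <- pixels[, 1L] * 100000 + pixels[, 2L]
  for (i in seq_len(nrow(pixels))) {
    cand <- (pixels[i, 1L] + off$dr) * 100000 + (pixels[i, 2L] + off$dc)
    if (all(cand %in% key)) return(TRUE)
  }
  FALSE
}

# 8-connected random-walk blob of about n pixels inside an nr x nc frame
random_blob <- function(nr, nc, n, margin = 2L) {
  r <- sample(seq(margin + 1L, nr - margin), 1L)
  c <- sample(seq(margin + 1L, nc - margin), 1L)
  pix <- matrix(c(r, c), 1L, 2L)
  for (i in seq_len(n)) {
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    r <- min(max(r + step[1L], margin + 1L), nr - margin)
    c <- min(max(c + step[2L], margin + 1L), nc - margin)
    pix <- rbind(pix, c(r, c))
  }
  unique(pix)
}

# small synthetic image builders -------------------------------------------

disk_image <- function(n = 101L, radius = 30, value = 200, bg = 10,
                       pixel_size_um = 1, label = "t") {
  ctr <- (n + 1) / 2
  d2 <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2
  px <- matrix(bg, n, n)
  px[d2 <= radius^2] <- value
  calibrated_image(px, pixel_size_um, label)
}

bump_image <- function(nr, nc, bumps, bg = 10, pixel_size_um = 1,
                       label = "t") {
  px <- matrix(bg, nr, nc)
  rg <- row(px); cg <- col(px)
  for (b in bumps)  # b = c(row, col, peak, sigma)
    px <- px + b[3L] * exp(-((rg - b[1L])^2 + (cg - b[2L])^2) / (2 * b[4L]^2))
  calibrated_image(round(px), pixel_size_um, label)
}

mask_from_grid <- function(grid, pixel_size_um = 1, mode = "compact") {
  spheroid_mask(grid, mode, pixel_size_um)
}

presets_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- scenario_presets()
    cache
  }
})

fixture_cached <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <<- render_fixture(presets_cached()[[name]])
    cache[[name]]
  }
})
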