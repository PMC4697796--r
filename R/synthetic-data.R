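# Synthetic ground truth: nuclei, DSB-derived focus patterns, CSR
# backgrounds, a widefield observation model, and blinking-emitter stacks.
# The generator encodes the generative geometry under study: each DNA
# double-strand break (DSB) yields two resected ends separated by up to
# 400 nm, and each end can carry a side-by-side Rad51/Dmc1 co-focus
# offset by less than the ~200 nm colocalization radius.

#' Parameters of the paired-focus generative model
#'
#' @param n_dsb number of DSBs per nucleus.
#' @param pair_sep_sampler function(n) drawing end-to-end separations, nm.
#'   Default: uniform on \[150, 400\] nm — the pairing band observed above
#'   the ~150 nm detection floor; no parametric form is implied by the
#'   data, so the least-committal bounded choice is used.
#' @param cofocus_offset_sampler function(n) drawing the within-end
#'   Rad51<->Dmc1 offset, nm. Default: uniform on \[0, 150\] nm.
#' @param occupancy named numeric `c(both, rad51_only, dmc1_only, empty)`,
#'   per-end channel occupancy probabilities summing to 1. The default
#'   0.7/0.1/0.1/0.1 makes ~85% of foci carry a cross-channel partner.
#' @param n_background_per_channel CSR background foci per channel.
#' @param intensity_sampler function(n) drawing intensities (a.u. >= 0).
#'   Default: log-normal with median 100 a.u.
#' @return an object of class `pair_model_params`.
#' @export
pair_model_params <- function(n_dsb = 15,
                              pair_sep_sampler = function(n) stats::runif(n, 150, 400),
                              cofocus_offset_sampler = function(n) stats::runif(n, 0, 150),
                              occupancy = c(
                                both = 0.7, rad51_only = 0.1,
                                dmc1_only = 0.1, empty = 0.1
                              ),
                              n_background_per_channel = 0,
                              intensity_sampler = function(n) stats::rlnorm(n, log(100), 0.5)) {
  stopifnot(n_dsb >= 0, n_background_per_channel >= 0)
  occupancy <- occupancy[c("both", "rad51_only", "dmc1_only", "empty")]
  if (any(is.na(occupancy)) || any(occupancy < 0) ||
    abs(sum(occupancy) - 1) > 1e-12) {
    stop_format("occupancy must be nonnegative probabilities (both, rad51_only, dmc1_only, empty) summing to 1")
  }
  structure(
    list(
      n_dsb = as.integer(n_dsb),
      pair_sep_sampler = pair_sep_sampler,
      cofocus_offset_sampler = cofocus_offset_sampler,
      occupancy = occupancy,
      n_background_per_channel = as.integer(n_background_per_channel),
      intensity_sampler = intensity_sampler
    ),
    class = "pair_model_params"
  )
}

#' Make a disc nucleus of a given area
#'
#' Creates a disc with radius `sqrt(area / pi)`, centred so that all
#' coordinates in the region are >= 0 (image convention).
#'
#' @param area_um2 nuclear area, um^2 (> 0).
#' @param nucleus_id identifier.
#' @param stage_label optional free text.
#' @return a [nucleus_record()].
#' @export
make_nucleus <- function(area_um2, nucleus_id = "n1", stage_label = NA_character_) {
  if (!is.finite(area_um2) || area_um2 <= 0) {
    stop_format("area_um2 must be > 0")
  }
  r_nm <- sqrt(area_um2 / pi) * 1e3
  nucleus_record(nucleus_id, region_disc(r_nm, r_nm, r_nm), stage_label)
}

# place a point uniformly in `region` such that both ends of a segment of
# length `sep` at a uniform random orientation stay inside; returns
# list(mid = c(x, y), theta). Errors after `max_tries` rejections.
place_segment_in_region <- function(region, sep, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    mid <- region_sample(region, 1L)
    theta <- stats::runif(1, 0, 2 * pi)
    dx <- sep / 2 * cos(theta)
    dy <- sep / 2 * sin(theta)
    if (region_contains(region, mid[1] + dx, mid[2] + dy) &&
      region_contains(region, mid[1] - dx, mid[2] - dy)) {
      return(list(mid = as.numeric(mid), theta = theta))
    }
  }
  stop_format("nucleus too small: %d consecutive rejections placing a DSB", max_tries)
}

#' Simulate a DSB-derived focus pattern
#'
#' For each DSB a midpoint is placed uniformly in the nuclear region and
#' the two resected ends are put at `+/- sep/2` along a uniform random
#' orientation (rejection-sampled so both ends stay inside the region).
#' Each end independently draws an occupancy class; present channels are
#' offset from the end position by the co-focus offset sampler at a
#' uniform angle. Background foci are CSR per channel. Every record
#' carries truth tags (`dsb_id`, `end_id`, `is_background`); the sampled
#' end positions and separations are attached as attribute `"dsb_truth"`.
#'
#' @param nucleus a [nucleus_record()].
#' @param params a [pair_model_params()].
#' @param seed integer seed or `NULL`.
#' @return a [focus_set()] linked to `nucleus`.
#' @export
simulate_dsb_pattern <- function(nucleus, params = pair_model_params(), seed = NULL) {
  stopifnot(inherits(nucleus, "nucleus_record"), inherits(params, "pair_model_params"))
  with_seed(seed, {
    region <- nucleus$region
    rows <- list()
    truth <- list()
    classes <- names(params$occupancy)
    for (d in seq_len(params$n_dsb)) {
      sep <- params$pair_sep_sampler(1L)
      seg <- place_segment_in_region(region, sep)
      ends <- rbind(
        seg$mid + sep / 2 * c(cos(seg$theta), sin(seg$theta)),
        seg$mid - sep / 2 * c(cos(seg$theta), sin(seg$theta))
      )
      truth[[length(truth) + 1L]] <- data.frame(
        dsb_id = d,
        end1_x_nm = ends[1, 1], end1_y_nm = ends[1, 2],
        end2_x_nm = ends[2, 1], end2_y_nm = ends[2, 2],
        separation_nm = sep
      )
      for (e in 1:2) {
        occ <- sample(classes, 1L, prob = params$occupancy)
        channels <- switch(occ,
          both = c("RAD51", "DMC1"),
          rad51_only = "RAD51",
          dmc1_only = "DMC1",
          empty = character(0)
        )
        for (ch in channels) {
          off <- params$cofocus_offset_sampler(1L)
          phi <- stats::runif(1, 0, 2 * pi)
          rows[[length(rows) + 1L]] <- data.frame(
            nucleus_id = nucleus$nucleus_id, channel = ch,
            x_nm = ends[e, 1] + off * cos(phi),
            y_nm = ends[e, 2] + off * sin(phi),
            intensity = params$intensity_sampler(1L),
            dsb_id = d, end_id = e, is_background = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    for (ch in c("RAD51", "DMC1")) {
      nb <- params$n_background_per_channel
      if (nb > 0L) {
        xy <- region_sample(region, nb)
        rows[[length(rows) + 1L]] <- data.frame(
          nucleus_id = nucleus$nucleus_id, channel = ch,
          x_nm = xy[, 1], y_nm = xy[, 2],
          intensity = params$intensity_sampler(nb),
          dsb_id = NA_integer_, end_id = NA_integer_, is_background = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
    foci <- if (length(rows)) do.call(rbind, rows) else NULL
    out <- focus_set(foci, list(nucleus))
    attr(out, "dsb_truth") <- if (length(truth)) do.call(rbind, truth) else NULL
    out
  })
}

#' Simulate complete spatial randomness (CSR) foci
#'
#' @param nucleus a [nucleus_record()].
#' @param n number of foci.
#' @param channel channel label.
#' @param seed integer seed or `NULL`.
#' @param intensity_sampler function(n) drawing intensities.
#' @return a [focus_set()] linked to `nucleus`.
#' @export
simulate_csr <- function(nucleus, n, channel = "RAD51", seed = NULL,
                         intensity_sampler = function(n) stats::rlnorm(n, log(100), 0.5)) {
  stopifnot(inherits(nucleus, "nucleus_record"), n >= 0)
  with_seed(seed, {
    xy <- region_sample(nucleus$region, n)
    foci <- if (nrow(xy) > 0L) {
      data.frame(
        nucleus_id = nucleus$nucleus_id, channel = channel,
        x_nm = xy[, 1], y_nm = xy[, 2],
        intensity = intensity_sampler(nrow(xy)),
        stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
    focus_set(foci, list(nucleus))
  })
}

#' Simulate a pattern with a known paired fraction
#'
#' Places `round(fraction_paired * n / 2)` pairs of foci at exactly
#' `pair_distance_nm` (uniform random centre and orientation, both
#' members inside the region) and fills the remainder with CSR foci.
#' Used for parameter-recovery and detectability calibrations where the
#' ground-truth paired fraction must be known exactly.
#'
#' @param nucleus a [nucleus_record()].
#' @param n_foci total foci.
#' @param fraction_paired fraction of foci that are members of a pair.
#' @param pair_distance_nm exact pair separation, nm.
#' @param channel channel label.
#' @param seed integer seed or `NULL`.
#' @return a [focus_set()] with logical truth column `is_paired`.
#' @export
simulate_spiked_pattern <- function(nucleus, n_foci, fraction_paired,
                                    pair_distance_nm, channel = "RAD51",
                                    seed = NULL) {
  stopifnot(
    inherits(nucleus, "nucleus_record"),
    fraction_paired >= 0, fraction_paired <= 1, n_foci >= 0
  )
  with_seed(seed, {
    n_pairs <- round(fraction_paired * n_foci / 2)
    n_csr <- n_foci - 2L * n_pairs
    region <- nucleus$region
    xs <- numeric(0)
    ys <- numeric(0)
    paired <- logical(0)
    for (p in seq_len(n_pairs)) {
      seg <- place_segment_in_region(region, pair_distance_nm)
      dx <- pair_distance_nm / 2 * cos(seg$theta)
      dy <- pair_distance_nm / 2 * sin(seg$theta)
      xs <- c(xs, seg$mid[1] + dx, seg$mid[1] - dx)
      ys <- c(ys, seg$mid[2] + dy, seg$mid[2] - dy)
      paired <- c(paired, TRUE, TRUE)
    }
    if (n_csr > 0L) {
      xy <- region_sample(region, n_csr)
      xs <- c(xs, xy[, 1])
      ys <- c(ys, xy[, 2])
      paired <- c(paired, rep(FALSE, n_csr))
    }
    foci <- if (length(xs)) {
      data.frame(
        nucleus_id = nucleus$nucleus_id, channel = channel,
        x_nm = xs, y_nm = ys, intensity = 100,
        is_paired = paired, stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
    focus_set(foci, list(nucleus))
  })
}

#' Simulate a paired super-resolution focus dataset
#'
#' Generates the two-scale pairing geometry against which dSTORM and
#' widefield views are compared: isolated units each consisting of a
#' pair of diffraction-scale foci separated by `wf_sep_nm`, where every
#' such focus is itself a pair of sr foci separated by `sr_sep_nm`
#' (below the widefield resolution limit). Each sr focus is rendered as
#' a Gaussian scatter of localizations. Units are laid out on a jittered
#' grid with random orientations, far enough apart that between-unit
#' distances never compete with the within-unit scales.
#'
#' @param n_units number of paired-focus units.
#' @param wf_sep_nm separation between the two widefield-scale foci of a
#'   unit (default 300).
#' @param sr_sep_nm separation between the two sr foci within each
#'   widefield focus (default 100).
#' @param locs_per_sr localizations per sr focus (default 30).
#' @param loc_sigma_nm localization scatter per sr focus (default 15).
#' @param spacing_nm grid spacing between units (default 2500).
#' @param seed integer seed or `NULL`.
#' @return list with `locs` (a [localization_set()]), `widefield_xy`
#'   (matrix of the widefield-scale focus centres), and `sr_truth`
#'   (matrix of true sr-focus centres).
#' @export
simulate_sr_pair_dataset <- function(n_units = 25, wf_sep_nm = 300,
                                     sr_sep_nm = 100, locs_per_sr = 30,
                                     loc_sigma_nm = 15, spacing_nm = 2500,
                                     seed = NULL) {
  with_seed(seed, {
    n_side <- ceiling(sqrt(n_units))
    wf <- list()
    sr <- list()
    lx <- ly <- lframe <- numeric(0)
    u <- 0L
    for (gy in seq_len(n_side)) {
      for (gx in seq_len(n_side)) {
        if (u >= n_units) break
        u <- u + 1L
        centre <- c(gx, gy) * spacing_nm +
          stats::runif(2, -spacing_nm / 8, spacing_nm / 8)
        th <- stats::runif(1, 0, 2 * pi)
        for (s in c(-1, 1)) {
          wf_pos <- centre + s * wf_sep_nm / 2 * c(cos(th), sin(th))
          wf[[length(wf) + 1L]] <- wf_pos
          phi <- stats::runif(1, 0, 2 * pi)
          for (t in c(-1, 1)) {
            sr_pos <- wf_pos + t * sr_sep_nm / 2 * c(cos(phi), sin(phi))
            sr[[length(sr) + 1L]] <- sr_pos
            lx <- c(lx, stats::rnorm(locs_per_sr, sr_pos[1], loc_sigma_nm))
            ly <- c(ly, stats::rnorm(locs_per_sr, sr_pos[2], loc_sigma_nm))
          }
        }
      }
    }
    n <- length(lx)
    list(
      locs = localization_set(
        x_nm = lx, y_nm = ly, frame = seq_len(n) - 1L,
        photons = rep(1000, n), fwhm_nm = rep(180, n)
      ),
      widefield_xy = do.call(rbind, wf),
      sr_truth = do.call(rbind, sr)
    )
  })
}

# ---- resolution censoring --------------------------------------------

# merge the closest sub-threshold pair of a coordinate/intensity set until
# all pairwise distances are >= d_min; deterministic (closest pair first,
# ties broken by lexicographic coordinate order of the pair).
censor_points <- function(xy, intensity, d_min) {
  repeat {
    n <- nrow(xy)
    if (n < 2L) break
    d <- cross_dist(xy, xy)
    d[!upper.tri(d)] <- Inf
    dmin <- min(d)
    if (dmin >= d_min) break
    hits <- which(d == dmin, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      # order each candidate pair's members lexicographically, then order
      # candidates by the concatenated coordinates
      key <- t(apply(hits, 1, function(ij) {
        a <- xy[ij[1], ]
        b <- xy[ij[2], ]
        if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b) else c(b, a)
      }))
      hits <- hits[do.call(order, as.data.frame(key))[1], , drop = FALSE]
    }
    i <- hits[1, 1]
    j <- hits[1, 2]
    w <- intensity[c(i, j)]
    if (sum(w) <= 0) w <- c(1, 1) # zero-intensity pair: plain midpoint
    merged <- colSums(xy[c(i, j), , drop = FALSE] * w) / sum(w)
    xy <- rbind(xy[-c(i, j), , drop = FALSE], merged)
    intensity <- c(intensity[-c(i, j)], intensity[i] + intensity[j])
  }
  list(xy = xy, intensity = intensity)
}

#' Apply the widefield resolution censor
#'
#' Models the observation floor of widefield focus scoring: within each
#' (nucleus, channel) group, the closest pair of foci at distance below
#' `d_min_nm` is iteratively replaced by a single focus at their
#' intensity-weighted centroid (intensity summed) until all pairwise
#' distances are >= `d_min_nm`. Total intensity is conserved. Truth tag
#' columns do not survive merging and are dropped.
#'
#' @param x a [focus_set()].
#' @param d_min_nm observation floor, nm (default 150).
#' @return a censored [focus_set()].
#' @export
apply_resolution_censor <- function(x, d_min_nm = 150) {
  stopifnot(inherits(x, "focus_set"))
  f <- x$foci
  out <- list()
  for (nid in unique(f$nucleus_id)) {
    for (ch in unique(f$channel[f$nucleus_id == nid])) {
      g <- f[f$nucleus_id == nid & f$channel == ch, , drop = FALSE]
      res <- censor_points(as.matrix(g[, c("x_nm", "y_nm")]), g$intensity, d_min_nm)
      out[[length(out) + 1L]] <- data.frame(
        nucleus_id = nid, channel = ch,
        x_nm = res$xy[, 1], y_nm = res$xy[, 2],
        intensity = res$intensity, stringsAsFactors = FALSE
      )
    }
  }
  focus_set(if (length(out)) do.call(rbind, out) else NULL, x$nuclei)
}

# ---- widefield rendering ---------------------------------------------

# per-pixel mass of a 1-D Gaussian integrated over pixel bins
# edges: (0, 1, ..., n) * px ; returns the vector of bin masses
gauss_bin_mass <- function(mu, sigma, n_px, px) {
  edges <- (0:n_px) * px
  p <- stats::pnorm(edges, mean = mu, sd = sigma)
  diff(p)
}

#' Render a widefield image of a focus set
#'
#' Each focus contributes `intensity` times an isotropic Gaussian point
#' spread function integrated over pixel bins, on top of a constant
#' background; optional Poisson noise models the camera.
#'
#' @param x a [focus_set()].
#' @param psf_sigma_nm PSF standard deviation, nm (default 110,
#'   approximating a 100x widefield system at 100 nm pixels).
#' @param pixel_size_nm pixel size, nm.
#' @param background_mean constant background per pixel.
#' @param poisson_noise if `TRUE`, pixel values are Poisson draws.
#' @param seed integer seed (used only when `poisson_noise`).
#' @param bounds optional `c(width_nm, height_nm)`; defaults to the
#'   nuclei bounding boxes (or foci extent + 4 sigma) padded to pixels.
#' @return a single-frame [frame_stack()].
#' @export
render_widefield <- function(x, psf_sigma_nm = 110, pixel_size_nm = 100,
                             background_mean = 0, poisson_noise = FALSE,
                             seed = NULL, bounds = NULL) {
  stopifnot(inherits(x, "focus_set"))
  f <- x$foci
  if (is.null(bounds)) {
    if (!is.null(x$nuclei) && length(x$nuclei) > 0L) {
      bbs <- vapply(x$nuclei, function(n) region_bbox(n$region), numeric(4))
      bounds <- c(max(bbs["xmax", ]), max(bbs["ymax", ]))
    } else if (nrow(f) > 0L) {
      bounds <- c(max(f$x_nm), max(f$y_nm)) + 4 * psf_sigma_nm
    } else {
      bounds <- c(10, 10) * pixel_size_nm
    }
  }
  w_px <- max(1L, as.integer(ceiling(bounds[1] / pixel_size_nm)))
  h_px <- max(1L, as.integer(ceiling(bounds[2] / pixel_size_nm)))
  img <- matrix(background_mean, nrow = h_px, ncol = w_px)
  for (k in seq_len(nrow(f))) {
    mx <- gauss_bin_mass(f$x_nm[k], psf_sigma_nm, w_px, pixel_size_nm)
    my <- gauss_bin_mass(f$y_nm[k], psf_sigma_nm, h_px, pixel_size_nm)
    img <- img + f$intensity[k] * (my %o% mx)
  }
  if (poisson_noise) {
    img <- with_seed(seed, matrix(
      stats::rpois(length(img), img),
      nrow = h_px, ncol = w_px
    ))
  }
  frame_stack(img, pixel_size_nm, background_mean)
}

# ---- blinking emitters ------------------------------------------------

#' Blinking-emitter model
#'
#' Fixed emitter positions with a two-state photoswitching model: in each
#' frame every emitter is on independently with probability `p_on` and,
#' when on, emits a Poisson number of photons spread over the PSF.
#'
#' @param positions n x 2 matrix of emitter positions (`x_nm`, `y_nm`).
#' @param p_on per-frame on-probability, in (0, 1\].
#' @param photons_mean mean photons per on-event.
#' @param psf_sigma_nm PSF standard deviation, nm.
#' @param background_rate mean background photons per pixel per frame.
#' @return an object of class `emitter_model`.
#' @export
emitter_model <- function(positions, p_on, photons_mean = 800,
                          psf_sigma_nm = 130, background_rate = 1) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2L)
  if (!(p_on > 0 && p_on <= 1)) stop_format("p_on must be in (0, 1]")
  if (photons_mean <= 0) stop_format("photons_mean must be > 0")
  structure(
    list(
      positions = positions, p_on = p_on, photons_mean = photons_mean,
      psf_sigma_nm = psf_sigma_nm, background_rate = background_rate
    ),
    class = "emitter_model"
  )
}

#' Emitter positions for a point cluster
#'
#' Isotropic Gaussian scatter of labelling sites around a centre,
#' modelling an immunostained focus. A finite `truncate_sigma` bounds
#' the scatter (rejection-sampled truncated normal), reflecting the
#' finite physical footprint of a labelled structure. Uses the current
#' RNG stream.
#'
#' @param center `c(x_nm, y_nm)`.
#' @param sigma_nm scatter, nm.
#' @param count number of emitters.
#' @param truncate_sigma radial truncation in sigmas (default `Inf`,
#'   i.e. untruncated).
#' @return a `count` x 2 position matrix.
#' @export
emitters_point_cluster <- function(center, sigma_nm, count, truncate_sigma = Inf) {
  draw <- function(n) {
    cbind(
      stats::rnorm(n, 0, sigma_nm),
      stats::rnorm(n, 0, sigma_nm)
    )
  }
  xy <- draw(count)
  if (is.finite(truncate_sigma)) {
    rmax <- truncate_sigma * sigma_nm
    repeat {
      bad <- which(sqrt(rowSums(xy^2)) > rmax)
      if (length(bad) == 0L) break
      xy[bad, ] <- draw(length(bad))
    }
  }
  cbind(x_nm = center[1] + xy[, 1], y_nm = center[2] + xy[, 2])
}

#' Emitter positions along a filament segment
#'
#' Poisson-distributed labelling along a line segment at a given density,
#' modelling an extended nucleoprotein filament. Uses the current stream.
#'
#' @param p0,p1 segment endpoints `c(x_nm, y_nm)`.
#' @param density_per_nm mean labels per nm (> 0).
#' @param lateral_sigma_nm isotropic label displacement off the axis, nm.
#' @return a position matrix.
#' @export
emitters_filament <- function(p0, p1, density_per_nm, lateral_sigma_nm = 0) {
  if (density_per_nm <= 0) stop_format("density_per_nm must be > 0")
  len <- sqrt(sum((p1 - p0)^2))
  n <- stats::rpois(1, len * density_per_nm)
  t <- stats::runif(n)
  pos <- cbind(
    x_nm = p0[1] + t * (p1[1] - p0[1]),
    y_nm = p0[2] + t * (p1[2] - p0[2])
  )
  if (lateral_sigma_nm > 0 && n > 0) {
    pos <- pos + matrix(stats::rnorm(2 * n, 0, lateral_sigma_nm), ncol = 2)
  }
  pos
}

#' Simulate a dSTORM blink stack
#'
#' Per frame, each emitter switches on independently with `p_on`; on
#' emitters contribute `Poisson(photons_mean)` photons rendered through
#' the Gaussian PSF (pixel-integrated, as in [render_widefield()]);
#' Poisson background is added per pixel. The per-frame on-states of
#' every emitter are returned as ground truth.
#'
#' @param model an [emitter_model()].
#' @param n_frames number of frames (>= 1).
#' @param pixel_size_nm camera pixel size, nm.
#' @param seed integer seed or `NULL`.
#' @param bounds optional `c(width_nm, height_nm)`; defaults to the
#'   emitter extent padded by 6 PSF sigma.
#' @param shot_noise if `TRUE`, per-pixel Poisson shot noise is applied
#'   to the rendered signal (default `FALSE`: the expected PSF profile
#'   is rendered and only the background fluctuates).
#' @return list with elements `stack` (a [frame_stack()]) and `truth`
#'   (an `n_frames` x n_emitters logical on-state matrix).
#' @export
simulate_blink_stack <- function(model, n_frames, pixel_size_nm = 100,
                                 seed = NULL, bounds = NULL,
                                 shot_noise = FALSE) {
  stopifnot(inherits(model, "emitter_model"), n_frames >= 1)
  with_seed(seed, {
    pos <- model$positions
    pad <- 6 * model$psf_sigma_nm
    if (is.null(bounds)) {
      bounds <- c(max(pos[, 1]) + pad, max(pos[, 2]) + pad)
    }
    w_px <- as.integer(ceiling(bounds[1] / pixel_size_nm))
    h_px <- as.integer(ceiling(bounds[2] / pixel_size_nm))
    n_em <- nrow(pos)
    # precompute each emitter's pixel-integrated PSF mass (restricted to
    # a +/- 5 sigma index window for speed)
    halfw <- ceiling(5 * model$psf_sigma_nm / pixel_size_nm)
    masses <- vector("list", n_em)
    for (e in seq_len(n_em)) {
      cx <- as.integer(ceiling(pos[e, 1] / pixel_size_nm))
      cy <- as.integer(ceiling(pos[e, 2] / pixel_size_nm))
      ix <- max(1L, cx - halfw):min(w_px, cx + halfw)
      iy <- max(1L, cy - halfw):min(h_px, cy + halfw)
      px_mass_x <- diff(stats::pnorm(c(ix[1] - 1L, ix) * pixel_size_nm,
        mean = pos[e, 1], sd = model$psf_sigma_nm
      ))
      px_mass_y <- diff(stats::pnorm(c(iy[1] - 1L, iy) * pixel_size_nm,
        mean = pos[e, 2], sd = model$psf_sigma_nm
      ))
      masses[[e]] <- list(ix = ix, iy = iy, m = px_mass_y %o% px_mass_x)
    }
    frames <- array(0, dim = c(h_px, w_px, n_frames))
    truth <- matrix(FALSE, nrow = n_frames, ncol = n_em)
    npx <- h_px * w_px
    for (f in seq_len(n_frames)) {
      on <- stats::runif(n_em) < model$p_on
      truth[f, ] <- on
      img <- matrix(0, nrow = h_px, ncol = w_px)
      for (e in which(on)) {
        ph <- stats::rpois(1, model$photons_mean)
        m <- masses[[e]]
        img[m$iy, m$ix] <- img[m$iy, m$ix] + ph * m$m
      }
      if (shot_noise) {
        img <- matrix(stats::rpois(npx, img), nrow = h_px, ncol = w_px)
      }
      if (model$background_rate > 0) {
        img <- img + stats::rpois(npx, model$background_rate)
      }
      frames[, , f] <- img
    }
    list(
      stack = frame_stack(frames, pixel_size_nm, model$background_rate),
      truth = truth
    )
  })
}
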