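# Core domain containers: nuclei, focus sets, localization sets, frame
# stacks, and the analysis configuration that holds the distance
# thresholds shared across the pipeline.

FOCUS_CHANNELS <- c("RAD51", "DMC1", "ZIP1", "OTHER")

#' Per-nucleus record
#'
#' Bundles a nucleus identifier with the planar region of its spread
#' chromatin, which serves as the sampling domain for matched random
#' (CSR) simulations. The area is derived from the region geometry.
#'
#' @param nucleus_id character scalar.
#' @param region a [region_disc()] or [region_polygon()].
#' @param stage_label optional free text (timepoint, genotype, ...).
#' @return an object of class `nucleus_record`.
#' @export
nucleus_record <- function(nucleus_id, region, stage_label = NA_character_) {
  stopifnot(is.character(nucleus_id), length(nucleus_id) == 1L)
  if (!inherits(region, "region")) {
    stop_format("region must be a 'region' object")
  }
  structure(
    list(
      nucleus_id = nucleus_id,
      region = region,
      area_um2 = region_area_um2(region),
      stage_label = stage_label
    ),
    class = "nucleus_record"
  )
}

#' @export
print.nucleus_record <- function(x, ...) {
  cat(sprintf(
    "<nucleus %s: %s region, %.2f um^2>\n",
    x$nucleus_id, x$region$type, x$area_um2
  ))
  invisible(x)
}

#' Focus set
#'
#' A collection of focus centroids grouped by (nucleus, channel), with an
#' optional link to the per-nucleus regions. Coordinates are continuous
#' nm in image convention (origin top-left, y increasing downward).
#'
#' @param foci data.frame with columns `nucleus_id`, `channel`, `x_nm`,
#'   `y_nm`, `intensity`; extra columns (e.g. synthetic truth tags
#'   `dsb_id`, `end_id`, `is_background`) are preserved.
#' @param nuclei optional named list of [nucleus_record()]s (or a list that
#'   is named here by the records' own ids). When present, every focus
#'   `nucleus_id` must resolve to a record.
#' @return an object of class `focus_set`.
#' @export
focus_set <- function(foci = NULL, nuclei = NULL) {
  if (is.null(foci)) {
    foci <- data.frame(
      nucleus_id = character(0), channel = character(0),
      x_nm = numeric(0), y_nm = numeric(0), intensity = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  required <- c("nucleus_id", "channel", "x_nm", "y_nm", "intensity")
  missing <- setdiff(required, names(foci))
  if (length(missing) > 0L) {
    stop_format("foci table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  foci$nucleus_id <- as.character(foci$nucleus_id)
  foci$channel <- as.character(foci$channel)
  bad_chan <- setdiff(unique(foci$channel), FOCUS_CHANNELS)
  if (length(bad_chan) > 0L) {
    stop_format(
      "unknown channel label(s): %s (allowed: %s)",
      paste(bad_chan, collapse = ", "), paste(FOCUS_CHANNELS, collapse = ", ")
    )
  }
  if (!all(is.finite(foci$x_nm)) || !all(is.finite(foci$y_nm))) {
    stop_format("focus coordinates must be finite")
  }
  if (any(!is.finite(foci$intensity)) || any(foci$intensity < 0)) {
    bad <- which(!is.finite(foci$intensity) | foci$intensity < 0)[1]
    stop_format("focus intensity must be finite and >= 0 (first bad row: %d)", bad)
  }
  if (!is.null(nuclei)) {
    if (inherits(nuclei, "nucleus_record")) nuclei <- list(nuclei)
    names(nuclei) <- vapply(nuclei, function(n) n$nucleus_id, character(1))
    unresolved <- setdiff(unique(foci$nucleus_id), names(nuclei))
    if (length(unresolved) > 0L) {
      stop_format(
        "focus nucleus_id(s) with no nucleus record: %s",
        paste(unresolved, collapse = ", ")
      )
    }
  }
  # stable grouping by (nucleus, channel), preserving row order within groups
  ord <- order(match(foci$nucleus_id, unique(foci$nucleus_id)),
    match(foci$channel, FOCUS_CHANNELS),
    method = "radix"
  )
  foci <- foci[ord, , drop = FALSE]
  rownames(foci) <- NULL
  structure(list(foci = foci, nuclei = nuclei), class = "focus_set")
}

#' @export
print.focus_set <- function(x, ...) {
  tab <- table(x$foci$channel)
  cat(sprintf(
    "<focus_set: %d foci in %d nuclei%s>\n",
    nrow(x$foci), length(unique(x$foci$nucleus_id)),
    if (length(tab)) paste0(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")") else ""
  ))
  invisible(x)
}

#' Number of foci in a focus set
#' @param x a `focus_set`.
#' @export
n_foci <- function(x) nrow(x$foci)

#' Subset a focus set by channel and/or nucleus
#'
#' @param x a `focus_set`.
#' @param channel optional channel label(s) to keep.
#' @param nucleus_id optional nucleus id(s) to keep.
#' @return a `focus_set` (nucleus links are preserved).
#' @export
subset_foci <- function(x, channel = NULL, nucleus_id = NULL) {
  keep <- rep(TRUE, nrow(x$foci))
  if (!is.null(channel)) keep <- keep & x$foci$channel %in% channel
  if (!is.null(nucleus_id)) keep <- keep & x$foci$nucleus_id %in% nucleus_id
  focus_set(x$foci[keep, , drop = FALSE], x$nuclei)
}

#' Analysis configuration
#'
#' Distance thresholds and binning shared by the analysis stages. The
#' defaults follow the conventions of widefield focus scoring on spread
#' nuclei: a 400 nm pairing window, a 200 nm two-channel colocalization
#' radius, a ~150 nm observation floor below which two foci of the same
#' channel merge, a 1 um single-linkage radius defining a cytological
#' complex, and a 0.8 foci/um^2 low-density cut.
#'
#' @param pair_window_nm pairing window, nm.
#' @param coloc_radius_nm cross-channel colocalization radius, nm.
#' @param resolution_censor_nm same-channel observation floor, nm.
#' @param cluster_link_nm single-linkage radius for cytological complexes, nm.
#' @param density_threshold_per_um2 low-density nucleus cut, foci per um^2.
#' @param nn_bin_width_nm histogram bin width, nm.
#' @param nn_max_nm histogram range upper limit, nm (beyond it, overflow).
#' @param rng_seed optional integer seed recorded with results.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(pair_window_nm = 400,
                            coloc_radius_nm = 200,
                            resolution_censor_nm = 150,
                            cluster_link_nm = 1000,
                            density_threshold_per_um2 = 0.8,
                            nn_bin_width_nm = 50,
                            nn_max_nm = 2000,
                            rng_seed = NULL) {
  lens <- c(
    pair_window_nm, coloc_radius_nm, resolution_censor_nm,
    cluster_link_nm, nn_bin_width_nm, nn_max_nm
  )
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop_format("all config lengths must be positive and finite")
  }
  if (pair_window_nm < coloc_radius_nm) {
    stop_format("pair_window_nm must be >= coloc_radius_nm")
  }
  structure(
    list(
      pair_window_nm = pair_window_nm,
      coloc_radius_nm = coloc_radius_nm,
      resolution_censor_nm = resolution_censor_nm,
      cluster_link_nm = cluster_link_nm,
      density_threshold_per_um2 = density_threshold_per_um2,
      nn_bin_width_nm = nn_bin_width_nm,
      nn_max_nm = nn_max_nm,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}

# ---- focus table I/O --------------------------------------------------

#' Read a focus table (TSV)
#'
#' Expects a tab-separated table with header columns `nucleus_id`,
#' `channel`, `x_nm`, `y_nm`, `intensity`; extra columns are preserved as
#' tags. Decimal separator is ".", no locale handling.
#'
#' @param path file path or connection.
#' @param nuclei optional named list of [nucleus_record()]s to link.
#' @return a [focus_set()].
#' @export
read_focus_table <- function(path, nuclei = NULL) {
  tab <- utils::read.delim(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  required <- c("nucleus_id", "channel", "x_nm", "y_nm", "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_format("focus table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in c("x_nm", "y_nm", "intensity")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L) {
        stop_format("non-numeric value in column '%s' at data row %d", col, bad[1])
      }
      tab[[col]] <- num
    }
  }
  bad_int <- which(tab$intensity < 0)
  if (length(bad_int) > 0L) {
    stop_format("negative intensity at data row %d", bad_int[1])
  }
  focus_set(tab, nuclei)
}

#' Write a focus table (TSV)
#'
#' Lossless, deterministic column order: the mandatory columns first,
#' then any tag columns in their stored order. `read_focus_table()` on
#' the output reproduces the input focus set field-for-field.
#'
#' @param x a `focus_set`.
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_focus_table <- function(x, path) {
  stopifnot(inherits(x, "focus_set"))
  required <- c("nucleus_id", "channel", "x_nm", "y_nm", "intensity")
  extras <- setdiff(names(x$foci), required)
  tab <- x$foci[, c(required, extras), drop = FALSE]
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

# ---- localization table I/O ------------------------------------------

#' Localization set
#'
#' dSTORM events: planar position, frame of origin, photon count and the
#' fitted spot width (FWHM). The container is a classed data.frame sorted
#' by frame then x.
#'
#' @param x_nm,y_nm positions, nm.
#' @param frame integer frame index, >= 0.
#' @param photons photon count, > 0.
#' @param fwhm_nm fitted spot FWHM, nm, > 0.
#' @param extra optional data.frame of additional per-event columns
#'   (e.g. synthetic truth tags), recycled/ordered with the events.
#' @return an object of class `localization_set` (a data.frame).
#' @export
localization_set <- function(x_nm = numeric(0), y_nm = numeric(0),
                             frame = integer(0), photons = numeric(0),
                             fwhm_nm = numeric(0), extra = NULL) {
  df <- data.frame(
    x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
    frame = as.integer(frame), photons = as.numeric(photons),
    fwhm_nm = as.numeric(fwhm_nm), stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  if (nrow(df) > 0L) {
    if (any(df$photons <= 0)) stop_format("photons must be > 0")
    if (any(df$fwhm_nm <= 0)) stop_format("fwhm_nm must be > 0")
    if (any(df$frame < 0)) stop_format("frame index must be >= 0")
    df <- df[order(df$frame, df$x_nm, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("localization_set", "data.frame")
  df
}

#' Read a localization table (TSV)
#'
#' Columns `x_nm`, `y_nm`, `frame`, `photons`, `fwhm_nm` (the common SMLM
#' export dialect). Records are sorted by frame then x.
#'
#' @param path file path or connection.
#' @return a [localization_set()].
#' @export
read_localization_table <- function(path) {
  tab <- utils::read.delim(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  required <- c("x_nm", "y_nm", "frame", "photons", "fwhm_nm")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_format("localization table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  extras <- setdiff(names(tab), required)
  localization_set(
    tab$x_nm, tab$y_nm, tab$frame, tab$photons, tab$fwhm_nm,
    extra = if (length(extras)) tab[, extras, drop = FALSE] else NULL
  )
}

#' Write a localization table (TSV)
#' @param x a `localization_set`.
#' @param path file path or connection.
#' @export
write_localization_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

# ---- frame stack ------------------------------------------------------

#' Image frame stack
#'
#' A stack of camera frames stored as a 3-D array `[row, col, frame]`
#' with a physical pixel size. Pixel `(i, j)` has its centre at
#' `((j - 0.5) * pixel_size_nm, (i - 0.5) * pixel_size_nm)` in the nm
#' coordinate frame (x right, y down).
#'
#' @param frames numeric array `[height_px, width_px, n_frames]` (a matrix
#'   is treated as a single frame); all intensities must be >= 0.
#' @param pixel_size_nm physical pixel size, nm (> 0).
#' @param background_mean mean background level recorded with the stack.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_nm = 100, background_mean = 0) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(nrow(frames), ncol(frames), 1L))
  }
  stopifnot(length(dim(frames)) == 3L)
  if (any(frames < 0)) stop_format("frame intensities must be >= 0")
  if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop_format("pixel_size_nm must be > 0")
  }
  structure(
    list(
      frames = frames,
      pixel_size_nm = pixel_size_nm,
      background_mean = background_mean
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack: %d x %d px, %d frame(s), %g nm/px>\n",
    d[2], d[1], d[3], x$pixel_size_nm
  ))
  invisible(x)
}
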