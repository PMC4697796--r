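# Nearest-neighbour (NN) distance statistics: per-nucleus NN distances,
# binned distributions, matched CSR nulls, pairing enrichment, the
# density/sparseness focus filters, and the subpopulation detectability
# bound.

#' Nearest-neighbour distances, pooled across nuclei
#'
#' For every focus in `from` that has at least one eligible neighbour,
#' the distance to the nearest neighbour is measured within the same
#' nucleus; measurements from all nuclei are pooled. In same-set mode
#' (`to = NULL`) the focus itself is excluded and nuclei contributing
#' fewer than two foci contribute nothing; in cross-set mode nuclei with
#' an empty `to` set contribute nothing.
#'
#' @param from a [focus_set()] (typically one channel, see [subset_foci()]).
#' @param to a second [focus_set()] for cross-channel mode, or `NULL`.
#' @return numeric vector of distances, nm.
#' @export
nn_distances <- function(from, to = NULL) {
  stopifnot(inherits(from, "focus_set"))
  same <- is.null(to)
  if (!same) {
    stopifnot(inherits(to, "focus_set"))
    check_nucleus_linkage(from, to)
  }
  f <- from$foci
  t_f <- if (same) f else to$foci
  out <- numeric(0)
  for (nid in unique(f$nucleus_id)) {
    a <- as.matrix(f[f$nucleus_id == nid, c("x_nm", "y_nm"), drop = FALSE])
    b <- as.matrix(t_f[t_f$nucleus_id == nid, c("x_nm", "y_nm"), drop = FALSE])
    if (same) {
      if (nrow(a) < 2L) next
      out <- c(out, nn_dist_chunked(a, a, exclude_self = TRUE))
    } else {
      if (nrow(b) < 1L || nrow(a) < 1L) next
      out <- c(out, nn_dist_chunked(a, b, exclude_self = FALSE))
    }
  }
  out
}

# two focus sets sharing nuclei must agree on the nucleus records
check_nucleus_linkage <- function(a, b) {
  if (is.null(a$nuclei) || is.null(b$nuclei)) {
    return(invisible(TRUE))
  }
  shared <- intersect(names(a$nuclei), names(b$nuclei))
  for (nid in shared) {
    if (!isTRUE(all.equal(
      a$nuclei[[nid]]$area_um2,
      b$nuclei[[nid]]$area_um2
    ))) {
      stop_format("mismatched nucleus linkage for nucleus '%s'", nid)
    }
  }
  invisible(TRUE)
}

#' Bin nearest-neighbour distances
#'
#' Right-open uniform bins `[k w, (k+1) w)` from 0 to `nn_max_nm`, with
#' an overflow count beyond the range.
#'
#' @param distances numeric distances, nm (>= 0).
#' @param config an [analysis_config()] (bin width and range).
#' @param label free-text label stored with the distribution.
#' @return an object of class `nn_distribution`.
#' @export
nn_histogram <- function(distances, config = analysis_config(), label = "") {
  if (any(distances < 0)) stop_format("distances must be >= 0")
  w <- config$nn_bin_width_nm
  edges <- seq(0, config$nn_max_nm, by = w)
  nbin <- length(edges) - 1L
  idx <- floor(distances / w) + 1L
  counts <- tabulate(idx[idx <= nbin], nbins = nbin)
  structure(
    list(
      bin_edges = edges,
      counts = counts,
      overflow = sum(idx > nbin),
      n_total = length(distances),
      raw_distances = distances,
      label = label
    ),
    class = "nn_distribution"
  )
}

#' @export
print.nn_distribution <- function(x, ...) {
  cat(sprintf(
    "<nn_distribution%s: n = %d, %d bins of %g nm (+%d overflow)>\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    x$n_total, length(x$counts), diff(x$bin_edges[1:2]), x$overflow
  ))
  invisible(x)
}

# per-bin fractions (overflow appended last)
nn_fractions <- function(d) {
  if (d$n_total == 0L) {
    return(rep(0, length(d$counts) + 1L))
  }
  c(d$counts, d$overflow) / d$n_total
}

#' Matched CSR null nearest-neighbour distribution
#'
#' For each replicate and each nucleus, the same number of foci as
#' observed in `channel` is placed uniformly at random within that
#' nucleus's region; with `censor = TRUE` the widefield observation
#' floor ([apply_resolution_censor()]) is applied before measurement, so
#' the null embeds the same resolution limit as the data. NN distances
#' are pooled over nuclei and replicates (so nuclei are weighted by their
#' focus counts, as in pooling of the observed data); per-replicate bin
#' fractions are retained for Monte-Carlo standard errors.
#'
#' @param observed a [focus_set()] with nucleus records.
#' @param channel channel whose per-nucleus counts are matched.
#' @param to_channel for cross-channel nulls: the target channel, also
#'   re-randomized at its observed counts. `NULL` for same-channel mode.
#' @param reps number of null replicates.
#' @param censor apply the resolution censor to each replicate.
#' @param config an [analysis_config()].
#' @param seed integer seed or `NULL`.
#' @return an `nn_distribution` with extra fields `rep_fracs` (reps x
#'   bins matrix, overflow last) and `frac` (mean per-replicate fraction).
#' @export
simulate_matched_null <- function(observed, channel = "RAD51",
                                  to_channel = NULL, reps = 100,
                                  censor = TRUE,
                                  config = analysis_config(), seed = NULL) {
  stopifnot(inherits(observed, "focus_set"))
  if (is.null(observed$nuclei) || length(observed$nuclei) == 0L) {
    stop_format("matched null requires nucleus records with regions")
  }
  f <- observed$foci
  nids <- unique(f$nucleus_id)
  counts_from <- vapply(
    nids,
    function(n) sum(f$nucleus_id == n & f$channel == channel), integer(1)
  )
  cross <- !is.null(to_channel)
  counts_to <- if (cross) {
    vapply(
      nids,
      function(n) sum(f$nucleus_id == n & f$channel == to_channel), integer(1)
    )
  }
  d_min <- config$resolution_censor_nm
  with_seed(seed, {
    all_d <- vector("list", reps)
    for (r in seq_len(reps)) {
      dd <- numeric(0)
      for (i in seq_along(nids)) {
        region <- observed$nuclei[[nids[i]]]$region
        a <- region_sample(region, counts_from[i])
        if (censor && nrow(a) > 1L) {
          a <- censor_points(a, rep(1, nrow(a)), d_min)$xy
        }
        if (!cross) {
          if (nrow(a) < 2L) next
          dd <- c(dd, nn_dist_chunked(a, a, exclude_self = TRUE))
        } else {
          b <- region_sample(region, counts_to[i])
          if (censor && nrow(b) > 1L) {
            b <- censor_points(b, rep(1, nrow(b)), d_min)$xy
          }
          if (nrow(a) < 1L || nrow(b) < 1L) next
          dd <- c(dd, nn_dist_chunked(a, b, exclude_self = FALSE))
        }
      }
      all_d[[r]] <- dd
    }
    pooled <- unlist(all_d)
    out <- nn_histogram(pooled, config, label = sprintf(
      "CSR null (%s%s, %d reps, censor %s)",
      channel, if (cross) paste0("->", to_channel) else "", reps,
      if (censor) "on" else "off"
    ))
    rep_fracs <- t(vapply(
      all_d,
      function(d) nn_fractions(nn_histogram(d, config)),
      numeric(length(out$counts) + 1L)
    ))
    out$rep_fracs <- rep_fracs
    out$frac <- colMeans(rep_fracs)
    out$n_reps <- reps
    out
  })
}

#' Pairing enrichment against a matched null
#'
#' Per-bin excess frequency (observed fraction minus null fraction) and
#' the paired-fraction estimate: the sum of positive excess over all
#' bins whose upper edge is within the pairing window.
#'
#' @param observed an `nn_distribution` of the data.
#' @param null an `nn_distribution` from [simulate_matched_null()]
#'   (identical binning required).
#' @param config an [analysis_config()] (pairing window).
#' @return an object of class `enrichment_result`: a per-bin table
#'   (`bin_lo_nm`, `bin_hi_nm`, `observed_fraction`, `null_fraction`,
#'   `excess`, `mc_se`; the last row is the overflow bin) plus fields
#'   `p_hat`, `window_nm`, `n_reps`.
#' @export
pairing_enrichment <- function(observed, null, config = analysis_config()) {
  stopifnot(inherits(observed, "nn_distribution"), inherits(null, "nn_distribution"))
  if (!isTRUE(all.equal(observed$bin_edges, null$bin_edges))) {
    stop_format("observed and null distributions have different binning")
  }
  obs_frac <- nn_fractions(observed)
  null_frac <- null$frac %||% nn_fractions(null)
  excess <- obs_frac - null_frac
  n_reps <- null$n_reps %||% 1L
  mc_se <- if (!is.null(null$rep_fracs) && n_reps > 1L) {
    apply(null$rep_fracs, 2, stats::sd) / sqrt(n_reps)
  } else {
    rep(NA_real_, length(excess))
  }
  lo <- observed$bin_edges[-length(observed$bin_edges)]
  hi <- observed$bin_edges[-1]
  in_window <- c(hi <= config$pair_window_nm, FALSE) # overflow never counts
  p_hat <- sum(pmax(0, excess[in_window]))
  tab <- data.frame(
    bin_lo_nm = c(lo, observed$bin_edges[length(observed$bin_edges)]),
    bin_hi_nm = c(hi, Inf),
    observed_fraction = obs_frac,
    null_fraction = null_frac,
    excess = excess,
    mc_se = mc_se
  )
  structure(
    list(
      table = tab, p_hat = p_hat,
      window_nm = config$pair_window_nm, n_reps = n_reps
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result: p_hat = %.3f within %g nm (null reps = %d)>\n",
    x$p_hat, x$window_nm, x$n_reps
  ))
  invisible(x)
}

#' Closed-form CSR nearest-neighbour CDF
#'
#' The planar-Poisson law `1 - exp(-lambda pi r^2)`, the infinite-plane
#' limit against which the simulated null is calibrated at low density.
#'
#' @param r_nm distance, nm (vectorized).
#' @param density_per_um2 point intensity, foci per um^2.
#' @return CDF values.
#' @export
csr_nn_cdf <- function(r_nm, density_per_um2) {
  lambda_nm2 <- density_per_um2 / 1e6
  1 - exp(-lambda_nm2 * pi * r_nm^2)
}

#' Keep low-density nuclei
#'
#' Keeps nuclei whose focus density (count / area) is strictly below the
#' threshold for the stated channel(s). With `require = "any"` (the
#' default) a nucleus qualifies when either stated channel is below the
#' threshold; `"all"` requires every stated channel to be below it.
#'
#' @param x a [focus_set()] with nucleus records.
#' @param channels channel(s) entering the density rule.
#' @param config an [analysis_config()] (density threshold, per um^2).
#' @param require `"any"` or `"all"`.
#' @return a [focus_set()] restricted to the qualifying nuclei.
#' @export
filter_low_density <- function(x, channels = c("RAD51", "DMC1"),
                               config = analysis_config(),
                               require = c("any", "all")) {
  stopifnot(inherits(x, "focus_set"))
  require <- match.arg(require)
  if (is.null(x$nuclei) || length(x$nuclei) == 0L) {
    stop_format("density filter requires nucleus records with areas")
  }
  f <- x$foci
  keep <- character(0)
  for (nid in unique(f$nucleus_id)) {
    area <- x$nuclei[[nid]]$area_um2
    if (area <= 0) stop_format("nucleus '%s' has zero area", nid)
    dens <- vapply(
      channels,
      function(ch) sum(f$nucleus_id == nid & f$channel == ch) / area,
      numeric(1)
    )
    ok <- dens < config$density_threshold_per_um2
    if ((require == "any" && any(ok)) || (require == "all" && all(ok))) {
      keep <- c(keep, nid)
    }
  }
  subset_foci(x, nucleus_id = keep)
}

#' Keep foci in locally sparse regions
#'
#' Keeps foci having exactly `required_neighbors` other same-channel foci
#' within the horizon (closed ball, self excluded), within each nucleus.
#'
#' @param x a [focus_set()] restricted to a single channel.
#' @param horizon_nm neighbourhood radius, nm.
#' @param required_neighbors exact neighbour count required.
#' @return a [focus_set()] with the qualifying foci.
#' @export
filter_locally_sparse <- function(x, horizon_nm = 1000, required_neighbors = 1L) {
  stopifnot(inherits(x, "focus_set"))
  if (length(unique(x$foci$channel)) > 1L) {
    stop_format("local-sparseness filter expects a single channel; use subset_foci()")
  }
  f <- x$foci
  keep <- logical(nrow(f))
  for (nid in unique(f$nucleus_id)) {
    idx <- which(f$nucleus_id == nid)
    xy <- as.matrix(f[idx, c("x_nm", "y_nm")])
    d <- cross_dist(xy, xy)
    diag(d) <- Inf
    nbr <- rowSums(d <= horizon_nm)
    keep[idx] <- nbr == required_neighbors
  }
  focus_set(f[keep, , drop = FALSE], x$nuclei)
}

# pool adjacent histogram columns until each pooled column's combined
# count is >= min_total (tail folded back into the last group), so the
# chi-square approximation is valid
pool_hist_counts <- function(c1, c2, min_total = 10) {
  groups <- integer(length(c1))
  g <- 1L
  acc <- 0
  for (i in seq_along(c1)) {
    groups[i] <- g
    acc <- acc + c1[i] + c2[i]
    if (acc >= min_total && i < length(c1)) {
      g <- g + 1L
      acc <- 0
    }
  }
  if (acc < min_total && g > 1L) {
    groups[groups == g] <- g - 1L
  }
  rbind(
    tapply(c1, groups, sum),
    tapply(c2, groups, sum)
  )
}

#' Detectability bound for a spiked pairing subpopulation
#'
#' Estimates, by simulation, the largest fraction of foci that could be
#' arranged in pairs at a fixed separation without being detected by a
#' chi-square two-sample comparison of NN histograms against CSR. For
#' each fraction `p` in the grid, `reps` spiked datasets
#' ([simulate_spiked_pattern()]) are each tested against an independent
#' CSR dataset of identical size; power is the rejection rate at level
#' `alpha`. The bound is the largest grid fraction whose power is below
#' `power_target`.
#'
#' @param null_params list with `n_foci_per_nucleus`, `n_nuclei`,
#'   `area_um2` (per-nucleus disc area).
#' @param spike_distance_nm pair separation of the spiked subpopulation.
#' @param fraction_grid sorted ascending fractions to probe.
#' @param alpha test level.
#' @param power_target detection power defining "would have been seen".
#' @param reps Monte-Carlo replicates per fraction.
#' @param config an [analysis_config()].
#' @param seed integer seed or `NULL`.
#' @return list with `max_undetectable_fraction` (NA if the whole grid is
#'   detectable), `power` (data.frame of fraction, power), and
#'   `critical_value` (the Monte-Carlo calibrated chi-square threshold).
#'
#' @details NN distances within a nucleus are positively correlated
#'   (mutual nearest neighbours contribute near-duplicate distances), so
#'   the nominal chi-square reference distribution is anti-conservative
#'   here. The statistic is therefore calibrated against its own
#'   Monte-Carlo null: `calibration_reps` CSR-vs-CSR datasets provide
#'   the `(1 - alpha)` critical value, and detection means exceeding it.
#'
#' @param calibration_reps CSR-vs-CSR replicates for the critical value
#'   (default `max(reps, 200)`).
#' @export
detectability_bound <- function(null_params, spike_distance_nm = 300,
                                fraction_grid = c(0.05, 0.1, 0.15, 0.2, 0.3),
                                alpha = 0.05, power_target = 0.8,
                                reps = 200, config = analysis_config(),
                                seed = NULL,
                                calibration_reps = max(reps, 200)) {
  if (length(fraction_grid) == 0L) stop_format("fraction_grid is empty")
  if (is.unsorted(fraction_grid)) stop_format("fraction_grid must be sorted ascending")
  n_nuc <- null_params$n_nuclei
  n_foc <- null_params$n_foci_per_nucleus
  area <- null_params$area_um2
  chisq_stat <- function(p) {
    d_test <- numeric(0)
    d_csr <- numeric(0)
    for (k in seq_len(n_nuc)) {
      nuc <- make_nucleus(area, sprintf("n%d", k))
      tst <- if (p > 0) {
        simulate_spiked_pattern(nuc, n_foc, p, spike_distance_nm)
      } else {
        simulate_csr(nuc, n_foc)
      }
      cs <- simulate_csr(nuc, n_foc)
      d_test <- c(d_test, nn_distances(tst))
      d_csr <- c(d_csr, nn_distances(cs))
    }
    h1 <- nn_histogram(d_test, config)
    h0 <- nn_histogram(d_csr, config)
    tab <- pool_hist_counts(c(h1$counts, h1$overflow), c(h0$counts, h0$overflow))
    unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic))
  }
  with_seed(seed, {
    null_stats <- vapply(seq_len(calibration_reps), function(r) chisq_stat(0), numeric(1))
    crit <- stats::quantile(null_stats, 1 - alpha, names = FALSE, type = 1)
    power <- vapply(fraction_grid, function(p) {
      mean(vapply(seq_len(reps), function(r) chisq_stat(p) > crit, logical(1)))
    }, numeric(1))
    undetect <- fraction_grid[power < power_target]
    list(
      max_undetectable_fraction = if (length(undetect)) max(undetect) else NA_real_,
      power = data.frame(fraction = fraction_grid, power = power),
      critical_value = crit
    )
  })
}
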