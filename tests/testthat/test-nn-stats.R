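test_that("nn_distances matches mutual-neighbour geometry and the brute-force oracle", {
  # two same-channel foci at distance d -> both report d
  fs <- fs_from_xy(c(0, 0), c(0, 250))
  expect_equal(nn_distances(fs), c(250, 250))

  # cross-channel: a coincident partner gives distance 0
  a <- fs_from_xy(100, 100, channel = "RAD51")
  b <- fs_from_xy(c(100, 900), c(100, 900), channel = "DMC1")
  expect_equal(nn_distances(a, b), 0)

  # randomized equivalence with the O(n^2) oracle, same- and cross-channel,
  # multiple nuclei pooled
  for (seed in 1:8) {
    fs <- random_focus_set(n_nuclei = 3, max_foci = 40, seed = seed)
    r <- subset_foci(fs, channel = "RAD51")
    d <- subset_foci(fs, channel = "DMC1")
    got_same <- nn_distances(r)
    got_cross <- nn_distances(r, d)
    exp_same <- exp_cross <- numeric(0)
    for (nid in unique(r$foci$nucleus_id)) {
      ra <- as.matrix(r$foci[r$foci$nucleus_id == nid, c("x_nm", "y_nm")])
      da <- as.matrix(d$foci[d$foci$nucleus_id == nid, c("x_nm", "y_nm")])
      if (nrow(ra) >= 2) exp_same <- c(exp_same, oracle_nn(ra))
      if (nrow(ra) >= 1 && nrow(da) >= 1) exp_cross <- c(exp_cross, oracle_nn(ra, da))
    }
    expect_equal(got_same, exp_same, tolerance = 1e-12)
    expect_equal(got_cross, exp_cross, tolerance = 1e-12)
  }
})

test_that("single-focus nuclei contribute nothing in same-channel mode", {
  fs <- focus_set(
    data.frame(
      nucleus_id = c("n1", "n2", "n2"), channel = "RAD51",
      x_nm = c(0, 0, 300), y_nm = 0, intensity = 1
    ),
    list(make_nucleus(50, "n1"), make_nucleus(50, "n2"))
  )
  expect_equal(nn_distances(fs), c(300, 300))
})

test_that("nn_histogram uses right-open bins with an overflow class", {
  cfg <- analysis_config()
  h0 <- nn_histogram(numeric(0), cfg)
  expect_equal(h0$n_total, 0L)
  expect_true(all(h0$counts == 0L))

  h <- nn_histogram(c(49.999, 50.0), cfg)
  expect_equal(h$counts[1:2], c(1L, 1L))

  h2 <- nn_histogram(c(1999.9, 2000, 5000), cfg)
  expect_equal(h2$overflow, 2L)
  expect_equal(sum(h2$counts) + h2$overflow, h2$n_total)

  expect_error(nn_histogram(c(-1, 5), cfg), ">= 0")

  # analytic check: uniform draws populate bins at their analytic masses
  set.seed(31)
  x <- runif(1e4, 0, 2000)
  h3 <- nn_histogram(x, cfg)
  p <- 50 / 2000
  z <- qnorm(1 - 0.01 / (2 * 40)) # 99% familywise over the 40 bins
  expect_true(all(abs(h3$counts / 1e4 - p) < z * sqrt(p * (1 - p) / 1e4)))
})

test_that("matched CSR nulls are reproducible and censor-aware", {
  nuc <- make_nucleus(60, "n1")
  obs <- simulate_csr(nuc, 25, seed = 3)
  n1 <- simulate_matched_null(obs, reps = 10, censor = TRUE, seed = 42)
  n2 <- simulate_matched_null(obs, reps = 10, censor = TRUE, seed = 42)
  expect_equal(n1$counts, n2$counts)
  expect_equal(n1$raw_distances, n2$raw_distances)

  # censoring leaves no same-channel distance below the floor and
  # shifts mass out of the sub-floor bins relative to the uncensored null
  expect_true(all(n1$raw_distances >= 150))
  n_free <- simulate_matched_null(obs, reps = 10, censor = FALSE, seed = 42)
  below <- function(d) mean(d$raw_distances < 150)
  expect_gt(below(n_free), 0)

  # missing regions are an error
  bare <- focus_set(obs$foci, nuclei = NULL)
  expect_error(simulate_matched_null(bare), "region")
})

test_that("the low-density CSR null reproduces the planar-Poisson NN law", {
  # 2e3 foci at 0.1 /um^2 in one large disc: Dvoretzky-Kiefer-Wolfowitz
  # band at alpha = 0.01 (module-scale version of the calibration)
  nuc <- make_nucleus(2e3 / 0.1, "big")
  obs <- simulate_csr(nuc, 2e3, seed = 17)
  null <- simulate_matched_null(obs, reps = 1, censor = FALSE, seed = 18)
  r <- sort(null$raw_distances)
  sup <- max(abs(seq_along(r) / length(r) - csr_nn_cdf(r, 0.1)))
  expect_lt(sup, sqrt(log(2 / 0.01) / (2 * length(r))))
})

test_that("pairing enrichment is zero for identical distributions and null-calibrated", {
  cfg <- analysis_config()
  h <- nn_histogram(c(100, 300, 700), cfg)
  enr <- pairing_enrichment(h, h, cfg)
  expect_equal(enr$p_hat, 0)
  expect_true(all(enr$table$excess == 0))

  wide <- nn_histogram(c(100, 300), analysis_config(nn_bin_width_nm = 100))
  expect_error(pairing_enrichment(h, wide, cfg), "binning")

  # CSR observed vs CSR null: p_hat within 3x the dataset-level MC
  # spread of the null (the per-replicate SD measures the sampling
  # variability of one dataset of the observed size)
  sets <- lapply(1:40, function(i) {
    simulate_csr(make_nucleus(50, sprintf("n%d", i)), 15, seed = 100 + i)
  })
  all <- do.call(combine_focus_sets, sets)
  obs <- nn_histogram(nn_distances(all), cfg)
  null <- simulate_matched_null(all, reps = 100, censor = FALSE, config = cfg, seed = 7)
  enr2 <- pairing_enrichment(obs, null, cfg)
  in_window <- enr2$table$bin_hi_nm <= cfg$pair_window_nm
  rep_sd <- apply(null$rep_fracs, 2, sd)[in_window]
  expect_lt(abs(enr2$p_hat), 3 * sqrt(sum(rep_sd^2)))
})

test_that("the density filter applies a strict per-area threshold", {
  mk <- function(n_r, nid) {
    nuc <- make_nucleus(25, nid)
    xy <- region_sample(nuc$region, n_r)
    focus_set(
      data.frame(
        nucleus_id = nid, channel = "RAD51",
        x_nm = xy[, 1], y_nm = xy[, 2], intensity = 1
      ),
      list(nuc)
    )
  }
  set.seed(12)
  kept <- filter_low_density(mk(19, "a"), channels = "RAD51") # 0.76 /um^2
  expect_equal(unique(kept$foci$nucleus_id), "a")
  excl <- filter_low_density(mk(20, "b"), channels = "RAD51") # 0.80: strict <
  expect_equal(n_foci(excl), 0L)

  # randomized equivalence against a direct reimplementation
  fs <- random_focus_set(6, 45, area_um2 = 25, seed = 3)
  got <- filter_low_density(fs, channels = c("RAD51", "DMC1"))
  want <- character(0)
  for (nid in names(fs$nuclei)) {
    dens <- sapply(c("RAD51", "DMC1"), function(ch) {
      sum(fs$foci$nucleus_id == nid & fs$foci$channel == ch) / 25
    })
    if (any(dens < 0.8)) want <- c(want, nid)
  }
  expect_setequal(unique(got$foci$nucleus_id), intersect(want, fs$foci$nucleus_id))
})

test_that("the local-sparseness filter keeps exactly-one-neighbour foci", {
  # isolated focus (0 neighbours) excluded; exactly 1 neighbour at 900 kept
  fs <- fs_from_xy(c(0, 900, 5000), c(0, 0, 0))
  out <- filter_locally_sparse(fs, 1000, 1L)
  expect_equal(sort(out$foci$x_nm), c(0, 900))

  # boundary: neighbour exactly at the horizon counts (closed ball)
  fs2 <- fs_from_xy(c(0, 1000), c(0, 0))
  expect_equal(n_foci(filter_locally_sparse(fs2, 1000, 1L)), 2L)

  # randomized equivalence against a brute-force count
  for (seed in 1:4) {
    fs3 <- subset_foci(random_focus_set(2, 60, seed = seed), channel = "RAD51")
    got <- filter_locally_sparse(fs3, 1000, 1L)
    keep <- logical(nrow(fs3$foci))
    for (i in seq_along(keep)) {
      cnt <- 0L
      for (j in seq_along(keep)) {
        if (i == j || fs3$foci$nucleus_id[i] != fs3$foci$nucleus_id[j]) next
        d <- sqrt((fs3$foci$x_nm[i] - fs3$foci$x_nm[j])^2 +
          (fs3$foci$y_nm[i] - fs3$foci$y_nm[j])^2)
        if (d <= 1000) cnt <- cnt + 1L
      }
      keep[i] <- cnt == 1L
    }
    expect_equal(got$foci, fs3$foci[keep, , drop = FALSE], ignore_attr = TRUE)
  }
})

test_that("detectability power is calibrated at zero and saturates at one", {
  db <- detectability_bound(
    list(n_foci_per_nucleus = 20, n_nuclei = 8, area_um2 = 100),
    spike_distance_nm = 300, fraction_grid = c(0, 0.4, 1),
    alpha = 0.05, reps = 500, seed = 23, calibration_reps = 400
  )
  pw <- db$power$power
  # type-I calibration within the binomial 99% CI around alpha
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(pw[1] - 0.05), ci + 0.01)
  expect_gt(pw[3], 0.95)
  # power non-decreasing in the spiked fraction (up to MC noise)
  expect_true(all(diff(pw) > -2 * sqrt(0.25 / 500)))
  expect_error(
    detectability_bound(list(
      n_foci_per_nucleus = 5, n_nuclei = 2,
      area_um2 = 10
    ), fraction_grid = numeric(0)),
    "empty"
  )
})
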