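test_that("degenerate samplers force the DSB pair geometry exactly", {
  nuc <- make_nucleus(100, "n1")
  params <- pair_model_params(
    n_dsb = 1,
    pair_sep_sampler = function(n) rep(300, n),
    cofocus_offset_sampler = function(n) rep(0, n),
    occupancy = c(both = 1, rad51_only = 0, dmc1_only = 0, empty = 0)
  )
  fs <- simulate_dsb_pattern(nuc, params, seed = 4)
  f <- fs$foci
  expect_equal(sum(f$channel == "RAD51"), 2L)
  expect_equal(sum(f$channel == "DMC1"), 2L)
  r <- f[f$channel == "RAD51", ]
  d <- f[f$channel == "DMC1", ]
  expect_equal(sqrt(diff(r$x_nm)^2 + diff(r$y_nm)^2), 300, tolerance = 1e-9)
  # zero offset: each RAD51 focus coincides with a DMC1 focus of the same end
  for (e in 1:2) {
    expect_equal(
      unlist(r[r$end_id == e, c("x_nm", "y_nm")]),
      unlist(d[d$end_id == e, c("x_nm", "y_nm")]),
      tolerance = 1e-9
    )
  }
  # n_dsb = 0, no background -> empty
  expect_equal(n_foci(simulate_dsb_pattern(nuc, pair_model_params(n_dsb = 0), seed = 1)), 0L)
})

test_that("truth tags reconstruct the sampled end separations", {
  nuc <- make_nucleus(80, "n1")
  fs <- simulate_dsb_pattern(nuc, pair_model_params(n_dsb = 25), seed = 9)
  truth <- attr(fs, "dsb_truth")
  sep <- sqrt((truth$end1_x_nm - truth$end2_x_nm)^2 +
    (truth$end1_y_nm - truth$end2_y_nm)^2)
  expect_equal(sep, truth$separation_nm, tolerance = 1e-6)
  expect_true(all(sep >= 150 & sep <= 400))
  # every focus either carries a dsb tag or is background
  expect_true(all(!is.na(fs$foci$dsb_id) | fs$foci$is_background))
})

test_that("occupancy probabilities are honoured (binomial check)", {
  nuc <- make_nucleus(400, "n1")
  params <- pair_model_params(n_dsb = 200)
  fs <- simulate_dsb_pattern(nuc, params, seed = 21)
  f <- fs$foci
  both <- 0L
  for (d in unique(f$dsb_id)) {
    for (e in 1:2) {
      ch <- f$channel[f$dsb_id == d & f$end_id == e]
      if (all(c("RAD51", "DMC1") %in% ch)) both <- both + 1L
    }
  }
  p_hat <- both / 400
  ci <- qnorm(0.995) * sqrt(0.7 * 0.3 / 400)
  expect_lt(abs(p_hat - 0.7), ci + 1e-12)
})

test_that("rejection sampling errors out when the nucleus cannot hold a DSB", {
  tiny <- make_nucleus(0.001, "t") # radius ~18 nm, pairs need >= 150 nm
  params <- pair_model_params(n_dsb = 1)
  expect_error(simulate_dsb_pattern(tiny, params, seed = 1), "too small")
})

test_that("CSR generator is uniform over the disc and reproducible", {
  nuc <- make_nucleus(100, "n1")
  expect_equal(n_foci(simulate_csr(nuc, 0)), 0L)
  a <- simulate_csr(nuc, 50, seed = 5)
  b <- simulate_csr(nuc, 50, seed = 5)
  expect_equal(a$foci, b$foci)

  fs <- simulate_csr(nuc, 1e4, seed = 6)
  r <- sqrt((fs$foci$x_nm - nuc$region$center_x_nm)^2 +
    (fs$foci$y_nm - nuc$region$center_y_nm)^2)
  # ten equal-area annuli: expected uniform occupancy
  edges <- nuc$region$radius_nm * sqrt(seq(0, 1, by = 0.1))
  counts <- table(cut(r, edges, include.lowest = TRUE))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("polygon regions sample uniformly inside the polygon", {
  reg <- region_polygon(c(0, 4000, 4000, 0), c(0, 0, 2000, 2000))
  set.seed(2)
  xy <- region_sample(reg, 4000)
  expect_true(all(region_contains(reg, xy[, 1], xy[, 2])))
  # left and right halves equally occupied
  p <- binom.test(sum(xy[, 1] < 2000), 4000)$p.value
  expect_gt(p, 0.001)
})

test_that("resolution censoring merges by the stated rule and conserves intensity", {
  # two equal foci 100 nm apart -> one focus at the midpoint, intensity summed
  fs <- fs_from_xy(c(1000, 1100), c(500, 500), intensity = c(10, 10))
  out <- apply_resolution_censor(fs, 150)
  expect_equal(n_foci(out), 1L)
  expect_equal(out$foci$x_nm, 1050)
  expect_equal(out$foci$y_nm, 500)
  expect_equal(out$foci$intensity, 20)

  # unequal intensities -> intensity-weighted centroid
  fs2 <- fs_from_xy(c(0, 100), c(0, 0), intensity = c(30, 10))
  out2 <- apply_resolution_censor(fs2, 150)
  expect_equal(out2$foci$x_nm, 25)

  # all pairwise distances >= 150 -> fixpoint
  fs3 <- fs_from_xy(c(0, 200, 400), c(0, 0, 0))
  out3 <- apply_resolution_censor(fs3, 150)
  expect_equal(sort(out3$foci$x_nm), c(0, 200, 400))
})

test_that("censoring yields min pairwise distance >= d_min on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    nuc <- make_nucleus(20, "n1")
    xy <- region_sample(nuc$region, 50)
    fs <- fs_from_xy(xy[, 1], xy[, 2],
      intensity = stats::rlnorm(50, log(100), 0.5),
      nuclei = list(nuc)
    )
    out <- apply_resolution_censor(fs, 150)
    m <- as.matrix(out$foci[, c("x_nm", "y_nm")])
    d <- focipair:::cross_dist(m, m)
    d[!upper.tri(d)] <- Inf
    expect_gte(min(d), 150)
    expect_equal(sum(out$foci$intensity), sum(fs$foci$intensity), tolerance = 1e-9)
    # censoring never decreases the minimum pairwise distance
    d0 <- focipair:::cross_dist(xy, xy)
    d0[!upper.tri(d0)] <- Inf
    expect_gte(min(d), min(d0) - 1e-9)
  }
})

test_that("widefield rendering conserves signal and resolves 600 nm doublets", {
  # no foci, flat background, no noise -> constant image
  img0 <- render_widefield(focus_set(), background_mean = 10, bounds = c(1000, 800))
  expect_true(all(img0$frames == 10))

  one <- fs_from_xy(1550, 1250, intensity = 500)
  st <- render_widefield(one, bounds = c(3100, 2500))
  img <- st$frames[, , 1]
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  # the brightest pixel contains the true position
  expect_equal(ceiling(1250 / 100), peak[["row"]])
  expect_equal(ceiling(1550 / 100), peak[["col"]])
  expect_equal(sum(img), 500, tolerance = 0.01 * 500)

  two <- fs_from_xy(c(1200, 1800), c(1000, 1000), intensity = c(500, 500))
  img2 <- render_widefield(two, bounds = c(3000, 2000))$frames[, , 1]
  maxima <- focipair:::find_local_maxima(img2, min_value = max(img2) / 4)
  expect_equal(nrow(maxima), 2L)
})

test_that("blink stacks follow the two-state switching model", {
  pos <- rbind(c(500, 500), c(900, 500))
  # p_on = 0 is rejected by the model contract; background-only stack
  # comes from the smallest p_on with no on-events by chance is not
  # deterministic, so test the p_on bound and the single-emitter case
  expect_error(emitter_model(pos, p_on = 0), "p_on")

  m1 <- emitter_model(matrix(c(700, 500), ncol = 2),
    p_on = 1,
    photons_mean = 2000, psf_sigma_nm = 75, background_rate = 0
  )
  sim <- simulate_blink_stack(m1, 50, seed = 3, bounds = c(1400, 1000))
  expect_true(all(sim$truth))
  for (f in c(1, 25, 50)) {
    img <- sim$stack$frames[, , f]
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    expect_equal(peak[["col"]], 7) # x = 700 nm -> pixel 7
    expect_equal(peak[["row"]], 5)
  }

  m2 <- emitter_model(pos,
    p_on = 0.05, photons_mean = 1000,
    psf_sigma_nm = 75, background_rate = 0
  )
  sim2 <- simulate_blink_stack(m2, 1e4, seed = 8, bounds = c(1400, 1000))
  co <- mean(rowSums(sim2$truth) == 2L)
  ci <- qnorm(0.995) * sqrt(0.0025 * 0.9975 / 1e4)
  expect_lt(abs(co - 0.0025), ci + 1e-12)

  # reproducibility from (params, seed)
  sim3 <- simulate_blink_stack(m2, 20, seed = 13, bounds = c(1400, 1000))
  sim4 <- simulate_blink_stack(m2, 20, seed = 13, bounds = c(1400, 1000))
  expect_identical(sim3$stack$frames, sim4$stack$frames)
  expect_identical(sim3$truth, sim4$truth)
})

test_that("spiked patterns hold the requested paired fraction exactly", {
  nuc <- make_nucleus(150, "n1")
  fs <- simulate_spiked_pattern(nuc, 30, 0.5, 300, seed = 2)
  expect_equal(sum(fs$foci$is_paired), 16L) # round(0.5 * 30 / 2) pairs
  xy <- as.matrix(fs$foci[fs$foci$is_paired, c("x_nm", "y_nm")])
  d <- focipair:::cross_dist(xy, xy)
  diag(d) <- Inf
  expect_true(all(abs(apply(d, 1, min) - 300) < 1e-6))
})

test_that("truncated emitter clusters stay within their radius", {
  set.seed(5)
  xy <- emitters_point_cluster(c(1000, 1000), 40, 500, truncate_sigma = 2)
  r <- sqrt((xy[, 1] - 1000)^2 + (xy[, 2] - 1000)^2)
  expect_lte(max(r), 80)
})
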