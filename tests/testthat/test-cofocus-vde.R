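test_that("cross-channel fractions follow the strict-radius rule", {
  a <- fs_from_xy(c(0, 1000), c(0, 0), channel = "RAD51")
  b_same <- fs_from_xy(c(0, 1000), c(0, 0), channel = "DMC1")
  expect_equal(cross_fraction_within(a, b_same), 1.0)

  b_far <- fs_from_xy(c(5000, 6000), c(0, 0), channel = "DMC1")
  expect_equal(cross_fraction_within(a, b_far), 0.0)

  # boundary: exactly at the radius does not count (strict <)
  b_edge <- fs_from_xy(200, 0, channel = "DMC1")
  expect_equal(cross_fraction_within(fs_from_xy(0, 0), b_edge), 0.0)

  # randomized equivalence with a brute-force fraction
  for (seed in 1:5) {
    fs <- random_focus_set(3, 30, seed = seed)
    r <- subset_foci(fs, channel = "RAD51")
    d <- subset_foci(fs, channel = "DMC1")
    got <- cross_fraction_within(r, d, 200)
    num <- den <- 0L
    for (i in seq_len(nrow(r$foci))) {
      dd <- Inf
      for (j in seq_len(nrow(d$foci))) {
        if (r$foci$nucleus_id[i] != d$foci$nucleus_id[j]) next
        dd <- min(dd, sqrt((r$foci$x_nm[i] - d$foci$x_nm[j])^2 +
          (r$foci$y_nm[i] - d$foci$y_nm[j])^2))
      }
      if (is.finite(dd)) {
        den <- den + 1L
        if (dd < 200) num <- num + 1L
      }
    }
    expect_equal(got, num / den)
  }
})

test_that("pair detection is mutual-nearest-neighbour within the window", {
  # two composites 300 nm apart -> one pair
  fs <- fs_from_xy(c(0, 300), c(0, 0))
  expect_equal(nrow(detect_pairs(fs)), 1L)

  # three collinear composites at 0, 300, 700 -> (0, 300) paired, 700 unpaired
  fs3 <- fs_from_xy(c(0, 300, 700), c(0, 0, 0))
  pr <- detect_pairs(fs3)
  expect_equal(nrow(pr), 1L)
  expect_equal(sort(c(pr$m1_x_nm, pr$m2_x_nm)), c(0, 300))

  # beyond the window -> nothing
  expect_equal(nrow(detect_pairs(fs_from_xy(c(0, 500), c(0, 0)))), 0L)

  # no composite ever sits in two pairs; pairing is symmetric
  for (seed in 1:5) {
    fs4 <- random_focus_set(3, 25, seed = 100 + seed)
    pr4 <- detect_pairs(fs4)
    members <- c(
      paste(pr4$nucleus_id, pr4$m1_x_nm, pr4$m1_y_nm),
      paste(pr4$nucleus_id, pr4$m2_x_nm, pr4$m2_y_nm)
    )
    expect_false(any(duplicated(members)))
    expect_true(all(pr4$separation_nm <= 400))
  }
})

test_that("pair detection recovers the generative DSB pairs from truth tags", {
  n_hit <- n_dsb_obs <- 0L
  for (i in 1:30) {
    nuc <- make_nucleus(200, sprintf("n%d", i))
    params <- pair_model_params(
      n_dsb = 4,
      cofocus_offset_sampler = function(n) rep(0, n),
      occupancy = c(both = 1, rad51_only = 0, dmc1_only = 0, empty = 0)
    )
    fs <- simulate_dsb_pattern(nuc, params, seed = 500 + i)
    truth <- attr(fs, "dsb_truth")
    pr <- detect_pairs(fs)
    for (d in seq_len(nrow(truth))) {
      n_dsb_obs <- n_dsb_obs + 1L
      ends <- rbind(
        c(truth$end1_x_nm[d], truth$end1_y_nm[d]),
        c(truth$end2_x_nm[d], truth$end2_y_nm[d])
      )
      hit <- FALSE
      for (k in seq_len(nrow(pr))) {
        m <- rbind(
          c(pr$m1_x_nm[k], pr$m1_y_nm[k]),
          c(pr$m2_x_nm[k], pr$m2_y_nm[k])
        )
        if ((all(abs(m[1, ] - ends[1, ]) < 1e-6) && all(abs(m[2, ] - ends[2, ]) < 1e-6)) ||
          (all(abs(m[1, ] - ends[2, ]) < 1e-6) && all(abs(m[2, ] - ends[1, ]) < 1e-6))) {
          hit <- TRUE
        }
      }
      if (hit) n_hit <- n_hit + 1L
    }
  }
  expect_gte(n_hit / n_dsb_obs, 0.95)
})

test_that("pair composition accounting is exact and generative", {
  fs <- fs_from_xy(c(0, 300), c(0, 0))
  fs <- focus_set(rbind(
    fs$foci,
    within(fs$foci, channel <- "DMC1")
  ))
  pr <- detect_pairs(fs) # both members co-foci
  cmp <- pair_composition_fraction(pr)
  expect_equal(cmp$fraction_both_cofoci, 1.0)
  expect_equal(sum(cmp$composition), nrow(pr))

  empty <- pair_composition_fraction(detect_pairs(focus_set()))
  expect_true(empty$undefined)
  expect_true(is.na(empty$fraction_both_cofoci))

  # occupancy both = 0 (one channel per end) -> no co+co pairs
  nuc <- make_nucleus(200, "n1")
  params <- pair_model_params(
    n_dsb = 20,
    cofocus_offset_sampler = function(n) rep(0, n),
    occupancy = c(both = 0, rad51_only = 0.5, dmc1_only = 0.5, empty = 0)
  )
  fs2 <- simulate_dsb_pattern(nuc, params, seed = 31)
  cmp2 <- pair_composition_fraction(detect_pairs(fs2))
  expect_equal(cmp2$fraction_both_cofoci, 0)
})

test_that("intensity shares: independence gives slope ~0, identity gives slope 1", {
  mk_pairs <- function(r1, d1) {
    n <- length(r1)
    data.frame(
      nucleus_id = sprintf("n%d", seq_len(n)),
      m1_x_nm = 0, m1_y_nm = 0, m2_x_nm = 300, m2_y_nm = 0,
      separation_nm = 300,
      m1_kind = "cofocus", m2_kind = "cofocus",
      m1_rad51_intensity = r1, m1_dmc1_intensity = d1,
      m2_rad51_intensity = 100 - r1, m2_dmc1_intensity = 100 - d1,
      stringsAsFactors = FALSE
    )
  }
  # equal intensities everywhere -> all shares 50, slope 0
  eq <- pair_intensity_shares(mk_pairs(rep(50, 10), rep(50, 10)))
  expect_true(all(eq$shares$rad51_share_pct == 50))
  expect_equal(eq$slope, 0)

  # independent uniform shares -> slope within +/- 0.1 of 0
  set.seed(9)
  ind <- pair_intensity_shares(mk_pairs(runif(500, 10, 90), runif(500, 10, 90)))
  expect_lt(abs(ind$slope), 0.1)

  # perfectly correlated shares -> slope exactly 1
  r <- runif(50, 10, 90)
  cor <- pair_intensity_shares(mk_pairs(r, r))
  expect_equal(cor$slope, 1, tolerance = 1e-9)

  # zero-total channel pairs are excluded and counted
  zz <- mk_pairs(c(50, 0), c(50, 0))
  zz$m2_rad51_intensity[2] <- 0
  out <- pair_intensity_shares(zz)
  expect_equal(out$n_excluded, 1L)
})

test_that("the category classifier covers the rule table", {
  co <- function(x, y) {
    rbind(
      data.frame(
        nucleus_id = "n1", channel = "RAD51", x_nm = x, y_nm = y,
        intensity = 100, stringsAsFactors = FALSE
      ),
      data.frame(
        nucleus_id = "n1", channel = "DMC1", x_nm = x, y_nm = y,
        intensity = 100, stringsAsFactors = FALSE
      )
    )
  }
  r_only <- function(x, y, ch = "RAD51") {
    data.frame(
      nucleus_id = "n1", channel = ch, x_nm = x, y_nm = y,
      intensity = 100, stringsAsFactors = FALSE
    )
  }
  cat_of <- function(foci) vde_classify_nucleus(foci)$category

  expect_equal(cat_of(co(0, 0)), "I") # single co-focus
  expect_equal(cat_of(co(0, 0)[0, ]), "NEGATIVE")
  expect_equal(cat_of(rbind(co(0, 0), co(500, 0))), "II") # two composites 500 apart
  # 3 RAD51 + 3 DMC1 all within 1 um -> III
  expect_equal(
    cat_of(rbind(co(0, 0), co(400, 0), co(800, 0))), "III"
  )
  # two complexes 2 um apart, one focus each -> IV
  expect_equal(cat_of(rbind(r_only(0, 0), r_only(2000, 0, "DMC1"))), "IV")
  # two complexes 2 um apart, 3 RAD51 total -> V
  expect_equal(
    cat_of(rbind(r_only(0, 0), r_only(300, 0), r_only(2300, 0))), "V"
  )
})

test_that("the classifier agrees with an independent rule-table oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(0:8, 1)
    foci <- if (n == 0) {
      data.frame(
        nucleus_id = character(0), channel = character(0),
        x_nm = numeric(0), y_nm = numeric(0), intensity = numeric(0)
      )
    } else {
      data.frame(
        nucleus_id = "n1",
        channel = sample(c("RAD51", "DMC1"), n, replace = TRUE),
        x_nm = runif(n, 0, 4000), y_nm = runif(n, 0, 4000),
        intensity = rlnorm(n, log(100), 0.5),
        stringsAsFactors = FALSE
      )
    }
    expect_equal(
      vde_classify_nucleus(foci)$category,
      oracle_vde(foci),
      info = sprintf("seed %d", seed)
    )
  }
})

test_that("focus-positive percentages use half-up rounding", {
  expect_equal(focus_positive_fraction(54, 116)$percent, 47)
  expect_equal(focus_positive_fraction(0, 20)$percent, 0)
  expect_equal(focus_positive_fraction(2, 47)$percent, 4)
  expect_equal(focus_positive_fraction(1, 8)$percent, 13) # 12.5 -> half-up
  expect_equal(focus_positive_fraction(c("I", "NEGATIVE", "II"))$percent, 67)
  expect_error(focus_positive_fraction(1, 0), "n_total")
})

test_that("landmark filtering applies the eligibility and call rules", {
  lm <- function(nid, kinds, xs, ys) {
    data.frame(
      nucleus_id = nid, kind = kinds, x_nm = xs, y_nm = ys,
      stringsAsFactors = FALSE
    )
  }
  # >2 tetO spots -> ineligible with a recorded reason
  res <- landmark_filter_and_score(
    fs_from_xy(0, 0, channel = "DMC1"),
    lm("n1", c("tetO", "tetO", "tetO", "lacO"), c(0, 100, 200, 400), c(0, 0, 0, 0))
  )
  expect_false(res$eligible)
  expect_match(res$reason, ">2")

  # anchor focus plus one extra DMC1 at 400 nm -> eligible pair call;
  # two tetO spots 400 apart -> split distance reported
  dmc1 <- fs_from_xy(c(400, 800), c(200, 200), channel = "DMC1")
  res2 <- landmark_filter_and_score(
    dmc1,
    lm("n1", c("tetO", "tetO", "lacO"), c(300, 700, 500), c(0, 0, 400))
  )
  expect_true(res2$eligible)
  expect_equal(res2$call, "pair")
  expect_equal(res2$tetO_split_nm, 400)

  # lone anchor focus -> single call
  res3 <- landmark_filter_and_score(
    fs_from_xy(400, 200, channel = "DMC1"),
    lm("n1", c("tetO", "lacO"), c(300, 500), c(0, 400))
  )
  expect_equal(res3$call, "single")

  # missing lacO -> ineligible; crowded anchor -> ineligible
  res4 <- landmark_filter_and_score(
    dmc1, lm("n1", c("tetO", "tetO"), c(300, 700), c(0, 0))
  )
  expect_match(res4$reason, "missing")
  crowd <- fs_from_xy(c(500, 600, 700, 800, 900), rep(0, 5), channel = "DMC1")
  res5 <- landmark_filter_and_score(
    crowd, lm("n1", c("tetO", "lacO"), c(300, 700), c(0, 0))
  )
  expect_false(res5$eligible)

  expect_error(
    landmark_filter_and_score(dmc1, lm("n1", "oops", 0, 0)),
    "lacO or tetO"
  )
})
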