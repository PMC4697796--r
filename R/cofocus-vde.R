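# Two-channel co-focus analysis, the per-nucleus focus-configuration
# classifier for the single-cut-site (VDE) experiment, focus-positive
# bookkeeping, and chromosomal-landmark selection.

#' Fraction of foci with a cross-channel neighbour within a radius
#'
#' The fraction of `a`-foci whose nearest `b`-focus in the same nucleus
#' lies strictly within `radius_nm` — the two-channel colocalization
#' convention (different fluorophores allow distances below the
#' single-channel resolution limit). Nuclei with no `b`-foci contribute
#' nothing to the denominator.
#'
#' @param a,b [focus_set()]s sharing nuclei (one channel each).
#' @param radius_nm colocalization radius, nm (default 200, strict `<`).
#' @return fraction in \[0, 1\] (NaN when no `a`-focus is countable).
#' @export
cross_fraction_within <- function(a, b, radius_nm = 200) {
  stopifnot(inherits(a, "focus_set"), inherits(b, "focus_set"))
  check_nucleus_linkage(a, b)
  n_counted <- 0L
  n_within <- 0L
  for (nid in unique(a$foci$nucleus_id)) {
    pa <- as.matrix(a$foci[a$foci$nucleus_id == nid, c("x_nm", "y_nm"), drop = FALSE])
    pb <- as.matrix(b$foci[b$foci$nucleus_id == nid, c("x_nm", "y_nm"), drop = FALSE])
    if (nrow(pa) == 0L || nrow(pb) == 0L) next
    nn <- nn_dist_chunked(pa, pb)
    n_counted <- n_counted + length(nn)
    n_within <- n_within + sum(nn < radius_nm)
  }
  n_within / n_counted
}

# ---- composite (co-focus) formation ----------------------------------

# Greedy mutual merging of cross-channel partners within the
# colocalization radius, for the foci of one nucleus. Returns one row per
# composite: position (intensity-weighted centroid for merged pairs),
# per-channel intensities, and the composite kind.
form_composites <- function(foci, coloc_radius_nm = 200) {
  r <- foci[foci$channel == "RAD51", , drop = FALSE]
  d <- foci[foci$channel == "DMC1", , drop = FALSE]
  comp <- list()
  add <- function(x, y, ri, di, kind) {
    comp[[length(comp) + 1L]] <<- data.frame(
      x_nm = x, y_nm = y, rad51_intensity = ri, dmc1_intensity = di,
      kind = kind, stringsAsFactors = FALSE
    )
  }
  while (nrow(r) > 0L && nrow(d) > 0L) {
    dm <- cross_dist(
      as.matrix(r[, c("x_nm", "y_nm")]),
      as.matrix(d[, c("x_nm", "y_nm")])
    )
    dmin <- min(dm)
    if (dmin >= coloc_radius_nm) break
    hits <- which(dm == dmin, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      key <- cbind(
        r$x_nm[hits[, 1]], r$y_nm[hits[, 1]],
        d$x_nm[hits[, 2]], d$y_nm[hits[, 2]]
      )
      hits <- hits[do.call(order, as.data.frame(key))[1], , drop = FALSE]
    }
    i <- hits[1, 1]
    j <- hits[1, 2]
    w <- c(r$intensity[i], d$intensity[j])
    if (sum(w) <= 0) w <- c(1, 1)
    add(
      (r$x_nm[i] * w[1] + d$x_nm[j] * w[2]) / sum(w),
      (r$y_nm[i] * w[1] + d$y_nm[j] * w[2]) / sum(w),
      r$intensity[i], d$intensity[j], "cofocus"
    )
    r <- r[-i, , drop = FALSE]
    d <- d[-j, , drop = FALSE]
  }
  for (k in seq_len(nrow(r))) add(r$x_nm[k], r$y_nm[k], r$intensity[k], 0, "rad51_only")
  for (k in seq_len(nrow(d))) add(d$x_nm[k], d$y_nm[k], 0, d$intensity[k], "dmc1_only")
  if (length(comp) == 0L) {
    return(data.frame(
      x_nm = numeric(0), y_nm = numeric(0),
      rad51_intensity = numeric(0), dmc1_intensity = numeric(0),
      kind = character(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, comp)
  out[order(out$x_nm, out$y_nm), , drop = FALSE]
}

#' Detect focus pairs
#'
#' Composite positions are formed per nucleus by merging cross-channel
#' partners within the colocalization radius into co-foci
#' (intensity-weighted centroid); pairs are mutual nearest neighbours
#' among composites with separation at most the pairing window. Each
#' composite belongs to at most one pair; ties are broken by smallest
#' separation then lexicographic position.
#'
#' @param x a [focus_set()] with RAD51/DMC1 channels.
#' @param config an [analysis_config()] (colocalization radius, window).
#' @return data.frame of pair records: nucleus, both member positions,
#'   separation, each member's kind and per-channel intensities.
#' @export
detect_pairs <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "focus_set"))
  out <- list()
  for (nid in unique(x$foci$nucleus_id)) {
    comp <- form_composites(
      x$foci[x$foci$nucleus_id == nid, , drop = FALSE],
      config$coloc_radius_nm
    )
    n <- nrow(comp)
    if (n < 2L) next
    dm <- cross_dist(as.matrix(comp[, c("x_nm", "y_nm")]), as.matrix(comp[, c("x_nm", "y_nm")]))
    diag(dm) <- Inf
    nn_idx <- apply(dm, 1, which.min) # ties: smallest index, after the
    # lexicographic row ordering of form_composites()
    for (i in seq_len(n)) {
      j <- nn_idx[i]
      if (j > i && nn_idx[j] == i && dm[i, j] <= config$pair_window_nm) {
        out[[length(out) + 1L]] <- data.frame(
          nucleus_id = nid,
          m1_x_nm = comp$x_nm[i], m1_y_nm = comp$y_nm[i],
          m2_x_nm = comp$x_nm[j], m2_y_nm = comp$y_nm[j],
          separation_nm = dm[i, j],
          m1_kind = comp$kind[i], m2_kind = comp$kind[j],
          m1_rad51_intensity = comp$rad51_intensity[i],
          m1_dmc1_intensity = comp$dmc1_intensity[i],
          m2_rad51_intensity = comp$rad51_intensity[j],
          m2_dmc1_intensity = comp$dmc1_intensity[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      nucleus_id = character(0), m1_x_nm = numeric(0), m1_y_nm = numeric(0),
      m2_x_nm = numeric(0), m2_y_nm = numeric(0), separation_nm = numeric(0),
      m1_kind = character(0), m2_kind = character(0),
      m1_rad51_intensity = numeric(0), m1_dmc1_intensity = numeric(0),
      m2_rad51_intensity = numeric(0), m2_dmc1_intensity = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Pair composition table and both-co-foci fraction
#'
#' @param pairs pair table from [detect_pairs()].
#' @return list with `fraction_both_cofoci`, and `composition`
#'   (named counts over co+co, co+R, co+D, R+R, R+D, D+D); the fraction
#'   is `NA` (flagged via `undefined = TRUE`) when there are no pairs.
#' @export
pair_composition_fraction <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(
      fraction_both_cofoci = NA_real_, undefined = TRUE,
      composition = c(
        "co+co" = 0L, "co+R" = 0L, "co+D" = 0L,
        "R+R" = 0L, "R+D" = 0L, "D+D" = 0L
      )
    ))
  }
  short <- c(cofocus = "co", rad51_only = "R", dmc1_only = "D")
  lab <- vapply(seq_len(n), function(i) {
    m <- sort(short[c(pairs$m1_kind[i], pairs$m2_kind[i])],
      method = "radix"
    )
    # canonical order: co before R before D
    rank <- c(co = 1L, R = 2L, D = 3L)
    m <- m[order(rank[m])]
    paste(m, collapse = "+")
  }, character(1))
  keys <- c("co+co", "co+R", "co+D", "R+R", "R+D", "D+D")
  composition <- vapply(keys, function(k) sum(lab == k), integer(1))
  list(
    fraction_both_cofoci = composition[["co+co"]] / n,
    undefined = FALSE,
    composition = composition
  )
}

#' Per-pair intensity shares and their regression slope
#'
#' For each pair in which both members are co-foci, the brightness of a
#' member in one channel is expressed as the percentage of the pair's
#' total signal in that channel. If assembly of the two co-foci is
#' independent, the RAD51 share of a member carries no information about
#' its DMC1 share and the least-squares slope is ~0. The reported member
#' is the lexicographically first of each pair.
#'
#' @param pairs pair table from [detect_pairs()].
#' @return list with `shares` (data.frame `rad51_share_pct`,
#'   `dmc1_share_pct` in \[0, 100\]), `slope`, `intercept`, and
#'   `n_excluded` (pairs dropped for a zero channel total or a
#'   non-co-focus member).
#' @export
pair_intensity_shares <- function(pairs) {
  both_co <- pairs$m1_kind == "cofocus" & pairs$m2_kind == "cofocus"
  pp <- pairs[both_co, , drop = FALSE]
  rt <- pp$m1_rad51_intensity + pp$m2_rad51_intensity
  dt <- pp$m1_dmc1_intensity + pp$m2_dmc1_intensity
  ok <- rt > 0 & dt > 0
  n_excluded <- nrow(pairs) - sum(ok)
  pp <- pp[ok, , drop = FALSE]
  # member 1 is already the lexicographically first composite (see
  # detect_pairs); use its shares
  shares <- data.frame(
    rad51_share_pct = 100 * pp$m1_rad51_intensity / rt[ok],
    dmc1_share_pct = 100 * pp$m1_dmc1_intensity / dt[ok]
  )
  slope <- NA_real_
  intercept <- NA_real_
  if (nrow(shares) >= 2L) {
    if (stats::sd(shares$rad51_share_pct) > 0) {
      fit <- stats::lm(dmc1_share_pct ~ rad51_share_pct, data = shares)
      slope <- unname(stats::coef(fit)[2])
      intercept <- unname(stats::coef(fit)[1])
    } else {
      # constant predictor carries no relationship: slope 0 by convention
      slope <- 0
      intercept <- mean(shares$dmc1_share_pct)
    }
  }
  list(
    shares = shares, slope = slope, intercept = intercept,
    n_excluded = n_excluded
  )
}

# ---- VDE category classifier -----------------------------------------

# single-linkage connected components at a distance threshold
single_linkage_components <- function(xy, link_nm) {
  n <- nrow(xy)
  if (n == 0L) {
    return(integer(0))
  }
  comp <- seq_len(n)
  d <- cross_dist(xy, xy)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] <= link_nm) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify a nucleus's focus configuration (categories I-V)
#'
#' Classifies a single nucleus by the arrangement of its RAD51/DMC1
#' staining: composite (co-focus) positions are formed as in
#' [detect_pairs()], and cytological complexes are single-linkage
#' clusters of composites at the 1 um linking radius. Categories:
#' `NEGATIVE` (no foci); one complex with one composite (`I`: a single
#' focus), with two composites (`II`: a focus pair), or with more than
#' two composites or more than two foci in either channel (`III`);
#' multiple complexes with at most two foci per channel (`IV`) or more
#' than two foci in some channel (`V`).
#'
#' @param x a [focus_set()] (or data.frame of foci) for one nucleus.
#' @param config an [analysis_config()].
#' @return list with `category` (factor level among I, II, III, IV, V,
#'   NEGATIVE), `n_rad51`, `n_dmc1`, `n_composites`, `n_complexes`, and
#'   `note` (non-empty when a degenerate >2-composite/<=2-foci single
#'   complex was classified III).
#' @export
vde_classify_nucleus <- function(x, config = analysis_config()) {
  foci <- if (inherits(x, "focus_set")) x$foci else x
  if (length(unique(foci$nucleus_id)) > 1L) {
    stop_format("vde_classify_nucleus() expects a single nucleus")
  }
  foci <- foci[foci$channel %in% c("RAD51", "DMC1"), , drop = FALSE]
  n_r <- sum(foci$channel == "RAD51")
  n_d <- sum(foci$channel == "DMC1")
  if (n_r + n_d == 0L) {
    return(list(
      category = "NEGATIVE", n_rad51 = 0L, n_dmc1 = 0L,
      n_composites = 0L, n_complexes = 0L, note = ""
    ))
  }
  comp <- form_composites(foci, config$coloc_radius_nm)
  membership <- single_linkage_components(
    as.matrix(comp[, c("x_nm", "y_nm")]), config$cluster_link_nm
  )
  n_complexes <- length(unique(membership))
  n_comp <- nrow(comp)
  note <- ""
  category <- if (n_complexes == 1L) {
    if (n_comp == 1L) {
      "I"
    } else if (n_comp == 2L) {
      "II"
    } else {
      if (n_r <= 2L && n_d <= 2L) {
        note <- ">2 composites but <=2 foci per channel; classified III"
      }
      "III"
    }
  } else {
    if (n_r <= 2L && n_d <= 2L) "IV" else "V"
  }
  list(
    category = category, n_rad51 = n_r, n_dmc1 = n_d,
    n_composites = n_comp, n_complexes = n_complexes, note = note
  )
}

#' Classify every nucleus of a focus set
#'
#' @param x a [focus_set()].
#' @param config an [analysis_config()].
#' @return data.frame with one row per nucleus (including category and
#'   supporting counts).
#' @export
vde_classify <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "focus_set"))
  nids <- unique(x$foci$nucleus_id)
  if (!is.null(x$nuclei)) nids <- union(nids, names(x$nuclei))
  rows <- lapply(nids, function(nid) {
    res <- vde_classify_nucleus(
      x$foci[x$foci$nucleus_id == nid, , drop = FALSE], config
    )
    data.frame(nucleus_id = nid, category = res$category,
      n_rad51 = res$n_rad51, n_dmc1 = res$n_dmc1,
      n_composites = res$n_composites, n_complexes = res$n_complexes,
      note = res$note, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Focus-positive fraction and rounded percentage
#'
#' @param x either the number of positive nuclei, or a character vector
#'   of per-nucleus categories (positive = not `"NEGATIVE"`).
#' @param n_total total nuclei (required in the count form).
#' @return list with `fraction` and `percent` (half-up to integer).
#' @export
focus_positive_fraction <- function(x, n_total = NULL) {
  if (is.character(x)) {
    n_pos <- sum(x != "NEGATIVE")
    n_total <- length(x)
  } else {
    n_pos <- x
    if (is.null(n_total)) stop_format("n_total is required with a count")
  }
  if (n_total < 1L) stop_format("n_total must be >= 1")
  fraction <- n_pos / n_total
  list(fraction = fraction, percent = round_half_up(100 * fraction))
}

# ---- landmark selection ----------------------------------------------

#' Validate a landmark table
#'
#' @param landmarks data.frame with columns `nucleus_id`, `kind` (one of
#'   `lacO`, `tetO`), `x_nm`, `y_nm`.
#' @return the validated data.frame.
#' @export
landmark_records <- function(landmarks) {
  required <- c("nucleus_id", "kind", "x_nm", "y_nm")
  missing <- setdiff(required, names(landmarks))
  if (length(missing) > 0L) {
    stop_format("landmark table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(landmarks$kind), c("lacO", "tetO"))
  if (length(bad) > 0L) {
    stop_format("landmark kind must be lacO or tetO, got: %s", paste(bad, collapse = ", "))
  }
  landmarks
}

#' Select and score nuclei at a flanked cut-site locus
#'
#' Implements the landmark filtering rules for scoring recombinase foci
#' at a DSB hotspot flanked by `lacO` and `tetO` arrays: a nucleus is
#' eligible when it displays at least one and at most two spots of each
#' landmark; the anchor point is the midpoint of the closest
#' (`tetO`, `lacO`) spot pair; exactly one DMC1 focus must lie within
#' `anchor_radius_nm` of the anchor and at most `max_extra` additional
#' DMC1 foci within `horizon_nm` of that focus. An eligible nucleus is
#' called a `pair` when at least one additional DMC1 focus lies within
#' the horizon of the anchor focus, else `single`. When two `tetO`
#' spots are present their separation is reported (sister-chromatid
#' split distance).
#'
#' @param dmc1 a [focus_set()] of DMC1 foci.
#' @param landmarks a [landmark_records()] table.
#' @param anchor_radius_nm anchor capture radius, nm (default 300).
#' @param horizon_nm neighbourhood radius for extra foci, nm (default 1000).
#' @param max_extra maximum additional DMC1 foci near the anchor focus.
#' @return data.frame per nucleus: `eligible`, `reason`, `call`
#'   (`single`/`pair`/`NA`), `tetO_split_nm`, landmark spot counts.
#' @export
landmark_filter_and_score <- function(dmc1, landmarks,
                                      anchor_radius_nm = 300,
                                      horizon_nm = 1000,
                                      max_extra = 2L) {
  stopifnot(inherits(dmc1, "focus_set"))
  landmarks <- landmark_records(landmarks)
  rows <- list()
  for (nid in unique(landmarks$nucleus_id)) {
    lm_n <- landmarks[landmarks$nucleus_id == nid, , drop = FALSE]
    laco <- lm_n[lm_n$kind == "lacO", , drop = FALSE]
    teto <- lm_n[lm_n$kind == "tetO", , drop = FALSE]
    teto_split <- if (nrow(teto) == 2L) {
      sqrt(diff(teto$x_nm)^2 + diff(teto$y_nm)^2)
    } else {
      NA_real_
    }
    rec <- function(eligible, reason, call) {
      data.frame(
        nucleus_id = nid, eligible = eligible, reason = reason,
        call = call, tetO_split_nm = teto_split,
        n_lacO = nrow(laco), n_tetO = nrow(teto),
        stringsAsFactors = FALSE
      )
    }
    if (nrow(laco) < 1L || nrow(teto) < 1L) {
      rows[[length(rows) + 1L]] <- rec(FALSE, "missing landmark", NA_character_)
      next
    }
    if (nrow(laco) > 2L || nrow(teto) > 2L) {
      rows[[length(rows) + 1L]] <- rec(FALSE, ">2 landmark spots", NA_character_)
      next
    }
    dd <- cross_dist(
      as.matrix(teto[, c("x_nm", "y_nm")]),
      as.matrix(laco[, c("x_nm", "y_nm")])
    )
    hit <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    anchor <- c(
      (teto$x_nm[hit[1]] + laco$x_nm[hit[2]]) / 2,
      (teto$y_nm[hit[1]] + laco$y_nm[hit[2]]) / 2
    )
    dfoci <- dmc1$foci[dmc1$foci$nucleus_id == nid, , drop = FALSE]
    if (nrow(dfoci) == 0L) {
      rows[[length(rows) + 1L]] <- rec(FALSE, "no anchor focus", NA_character_)
      next
    }
    d_anchor <- sqrt((dfoci$x_nm - anchor[1])^2 + (dfoci$y_nm - anchor[2])^2)
    at_anchor <- which(d_anchor <= anchor_radius_nm)
    if (length(at_anchor) != 1L) {
      reason <- if (length(at_anchor) == 0L) "no anchor focus" else "multiple anchor foci"
      rows[[length(rows) + 1L]] <- rec(FALSE, reason, NA_character_)
      next
    }
    af <- dfoci[at_anchor, , drop = FALSE]
    d_af <- sqrt((dfoci$x_nm - af$x_nm)^2 + (dfoci$y_nm - af$y_nm)^2)
    extra <- sum(d_af <= horizon_nm) - 1L # closed ball, self excluded
    if (extra > max_extra) {
      rows[[length(rows) + 1L]] <- rec(FALSE, "too many nearby foci", NA_character_)
      next
    }
    call <- if (extra >= 1L) "pair" else "single"
    rows[[length(rows) + 1L]] <- rec(TRUE, "", call)
  }
  if (length(rows) == 0L) {
    return(data.frame(
      nucleus_id = character(0), eligible = logical(0), reason = character(0),
      call = character(0), tetO_split_nm = numeric(0),
      n_lacO = integer(0), n_tetO = integer(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
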