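# Independent brute-force oracles, structured differently from the
# package implementations they cross-check.

# per-focus nearest-neighbour distances by explicit double loop
oracle_nn <- function(a, b = NULL) {
  same <- is.null(b)
  if (same) b <- a
  out <- numeric(0)
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      if (same && i == j) next
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) out <- c(out, best)
  }
  out
}

# closed-form eigenvalues/vector of a symmetric 2x2 covariance
oracle_eigen2 <- function(m) {
  a <- m[1, 1]
  b <- m[1, 2]
  c <- m[2, 2]
  tr2 <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  l1 <- tr2 + disc
  l2 <- tr2 - disc
  v <- if (abs(b) > 1e-300) c(l1 - c, b) else if (a >= c) c(1, 0) else c(0, 1)
  v <- v / sqrt(sum(v^2))
  list(values = c(l1, l2), principal = v)
}

# rule-table classifier, independent structure: complexes by
# breadth-first search over the composite adjacency graph
oracle_vde <- function(foci, coloc_radius = 200, link = 1000) {
  foci <- foci[foci$channel %in% c("RAD51", "DMC1"), , drop = FALSE]
  n_r <- sum(foci$channel == "RAD51")
  n_d <- sum(foci$channel == "DMC1")
  if (n_r + n_d == 0) {
    return("NEGATIVE")
  }
  comp <- focipair:::form_composites(foci, coloc_radius)
  n <- nrow(comp)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt((comp$x_nm[i] - comp$x_nm[j])^2 + (comp$y_nm[i] - comp$y_nm[j])^2)
      adj[i, j] <- d <= link
    }
  }
  seen <- logical(n)
  n_complexes <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    n_complexes <- n_complexes + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  if (n_complexes == 1L) {
    if (n == 1L) {
      "I"
    } else if (n == 2L) {
      "II"
    } else {
      "III"
    }
  } else {
    if (n_r <= 2L && n_d <= 2L) "IV" else "V"
  }
}

# build a focus_set quickly from coordinate vectors
fs_from_xy <- function(x, y, channel = "RAD51", nucleus_id = "n1",
                       intensity = 100, nuclei = NULL) {
  focus_set(
    data.frame(
      nucleus_id = nucleus_id, channel = channel,
      x_nm = x, y_nm = y, intensity = intensity,
      stringsAsFactors = FALSE
    ),
    nuclei
  )
}

# random multi-nucleus two-channel focus set with linked disc nuclei
random_focus_set <- function(n_nuclei, max_foci, area_um2 = 50, seed = 1) {
  set.seed(seed)
  nuclei <- lapply(seq_len(n_nuclei), function(i) {
    make_nucleus(area_um2, sprintf("n%d", i))
  })
  rows <- list()
  for (i in seq_len(n_nuclei)) {
    for (ch in c("RAD51", "DMC1")) {
      k <- sample(0:max_foci, 1)
      if (k == 0) next
      xy <- region_sample(nuclei[[i]]$region, k)
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus_id = nuclei[[i]]$nucleus_id, channel = ch,
        x_nm = xy[, 1], y_nm = xy[, 2],
        intensity = stats::rlnorm(k, log(100), 0.5),
        stringsAsFactors = FALSE
      )
    }
  }
  focus_set(do.call(rbind, rows), nuclei)
}
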