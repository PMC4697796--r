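#!/usr/bin/env Rscript
# Two-channel co-focus analysis and per-nucleus classification of the
# simulated dataset: cross-channel colocalization fractions, mutual-NN
# pair detection with the full composition table, intensity-share
# regression (independence of the two co-foci of a pair), the category
# I-V classifier, and a landmark-selection demonstration.

suppressPackageStartupMessages(library(focipair))
stopifnot(file.exists("results/foci.tsv"))
seed <- 20260926L
cfg <- analysis_config()

nuclei <- lapply(sprintf("n%02d", 1:40), function(id) make_nucleus(50, id))
foci <- read_focus_table("results/foci.tsv", nuclei = nuclei)
r <- subset_foci(foci, channel = "RAD51")
d <- subset_foci(foci, channel = "DMC1")

cat(sprintf(
  "cross-channel colocalization (< %g nm): RAD51->DMC1 %.0f%%, DMC1->RAD51 %.0f%%\n",
  cfg$coloc_radius_nm,
  100 * cross_fraction_within(r, d, cfg$coloc_radius_nm),
  100 * cross_fraction_within(d, r, cfg$coloc_radius_nm)
))

pairs <- detect_pairs(foci, cfg)
write.table(pairs, "results/pairs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cmp <- pair_composition_fraction(pairs)
cat(sprintf(
  "%d pairs detected; both-co-foci fraction %.2f; composition: %s\n",
  nrow(pairs), cmp$fraction_both_cofoci,
  paste(names(cmp$composition), cmp$composition, sep = "=", collapse = " ")
))

sh <- pair_intensity_shares(pairs)
cat(sprintf(
  "intensity shares over %d co-focus pairs: slope %.3f (independent assembly ~ 0)\n",
  nrow(sh$shares), sh$slope
))

# the category I-V classifier belongs to the single-cut-site setting:
# per nucleus 0, 1 or 2 DSBs are present at any instant, so simulate a
# matching sparse dataset rather than reusing the dense one above
vde_sets <- focipair:::with_seed(seed + 9, {
  lapply(1:100, function(i) {
    ndsb <- sample(0:2, 1, prob = c(0.5, 0.3, 0.2))
    simulate_dsb_pattern(
      make_nucleus(50, sprintf("v%03d", i)),
      pair_model_params(n_dsb = ndsb),
      seed = seed + 200 + i
    )
  })
})
vde_foci <- do.call(combine_focus_sets, vde_sets)
vt <- vde_classify(vde_foci, cfg)
write.table(vt, "results/vde_categories.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
fp <- focus_positive_fraction(vt$category)
cat(sprintf(
  "cut-site-style categories over 100 nuclei: %s; focus-positive %d%%\n",
  paste(names(table(vt$category)), table(vt$category), sep = "=", collapse = " "),
  fp$percent
))

# landmark selection on a dedicated small simulation: a cut-site locus
# flanked by tetO/lacO arrays, one anchor DMC1 focus, sometimes paired
lmk <- focipair:::with_seed(seed + 5, {
  rows <- list()
  dmc1_rows <- list()
  for (i in 1:30) {
    nid <- sprintf("L%02d", i)
    base <- c(2000, 2000)
    teto <- base + runif(2, -300, 300)
    laco <- base + c(800, 0) + runif(2, -300, 300)
    rows[[i]] <- data.frame(
      nucleus_id = nid, kind = c("tetO", "lacO"),
      x_nm = c(teto[1], laco[1]), y_nm = c(teto[2], laco[2]),
      stringsAsFactors = FALSE
    )
    anchor <- (teto + laco) / 2
    xs <- anchor[1]
    ys <- anchor[2]
    if (runif(1) < 0.4) { # paired locus: second focus resolvable, i.e.
      # outside the 300 nm anchor radius but within the 1 um horizon
      th <- runif(1, 0, 2 * pi)
      sep <- runif(1, 400, 800)
      xs <- c(xs, anchor[1] + sep * cos(th))
      ys <- c(ys, anchor[2] + sep * sin(th))
    }
    dmc1_rows[[i]] <- data.frame(
      nucleus_id = nid, channel = "DMC1", x_nm = xs, y_nm = ys,
      intensity = 100, stringsAsFactors = FALSE
    )
  }
  list(landmarks = do.call(rbind, rows), dmc1 = focus_set(do.call(rbind, dmc1_rows)))
})
score <- landmark_filter_and_score(lmk$dmc1, lmk$landmarks)
write.table(score, "results/landmark_calls.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
el <- score[score$eligible, ]
cat(sprintf(
  "landmark demo: %d/%d nuclei eligible, %d called pair (%d%%)\n",
  nrow(el), nrow(score), sum(el$call == "pair"),
  focus_positive_fraction(sum(el$call == "pair"), nrow(el))$percent
))
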