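# End-to-end driver: a flat key-value run configuration, stage
# execution (simulate -> nn -> cofocus -> vde -> storm), TSV outputs and
# a machine- plus human-readable summary. One user seed governs all
# stages through fixed per-stage offsets, so stages are independently
# re-runnable yet jointly reproducible.

PIPELINE_DEFAULTS <- list(
  stages = "simulate,nn,cofocus,vde",
  seed = 1L,
  # generator
  n_nuclei = 20L, area_um2 = 50, n_dsb = 10L, n_background_per_channel = 0L,
  occupancy_both = 0.7, occupancy_rad51_only = 0.1,
  occupancy_dmc1_only = 0.1, occupancy_empty = 0.1,
  sep_min_nm = 150, sep_max_nm = 400, offset_max_nm = 150,
  # nn stage
  null_reps = 50L, censor = TRUE,
  # analysis thresholds
  pair_window_nm = 400, coloc_radius_nm = 200, resolution_censor_nm = 150,
  cluster_link_nm = 1000, density_threshold_per_um2 = 0.8,
  nn_bin_width_nm = 50, nn_max_nm = 2000,
  # storm stage (two-cluster artifact demonstration)
  storm_n_frames = 2000L, storm_p_on = 0.06, storm_photons = 800,
  storm_psf_sigma_nm = 75, storm_background = 1,
  storm_cluster_sep_nm = 300, storm_cluster_sigma_nm = 40,
  storm_emitters_per_cluster = 6L
)

# per-stage seed offsets (counter-based splitting of the one user seed)
STAGE_SEED_OFFSET <- c(simulate = 101L, nn = 202L, cofocus = 303L,
  vde = 404L, storm = 505L)

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_format("config must be a file path or a named list")
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    stop_format("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(PIPELINE_DEFAULTS, config)
}

#' Run the focus-pairing analysis pipeline
#'
#' Executes the configured stages over one synthetic dataset and writes
#' TSV tables plus a JSON and text summary to `out_dir`. The
#' configuration is a flat key-value list (or a YAML file of one); see
#' the packaged defaults in `focipair:::PIPELINE_DEFAULTS`. Re-running
#' with the same configuration reproduces identical outputs.
#'
#' @param config named list or path to a flat YAML file; unknown keys
#'   are an error.
#' @param out_dir output directory (created if needed).
#' @return the summary list from [make_report()], invisibly; files are
#'   the primary output.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_run_config(config)
  stages <- if (length(cfg$stages) > 1L) cfg$stages else
    trimws(strsplit(cfg$stages, ",")[[1]])
  known <- names(STAGE_SEED_OFFSET)
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop_format("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acfg <- analysis_config(
    pair_window_nm = cfg$pair_window_nm,
    coloc_radius_nm = cfg$coloc_radius_nm,
    resolution_censor_nm = cfg$resolution_censor_nm,
    cluster_link_nm = cfg$cluster_link_nm,
    density_threshold_per_um2 = cfg$density_threshold_per_um2,
    nn_bin_width_nm = cfg$nn_bin_width_nm,
    nn_max_nm = cfg$nn_max_nm,
    rng_seed = cfg$seed
  )
  outputs <- list(config = cfg)

  foci <- NULL
  if ("simulate" %in% stages) {
    params <- pair_model_params(
      n_dsb = cfg$n_dsb,
      pair_sep_sampler = function(n) stats::runif(n, cfg$sep_min_nm, cfg$sep_max_nm),
      cofocus_offset_sampler = function(n) stats::runif(n, 0, cfg$offset_max_nm),
      occupancy = c(
        both = cfg$occupancy_both, rad51_only = cfg$occupancy_rad51_only,
        dmc1_only = cfg$occupancy_dmc1_only, empty = cfg$occupancy_empty
      ),
      n_background_per_channel = cfg$n_background_per_channel
    )
    sets <- lapply(seq_len(cfg$n_nuclei), function(i) {
      simulate_dsb_pattern(
        make_nucleus(cfg$area_um2, sprintf("n%03d", i)),
        params,
        seed = cfg$seed + STAGE_SEED_OFFSET[["simulate"]] + i
      )
    })
    foci <- do.call(combine_focus_sets, sets)
    write_focus_table(foci, file.path(out_dir, "foci.tsv"))
    truths <- lapply(sets, function(s) attr(s, "dsb_truth"))
    truths <- truths[!vapply(truths, is.null, logical(1))]
    if (length(truths) > 0L) {
      tt <- do.call(rbind, Map(function(t, i) {
        cbind(nucleus_id = sprintf("n%03d", i), t)
      }, truths, seq_along(truths)))
      utils::write.table(tt, file.path(out_dir, "dsb_truth.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    outputs$simulate <- list(n_foci = n_foci(foci), n_nuclei = cfg$n_nuclei)
  }

  if ("nn" %in% stages) {
    if (is.null(foci)) stop_format("stage 'nn' requires stage 'simulate'")
    obs <- nn_histogram(
      nn_distances(subset_foci(foci, channel = "RAD51")), acfg,
      label = "observed RAD51->RAD51"
    )
    null <- simulate_matched_null(foci,
      channel = "RAD51", reps = cfg$null_reps,
      censor = isTRUE(cfg$censor), config = acfg,
      seed = cfg$seed + STAGE_SEED_OFFSET[["nn"]]
    )
    enr <- pairing_enrichment(obs, null, acfg)
    utils::write.table(enr$table, file.path(out_dir, "nn_rad51.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    outputs$nn <- list(
      p_hat_paired = enr$p_hat, window_nm = enr$window_nm,
      null_reps = cfg$null_reps, n_distances = obs$n_total
    )
  }

  if ("cofocus" %in% stages) {
    if (is.null(foci)) stop_format("stage 'cofocus' requires stage 'simulate'")
    r <- subset_foci(foci, channel = "RAD51")
    d <- subset_foci(foci, channel = "DMC1")
    pairs <- detect_pairs(foci, acfg)
    utils::write.table(pairs, file.path(out_dir, "pairs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    compo <- pair_composition_fraction(pairs)
    outputs$cofocus <- list(
      rad51_near_dmc1_fraction = cross_fraction_within(r, d, acfg$coloc_radius_nm),
      dmc1_near_rad51_fraction = cross_fraction_within(d, r, acfg$coloc_radius_nm),
      n_pairs = nrow(pairs),
      fraction_both_cofoci = compo$fraction_both_cofoci,
      composition = as.list(compo$composition)
    )
  }

  if ("vde" %in% stages) {
    if (is.null(foci)) stop_format("stage 'vde' requires stage 'simulate'")
    vt <- vde_classify(foci, acfg)
    utils::write.table(vt, file.path(out_dir, "vde_categories.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    fp <- focus_positive_fraction(vt$category)
    outputs$vde <- list(
      categories = as.list(table(vt$category)),
      focus_positive_fraction = fp$fraction,
      focus_positive_percent = fp$percent
    )
  }

  if ("storm" %in% stages) {
    half <- cfg$storm_cluster_sep_nm / 2
    centre <- c(800, 600)
    a <- centre + c(-half, 0)
    b <- centre + c(half, 0)
    storm_seed <- cfg$seed + STAGE_SEED_OFFSET[["storm"]]
    pos <- with_seed(storm_seed, rbind(
      emitters_point_cluster(a, cfg$storm_cluster_sigma_nm, cfg$storm_emitters_per_cluster),
      emitters_point_cluster(b, cfg$storm_cluster_sigma_nm, cfg$storm_emitters_per_cluster)
    ))
    model <- emitter_model(pos,
      p_on = cfg$storm_p_on, photons_mean = cfg$storm_photons,
      psf_sigma_nm = cfg$storm_psf_sigma_nm,
      background_rate = cfg$storm_background
    )
    sim <- simulate_blink_stack(model, cfg$storm_n_frames,
      seed = storm_seed + 1L,
      bounds = c(1600, 1200)
    )
    curve <- artifact_decay_curve(sim$stack, a, b)
    utils::write.table(as.data.frame(curve),
      file.path(out_dir, "artifact_curve.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    locs <- localize_frames(sim$stack, fwhm_cutoff_px = 2)
    write_localization_table(locs, file.path(out_dir, "localizations.tsv"))
    outputs$storm <- list(
      n_locs_2px = nrow(locs),
      midpoint_fraction_open = curve$midpoint_fraction[is.infinite(curve$cutoff_px)],
      midpoint_fraction_2px = curve$midpoint_fraction[curve$cutoff_px == 2][1]
    )
  }

  report <- make_report(outputs)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(report$text, file.path(out_dir, "summary.txt"))
  invisible(report$summary)
}

#' Combine focus sets
#'
#' Concatenates the foci and merges the nucleus records of several
#' focus sets (duplicate nucleus ids must refer to identical records).
#'
#' @param ... `focus_set` objects.
#' @return a [focus_set()].
#' @export
combine_focus_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "focus_set")))
  foci <- do.call(rbind, lapply(sets, function(s) s$foci))
  nuclei <- do.call(c, lapply(sets, function(s) s$nuclei))
  nuclei <- nuclei[!duplicated(names(nuclei))]
  focus_set(foci, nuclei)
}

#' Build a run summary from stage outputs
#'
#' Cross-references every reported number to the stage that produced it
#' and the thresholds in force; missing stages are listed as absent,
#' not fatal.
#'
#' @param outputs named list of per-stage output lists (as assembled by
#'   [run_pipeline()]), with element `config`.
#' @return list with `summary` (machine-readable) and `text` (lines).
#' @export
make_report <- function(outputs) {
  cfg <- outputs$config %||% PIPELINE_DEFAULTS
  stage_names <- c("simulate", "nn", "cofocus", "vde", "storm")
  present <- intersect(stage_names, names(outputs))
  absent <- setdiff(stage_names, present)
  summary <- list(
    seed = cfg$seed,
    thresholds = list(
      pair_window_nm = cfg$pair_window_nm,
      coloc_radius_nm = cfg$coloc_radius_nm,
      resolution_censor_nm = cfg$resolution_censor_nm,
      cluster_link_nm = cfg$cluster_link_nm,
      density_threshold_per_um2 = cfg$density_threshold_per_um2
    ),
    stages = outputs[present],
    stages_absent = absent
  )
  text <- c(
    sprintf("focipair run summary (seed %s)", cfg$seed),
    sprintf(
      "thresholds: pair window %g nm, coloc %g nm, censor %g nm, link %g nm",
      cfg$pair_window_nm, cfg$coloc_radius_nm,
      cfg$resolution_censor_nm, cfg$cluster_link_nm
    )
  )
  if (length(present) == 0L) {
    text <- c(text, "no stages run")
  }
  for (s in present) {
    vals <- outputs[[s]]
    flat <- unlist(vals)
    text <- c(text, sprintf("[%s] %s", s, paste(
      names(flat), vapply(flat, function(v) format(v, digits = 4), character(1)),
      sep = "=", collapse = " "
    )))
  }
  if (length(absent) > 0L) {
    text <- c(text, sprintf("stages not run: %s", paste(absent, collapse = ", ")))
  }
  list(summary = summary, text = text)
}
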