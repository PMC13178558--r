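#' Pipeline configuration
#'
#' Assembles the full-run configuration: which stages to run, where files
#' live, the synthetic-generation settings (ZINB parameters per
#' strain x condition and spot-table settings), the MCMC settings, and one
#' global seed. Stage seeds are derived from the global seed by a fixed
#' counter scheme (`seed + 1000 * stage_index`, stages numbered simulate = 0,
#' quantify = 1, stats = 2, infer = 3), so each stage is individually
#' reproducible. The whole object is JSON-serializable; re-running the same
#' config and seed reproduces every output byte-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param stages Character subset of `c("simulate", "quantify", "stats",
#'   "infer")`; `"all"` expands to all four.
#' @param synthetic Tibble describing the synthetic conditions: columns
#'   `strain`, `condition_uM`, `omega`, `r`, `p`, `n_cells`. Default: one
#'   strain over the ladder 0/5/50/100 uM with repression rising with
#'   tryptophan.
#' @param unit_intensity,intensity_cv,n_control,control_scale Spot-table
#'   generation settings (see [generate_spot_table()]).
#' @param n_components Gaussian components for intensity calibration
#'   (default 1: the generator emits one spot per molecule, so synthetic
#'   intensities form a single quantal component).
#' @param mcmc An [mcmc_config()] (its `seed` is overridden by the derived
#'   stage seed).
#' @param counts_csv,spots_csv,control_csv Input paths for non-synthetic
#'   runs; when the simulate stage is active these are produced in
#'   `out_dir`.
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "burstfish_run",
                            stages = "all",
                            synthetic = default_synthetic_design(),
                            unit_intensity = 100,
                            intensity_cv = 0.05,
                            n_control = 500,
                            control_scale = 0.15 * unit_intensity,
                            n_components = 1,
                            mcmc = mcmc_config(),
                            counts_csv = NULL,
                            spots_csv = NULL,
                            control_csv = NULL,
                            seed = 1) {
  all_stages <- c("simulate", "quantify", "stats", "infer")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
      class = "burstfish_config_error"
    )
  }
  need <- c("strain", "condition_uM", "omega", "r", "p", "n_cells")
  if (!all(need %in% names(synthetic))) {
    abort(paste0("`synthetic` needs columns: ", paste(need, collapse = ", ")),
      class = "burstfish_config_error"
    )
  }
  structure(
    list(
      out_dir = out_dir, stages = stages,
      synthetic = as_tibble(synthetic),
      unit_intensity = unit_intensity, intensity_cv = intensity_cv,
      n_control = n_control, control_scale = control_scale,
      n_components = n_components, mcmc = mcmc,
      counts_csv = counts_csv, spots_csv = spots_csv,
      control_csv = control_csv, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Default synthetic study design
#'
#' One wild-type-like strain across the tryptophan ladder 0/5/50/100 uM
#' (0, 1x, 10x, 20x). Repression omega rises and burst size falls with
#' tryptophan, mimicking attenuation-mediated shutoff of the trp operon;
#' 300 cells per condition keep a full run fast while leaving the
#' population statistics stable.
#'
#' @return Tibble with columns `strain`, `condition_uM`, `omega`, `r`, `p`,
#'   `n_cells`.
#' @export
default_synthetic_design <- function() {
  tibble(
    strain = "WT",
    condition_uM = c(0, 5, 50, 100),
    omega = c(0.1, 0.3, 0.6, 0.8),
    r = c(1.5, 1.2, 1.0, 0.8),
    p = c(0.75, 0.70, 0.60, 0.50),
    n_cells = 300L
  )
}

stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "quantify", "stats", "infer")) - 1L
  as.integer(seed + 1000L * idx)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates simulate -> quantify -> stats -> infer per the config.
#' Outputs written under `config$out_dir`: `counts_true.csv`, `spots.csv`
#' and `control.csv` (simulate); `calibration.json` and `counts.csv`
#' (quantify); `noise_summary.csv`, `spearman.json` and `decay_fits.json`
#' (stats); `burst_estimates.json` (infer); plus `manifest.json` with the
#' config hash, package version and seed. Groups are processed in sorted
#' (strain, condition) order so logs and outputs are deterministic.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `counts`,
#'   `calibration`, `noise_summary`, `spearman`, `decay_fits`,
#'   `burst_estimates`, `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.",
      class = "burstfish_config_error"
    )
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  results <- list()
  counts <- NULL
  spots <- NULL

  if ("simulate" %in% config$stages) {
    say("[simulate] %d condition group(s)", nrow(config$synthetic))
    set.seed(stage_seed(config$seed, "simulate"))
    design <- arrange(config$synthetic, .data$strain, .data$condition_uM)
    pieces <- purrr::pmap(design, function(strain, condition_uM, omega, r, p,
                                           n_cells, ...) {
      cts <- sample_zinb(zinb_params(omega, r, p), n_cells,
        strain = strain, condition_uM = condition_uM
      )
      cts$cell_id <- sprintf("%s_%g_%s", strain, condition_uM, cts$cell_id)
      cts
    })
    counts <- bind_rows(pieces)
    tab <- generate_spot_table(counts,
      unit_intensity = config$unit_intensity,
      intensity_cv = config$intensity_cv,
      n_control = config$n_control,
      control_scale = config$control_scale
    )
    spots <- tab
    paths$counts_true <- file.path(config$out_dir, "counts_true.csv")
    paths$spots <- file.path(config$out_dir, "spots.csv")
    paths$control <- file.path(config$out_dir, "control.csv")
    write_counts(counts, paths$counts_true)
    write_spots(tab, paths$spots, paths$control)
  }

  if ("quantify" %in% config$stages) {
    if (is.null(spots)) {
      if (is.null(config$spots_csv) || is.null(config$control_csv)) {
        abort("quantify stage needs `spots_csv` and `control_csv` inputs.",
          class = "burstfish_config_error"
        )
      }
      spots <- read_spots(config$spots_csv, config$control_csv)
    }
    say("[quantify] %d spots, %d cells", nrow(spots$spots),
      length(spots$cells))
    calib <- calibrate_intensities(spots, n_components = config$n_components)
    quantified <- quantify_counts(spots, calib)
    # carry strain/condition labels over from the simulated truth if present
    if (!is.null(counts)) {
      quantified$strain <- counts$strain[match(quantified$cell_id,
        counts$cell_id)]
      quantified$condition_uM <- counts$condition_uM[match(
        quantified$cell_id, counts$cell_id
      )]
    }
    counts <- quantified
    results$calibration <- calib
    paths$calibration <- file.path(config$out_dir, "calibration.json")
    paths$counts <- file.path(config$out_dir, "counts.csv")
    write_calibration(calib, paths$calibration)
    write_counts(counts, paths$counts)
  }

  if (is.null(counts) && any(c("stats", "infer") %in% config$stages)) {
    if (is.null(config$counts_csv)) {
      abort("stats/infer stages need `counts_csv` when no upstream stage ran.",
        class = "burstfish_config_error"
      )
    }
    counts <- read_counts(config$counts_csv)
  }
  results$counts <- counts

  if ("stats" %in% config$stages) {
    say("[stats] summarizing %d cells", nrow(counts))
    noise <- summarize_counts(counts)
    results$noise_summary <- noise
    paths$noise_summary <- file.path(config$out_dir, "noise_summary.csv")
    readr::write_csv(noise, paths$noise_summary, progress = FALSE)
    per_strain <- split(noise, noise$strain)
    sp <- purrr::map(per_strain, function(g) {
      g <- filter(g, is.finite(.data$cv2) & is.finite(.data$fano))
      if (nrow(g) < 3L) {
        return(NULL)
      }
      list(
        noise_vs_mean = as.list(spearman_exact(g, .data$mu, .data$cv2)),
        burstiness_vs_mean = as.list(spearman_exact(g, .data$mu, .data$fano))
      )
    })
    fits <- purrr::map(per_strain, function(g) {
      g <- filter(g, is.finite(.data$cv2) & is.finite(.data$fano))
      if (length(unique(g$mu)) < 4L) {
        return(NULL)
      }
      fit_one <- function(y) {
        tryCatch(
          {
            f <- fit_exp_decay(x = g$mu, y = y)
            list(
              y0 = f$y0, plateau = f$plateau, k = f$k,
              r_squared = f$r_squared
            )
          },
          burstfish_fit_error = function(e) list(error = conditionMessage(e))
        )
      }
      list(noise = fit_one(g$cv2), burstiness = fit_one(g$fano))
    })
    results$spearman <- sp
    results$decay_fits <- fits
    paths$spearman <- file.path(config$out_dir, "spearman.json")
    paths$decay_fits <- file.path(config$out_dir, "decay_fits.json")
    jsonlite::write_json(sp, paths$spearman, auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null")
    jsonlite::write_json(fits, paths$decay_fits, auto_unbox = TRUE,
      digits = NA, pretty = TRUE, null = "null")
  }

  if ("infer" %in% config$stages) {
    groups <- counts %>%
      dplyr::distinct(.data$strain, .data$condition_uM) %>%
      arrange(.data$strain, .data$condition_uM)
    say("[infer] MCMC for %d group(s)", nrow(groups))
    base_seed <- stage_seed(config$seed, "infer")
    estimates <- purrr::pmap(
      list(groups$strain, groups$condition_uM, seq_len(nrow(groups))),
      function(st, cond, i) {
        g <- filter(counts, .data$strain == st, .data$condition_uM == cond)
        cfg <- config$mcmc
        cfg$seed <- base_seed + i
        chain <- run_mcmc(g, cfg)
        est <- summarize_posterior(chain)
        say(
          "  %s @ %g uM: omega MAP %.3f, b MAP %.2f, f MAP %.2f (acc %.2f)",
          st, cond, est$map[est$term == "omega"], est$map[est$term == "b"],
          est$map[est$term == "f"], chain$acceptance_rate
        )
        list(
          strain = st, condition_uM = cond, n_cells = nrow(g),
          map = as.list(setNames(est$map, est$term)),
          ci95 = purrr::map2(
            est$conf.low, est$conf.high, ~ c(.x, .y)
          ) |> setNames(est$term),
          acceptance_rate = chain$acceptance_rate,
          config = list(
            n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
            proposal_frac = cfg$proposal_frac,
            hastings_correction = cfg$hastings_correction, seed = cfg$seed
          )
        )
      }
    )
    results$burst_estimates <- estimates
    paths$burst_estimates <- file.path(config$out_dir, "burst_estimates.json")
    jsonlite::write_json(estimates, paths$burst_estimates, auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "burstfish",
    version = as.character(utils::packageVersion("burstfish")),
    seed = config$seed,
    stages = config$stages,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
    pretty = TRUE)
  results$paths <- paths
  invisible(results)
}
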