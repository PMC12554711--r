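#' Run the full pre/post EEG analysis pipeline
#'
#' Orchestrates every stage: obtain a cohort (synthetic, or recordings plus
#' a scale CSV on disk), preprocess and extract the feature grid, run the
#' paired indicator t-tests, correlate feature changes with both scale
#' changes, compute responder rates, fit the permutation-validated
#' leave-one-out SVR for both scales, and write all tables, JSON results
#' and topographic maps into a result directory.
#'
#' @param config Either a YAML file path or a nested list with elements:
#'   \describe{
#'     \item{cohort}{For a synthetic run, a list of [synthetic_config()]
#'       arguments under `synthetic`; for recorded data, `recordings_dir`
#'       (files `<subject>_<pre|post>.csv` or `.edf`) and `scale_csv`.}
#'     \item{features}{Optional [feature_params()] argument overrides.}
#'     \item{prognosis}{Optional: `alpha`, `selection`, plus
#'       [model_config()] argument overrides (`n_permutations`, `seed`,
#'       ...).}
#'     \item{topomaps}{Logical: render statistic topographies (default
#'       `TRUE`).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return The output directory path, invisibly; a `run_log.txt` inside it
#'   lists seeds, sizes and files written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("eegprognosr", as.character(utils::packageVersion("eegprognosr"))),
                 paste("R", getRversion()))
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$cohort$synthetic)) {
    scfg <- do.call(synthetic_config, config$cohort$synthetic)
    cohort <- generate_cohort(scfg)
    logf("synthetic cohort: n_subjects=%d seed=%d effect=%s@%s size=%g",
         scfg$n_subjects, scfg$seed, scfg$effect_band, scfg$effect_channel,
         scfg$effect_size)
  } else if (!is.null(config$cohort$recordings_dir)) {
    cohort <- read_cohort_dir(config$cohort$recordings_dir,
                              config$cohort$scale_csv)
    logf("cohort read from %s: %d subjects", config$cohort$recordings_dir,
         length(cohort$recordings))
  } else {
    stop("config$cohort must name either a synthetic spec or recordings_dir + scale_csv")
  }
  scores <- cohort$scores
  validate_scale_table(scores)

  # --- features -----------------------------------------------------------
  params <- do.call(feature_params, config$features %||% list())
  features <- extract_features(cohort, params)
  write_feature_table(features, file.path(out_dir, "features.tsv"))
  logf("feature table: %d rows", nrow(features))

  # --- group statistics ---------------------------------------------------
  ttests <- ttest_all_indicators(features)
  write_stat_table(ttests, file.path(out_dir, "ttest_indicators.tsv"))
  sct <- scale_ttests(scores)
  write_stat_table(sct, file.path(out_dir, "scale_ttests.tsv"))
  diffs <- feature_differences(features)
  sdiffs <- scale_differences(scores)
  cors <- list()
  for (sc in c("psqi", "isi")) {
    cors[[sc]] <- correlate_with_outcome(diffs, sdiffs, sc)
    write_stat_table(cors[[sc]], file.path(out_dir, paste0("correlations_", sc, ".tsv")))
  }
  responders <- list(psqi = responder_rate(scores, "psqi"),
                     isi = responder_rate(scores, "isi"))
  logf("responder rates: psqi=%.4f isi=%.4f", responders$psqi, responders$isi)

  # --- prognosis ----------------------------------------------------------
  pcfg_args <- config$prognosis %||% list()
  alpha <- pcfg_args$alpha %||% 0.05
  selection <- pcfg_args$selection %||% "full"
  mcfg <- do.call(model_config,
                  pcfg_args[setdiff(names(pcfg_args), c("alpha", "selection"))])
  for (sc in c("psqi", "isi")) {
    res <- run_prognosis(features, scores, sc, alpha = alpha, cfg = mcfg,
                         selection = selection)
    out <- list(
      scale = sc, selection = selection,
      observed_r = res$observed_r, p = res$p,
      n_permutations = res$n_permutations, seed = res$seed,
      n_selected = res$n_selected, selected = res$selected,
      predictions = res$loo_predictions, y = res$y,
      empty = isTRUE(res$empty)
    )
    jsonlite::write_json(out, file.path(out_dir, paste0("prognosis_", sc, ".json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (length(res$null_rs) > 0) {
      readr::write_tsv(tibble::tibble(null_r = res$null_rs),
                       file.path(out_dir, paste0("null_distribution_", sc, ".tsv")))
    }
    logf("prognosis %s: r=%.4f p=%.4f selected=%d", sc,
         res$observed_r %||% NA, res$p %||% NA, res$n_selected)
  }
  jsonlite::write_json(responders, file.path(out_dir, "responder_rates.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  # --- topomaps -----------------------------------------------------------
  if (isTRUE(config$topomaps %||% TRUE)) {
    tmap_dir <- file.path(out_dir, "topomaps")
    dir.create(tmap_dir, showWarnings = FALSE)
    for (b in band_names()) {
      sub <- ttests[ttests$band == b & ttests$feature == "PSD", ]
      vals <- stats::setNames(sub$statistic, sub$channel)
      render_topomap(vals, out_path = file.path(tmap_dir, paste0("ttest_PSD_", b, ".png")),
                     title = paste("paired t, band power,", b))
    }
    logf("topomaps written to %s", tmap_dir)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a cohort of recordings and scores from disk
#'
#' Recording files are named `<subject>_<pre|post>.csv` or `.edf`; every
#' subject in the scale CSV must have both sessions.
#'
#' @param recordings_dir Directory of recording files.
#' @param scale_csv Path to the scale CSV.
#' @return A cohort list (`recordings`, `scores`) as from [generate_cohort()].
#' @export
read_cohort_dir <- function(recordings_dir, scale_csv) {
  scores <- read_scale_table(scale_csv)
  recordings <- purrr::map(scores$subject_id, function(sid) {
    purrr::map(c(pre = "pre", post = "post"), function(ses) {
      base <- file.path(recordings_dir, paste0(sid, "_", ses))
      if (file.exists(paste0(base, ".csv"))) {
        read_recording_csv(paste0(base, ".csv"), subject_id = sid, session = ses)
      } else if (file.exists(paste0(base, ".edf"))) {
        read_recording_edf(paste0(base, ".edf"), subject_id = sid, session = ses)
      } else {
        stop("cohort integrity error: subject ", sid, " is missing the ",
             ses, " session (expected ", base, ".csv or .edf)")
      }
    })
  })
  names(recordings) <- scores$subject_id
  list(recordings = recordings, scores = scores)
}
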