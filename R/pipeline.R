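#' Run the full simulate -> preprocess -> detect -> threshold -> agree pipeline
#'
#' Orchestrates every stage for a synthetic cohort: generates the cohort,
#' preprocesses each recording (band-pass, baseline, 2-SD RMS rejection,
#' averaging), runs the requested detection methods, estimates ACC
#' thresholds over the SNR grid, applies the dead-region rules, and computes
#' the method-agreement and repeatability statistics. All randomness derives
#' from the single `seed` via a per-stage/per-recording splitting scheme, so
#' two runs with the same configuration are identical.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   entries: `design` (field overrides for [acc_design()]), `cohort`
#'   (`n_participants`, `dr_spec`, `attrition_fraction`), `detect`
#'   (`methods`, `n_boot`, `resample_size`, `alpha`,
#'   `bootstrap_pooling` = "per_ear" or "pooled"), `filter` (logical),
#'   and `seed`.
#' @param seed master seed; overrides `config$seed` when given.
#' @param out_dir optional directory; when set, all tables are written as
#'   CSV and the manifest as YAML.
#' @return A list of tibbles: `detections`, `thresholds`, `dead_regions`,
#'   `agreement`, `repeatability`, `behavioural`, `manifest`, plus
#'   `config` (the fully-resolved configuration) and `files` (paths
#'   written, if any).
#' @examples
#' \donttest{
#' res <- run_pipeline(list(
#'   design = list(fs = 256, sweeps = 20),
#'   cohort = list(n_participants = 2),
#'   detect = list(n_boot = 99)), seed = 1)
#' res$thresholds
#' }
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  design <- do.call(acc_design, config$design)
  validate_design(design)
  methods <- config$detect$methods

  cohort <- simulate_cohort(
    design,
    n_participants = config$cohort$n_participants,
    dr_spec = config$cohort$dr_spec,
    attrition_fraction = config$cohort$attrition_fraction,
    seed = split_seed(config$seed, "cohort")
  )

  # preprocess every present recording once; keep the cleaned epochs so the
  # bootstrap detector can resample them without re-filtering
  cleaned <- lapply(cohort$epochs, function(e) {
    if (config$filter) e <- filter_epochs(e)
    reject_artifacts(baseline_correct(e))
  })
  averages <- lapply(cleaned, average_epochs)

  man <- cohort$manifest
  detections <- list()
  for (i in seq_len(nrow(man))) {
    if (!man$present[i]) next
    key <- man$key[i]
    avg <- averages[[key]]
    row_ids <- man[i, c("participant", "frequency_hz", "snr_db",
                        "repetition", "channel")]
    if ("rms" %in% methods) {
      detections[[length(detections) + 1]] <-
        dplyr::bind_cols(row_ids, detect_rms(avg, design))
    }
    if ("bootstrap" %in% methods) {
      ep_ipsi <- cleaned[[key]]
      ep_contra <- NULL
      if (config$detect$bootstrap_pooling == "pooled") {
        other <- sub(paste0(man$channel[i], "$"),
                     setdiff(c("ipsi", "contra"), man$channel[i]), key)
        ep_contra <- cleaned[[other]]
      }
      detections[[length(detections) + 1]] <- dplyr::bind_cols(
        row_ids,
        detect_bootstrap(ep_ipsi, ep_contra, design,
                         n_boot = config$detect$n_boot,
                         resample_size = config$detect$resample_size,
                         alpha = config$detect$alpha,
                         seed = split_seed(config$seed, paste0("boot_", key))))
    }
  }
  # BSA pairs the two repetitions of one condition/channel
  if ("bsa" %in% methods) {
    pairs <- unique(man[man$repetition == 1,
                        c("participant", "frequency_hz", "snr_db", "channel")])
    for (i in seq_len(nrow(pairs))) {
      k1 <- paste(pairs$participant[i], pairs$frequency_hz[i], pairs$snr_db[i],
                  1, pairs$channel[i], sep = "_")
      k2 <- paste(pairs$participant[i], pairs$frequency_hz[i], pairs$snr_db[i],
                  2, pairs$channel[i], sep = "_")
      if (is.null(averages[[k1]]) || is.null(averages[[k2]])) next
      row_ids <- dplyr::mutate(pairs[i, ], repetition = NA_integer_,
                               .after = "snr_db")
      detections[[length(detections) + 1]] <- dplyr::bind_cols(
        row_ids, detect_bsa(averages[[k1]], averages[[k2]], design))
    }
  }
  detections <- dplyr::bind_rows(detections)

  thresholds <- threshold_table(detections, design)
  dead_regions <- dr_table(thresholds, cohort$behavioural,
                           acc_cutoff_db = config$dr_cutoff_db)
  agr <- agreement_tables(thresholds)

  out <- list(detections = detections, thresholds = thresholds,
              dead_regions = dead_regions, agreement = agr$agreement,
              repeatability = agr$repeatability,
              behavioural = cohort$behavioural,
              manifest = man, config = config, files = character(0))
  if (!is.null(out_dir)) out$files <- write_pipeline_outputs(out, out_dir)
  out
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    design = list(),
    cohort = list(n_participants = 4, dr_spec = NULL, attrition_fraction = 0),
    detect = list(methods = c("rms", "bsa", "bootstrap"), n_boot = 499,
                  resample_size = NA, alpha = 0.05,
                  bootstrap_pooling = "per_ear"),
    filter = TRUE,
    dr_cutoff_db = 12,
    seed = 1L
  )
  known <- names(defaults)
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in known) {
    if (is.list(defaults[[nm]]) && !is.null(config[[nm]])) {
      sub_bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(sub_bad) && nm != "design") {
        stop("unknown config entries in ", nm, ": ",
             paste(sub_bad, collapse = ", "), call. = FALSE)
      }
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else if (!is.null(config[[nm]])) {
      defaults[[nm]] <- config[[nm]]
    }
  }
  if (!defaults$detect$bootstrap_pooling %in% c("per_ear", "pooled")) {
    stop("bootstrap_pooling must be 'per_ear' or 'pooled'", call. = FALSE)
  }
  if (!all(defaults$detect$methods %in% c("rms", "bsa", "bootstrap"))) {
    stop("methods must be among rms, bsa, bootstrap", call. = FALSE)
  }
  defaults
}

#' Per-recording ACC thresholds from a detection table
#'
#' Groups the detection table by participant, frequency, method, channel and
#' repetition and applies [estimate_threshold()] to each group's per-SNR
#' outcomes.
#'
#' @param detections detection tibble as produced by [run_pipeline()] (needs
#'   columns participant, frequency_hz, snr_db, repetition, channel, method,
#'   outcome).
#' @param design an [acc_design()].
#' @return Tibble of thresholds, one row per group, with the pattern string
#'   and determination flag.
#' @export
threshold_table <- function(detections, design) {
  grp <- dplyr::group_by(detections, .data$participant, .data$frequency_hz,
                         .data$method, .data$channel, .data$repetition)
  out <- dplyr::group_modify(grp, function(df, key) {
    estimate_threshold(df[, c("snr_db", "outcome")], design)
  })
  dplyr::ungroup(out)
}

dr_table <- function(thresholds, behavioural, acc_cutoff_db = 12) {
  # one screen per participant x frequency x method, using the first
  # repetition (or the repetition-free BSA threshold)
  th <- dplyr::filter(thresholds,
                      is.na(.data$repetition) | .data$repetition == 1,
                      .data$channel == "ipsi")
  th <- dplyr::left_join(th, behavioural,
                         by = c("participant", "frequency_hz"))
  out <- dplyr::rowwise(th)
  out <- dplyr::mutate(out, classify_dead_region(
    .data$threshold_db_snr, acc_cutoff_db = acc_cutoff_db)[, "acc_rule_positive"])
  dplyr::ungroup(out)[, c("participant", "frequency_hz", "method",
                          "threshold_db_snr", "str_db", "acc_rule_positive")]
}

agreement_tables <- function(thresholds) {
  # first repetition for RMS/bootstrap, the repetition-free BSA threshold;
  # ipsi and contra enter as repeated measurements keyed by participant
  first <- dplyr::filter(thresholds,
                         is.na(.data$repetition) | .data$repetition == 1)
  wide <- tidyr::pivot_wider(
    first[, c("participant", "frequency_hz", "channel", "method",
              "threshold_db_snr")],
    names_from = "method", values_from = "threshold_db_snr")
  pairs <- list(c("bsa", "rms"), c("bsa", "bootstrap"), c("rms", "bootstrap"))
  agreement <- list()
  for (f in unique(wide$frequency_hz)) {
    wf <- wide[wide$frequency_hz == f, ]
    for (p in pairs) {
      if (!all(p %in% names(wf))) next
      ok <- stats::complete.cases(wf[[p[1]]], wf[[p[2]]])
      if (sum(ok) < 3) next
      ba <- bland_altman(wf[[p[1]]][ok], wf[[p[2]]][ok], repeated = TRUE,
                         subject = wf$participant[ok])
      cc <- if (stats::var(wf[[p[1]]][ok]) > 0 && stats::var(wf[[p[2]]][ok]) > 0) {
        ccc(wf[[p[1]]][ok], wf[[p[2]]][ok])
      } else {
        tibble::tibble(ccc = NA_real_, conf_low = NA_real_,
                       conf_high = NA_real_, n = sum(ok))
      }
      agreement[[length(agreement) + 1]] <- tibble::tibble(
        comparison = paste(p, collapse = " vs "), frequency_hz = f,
        n = ba$n, bias = ba$bias,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        ci_bias_low = ba$ci_bias[1], ci_bias_high = ba$ci_bias[2],
        ccc = cc$ccc, ccc_low = cc$conf_low, ccc_high = cc$conf_high)
    }
  }
  reps <- dplyr::filter(thresholds, !is.na(.data$repetition))
  wide_r <- tidyr::pivot_wider(
    reps[, c("participant", "frequency_hz", "channel", "method",
             "repetition", "threshold_db_snr")],
    names_from = "repetition", values_from = "threshold_db_snr",
    names_prefix = "rep")
  repeat_tab <- list()
  for (f in unique(wide_r$frequency_hz)) {
    for (m in unique(wide_r$method)) {
      wf <- wide_r[wide_r$frequency_hz == f & wide_r$method == m, ]
      if (!all(c("rep1", "rep2") %in% names(wf))) next
      ok <- stats::complete.cases(wf$rep1, wf$rep2)
      if (sum(ok) < 3) next
      r <- repeatability(wf$rep1[ok], wf$rep2[ok], subject = wf$participant[ok])
      repeat_tab[[length(repeat_tab) + 1]] <- tibble::tibble(
        method = m, frequency_hz = f, n = r$n, bias = r$bias,
        loa_lower = r$loa_lower, loa_upper = r$loa_upper, cor = r$cor)
    }
  }
  list(agreement = dplyr::bind_rows(agreement),
       repeatability = dplyr::bind_rows(repeat_tab))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tabs <- c("detections", "thresholds", "dead_regions", "agreement",
            "repeatability", "behavioural", "manifest")
  for (nm in tabs) {
    if (is.null(out[[nm]]) || !nrow(out[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(out[[nm]], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  mf <- file.path(out_dir, "run_manifest.yaml")
  yaml::write_yaml(list(config = out$config, files = as.list(files)), mf)
  c(files, mf)
}
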