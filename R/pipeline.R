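#' Pipeline configuration
#'
#' Collects the tunable analysis constants: QC gate thresholds, the robust
#' outlier multiplier applied to control wells, and the SD multipliers of
#' the hit-selection and efflux-validation rules (both 3 by default).
#'
#' @param thresholds QC gate thresholds ([qc_thresholds()]).
#' @param outlier_k Control-well outlier multiplier (default 3).
#' @param hit_sd_multiplier SDs below the run mean for hit calling
#'   (default 3).
#' @param validation_sd_multiplier Control-SD multiplier for efflux
#'   validation (default 3).
#' @return Named list.
#' @export
run_config <- function(thresholds = qc_thresholds(), outlier_k = 3,
                       hit_sd_multiplier = 3, validation_sd_multiplier = 3) {
  stopifnot(outlier_k > 0, hit_sd_multiplier > 0, validation_sd_multiplier > 0)
  list(thresholds = thresholds, outlier_k = outlier_k,
       hit_sd_multiplier = hit_sd_multiplier,
       validation_sd_multiplier = validation_sd_multiplier)
}

#' Run the primary-screen analysis pipeline on raw plate reads
#'
#' Executes, in order: background subtraction, per-plate QC (CV, S:B, Z',
#' gate), control-anchored normalization, per-run hit thresholds over the
#' QC-passing plates, per-compound hit calls with duplicate confirmation,
#' replicate concordance, and screen rates. Compounds sitting on any
#' QC-failing or degenerate plate in either run are excluded from the
#' evaluable denominator; every exclusion is listed in the returned log.
#'
#' @param reads Well-level raw reads, as `reads` from [simulate_screen()]
#'   or stacked [read_plate_csv()] plates joined to a layout (must carry
#'   `plate_id`, `run_id`, `role`, `compound_id`, `baseline`, `final`).
#' @param config Analysis constants from [run_config()].
#' @param library_size Number of library compounds screened (defaults to
#'   the number of distinct compound ids present).
#' @return List of tibbles: `qc` (per plate), `normalized` (per well),
#'   `compounds` (per compound), `thresholds` (per run), `concordance`
#'   (controls and test wells), `rates`, and `exclusions` (compound,
#'   reason).
#' @export
run_screen_pipeline <- function(reads, config = run_config(),
                                library_size = NULL) {
  net <- subtract_background(reads)
  qc <- qc_plates(net, outlier_k = config$outlier_k,
                  thresholds = config$thresholds)
  normalized <- normalize_plates(net, outlier_k = config$outlier_k)
  res <- screen_result(normalized, qc,
                       sd_multiplier = config$hit_sd_multiplier)
  compounds <- res$compounds
  library_size <- library_size %||% nrow(compounds)

  failing <- qc$plate_id[!qc$passed]
  excl <- net[net$role == "TEST" & !is.na(net$compound_id) &
                net$plate_id %in% failing,
              c("compound_id", "plate_id")]
  exclusions <- if (nrow(excl) > 0) {
    dplyr::distinct(tibble::tibble(
      compound_id = excl$compound_id,
      reason = paste0("plate ", excl$plate_id, " failed QC")))
  } else {
    tibble::tibble(compound_id = character(0), reason = character(0))
  }

  nfs_cols <- grep("^nfs_run", names(compounds), value = TRUE)
  concordance <- NULL
  if (length(nfs_cols) >= 2) {
    ev <- compounds[compounds$evaluable, ]
    ctrl <- normalized[normalized$role %in%
                         c("ZERO_CONTROL", "POS_CONTROL", "ANTAG_CONTROL"), ]
    ctrl_conc <- NULL
    if ("plate_index" %in% names(ctrl)) {
      ctrl_wide <- ctrl |>
        dplyr::mutate(key = paste(.data$plate_index, .data$well)) |>
        dplyr::select("key", "run_id", "nfs") |>
        tidyr::pivot_wider(names_from = "run_id", values_from = "nfs")
      run_names <- setdiff(names(ctrl_wide), "key")
      if (length(run_names) >= 2 && nrow(ctrl_wide) >= 3) {
        ctrl_conc <- dplyr::mutate(
          replicate_concordance(ctrl_wide[[run_names[1]]],
                                ctrl_wide[[run_names[2]]]),
          well_class = "control")
      }
    }
    concordance <- dplyr::bind_rows(
      dplyr::mutate(replicate_concordance(ev[[nfs_cols[1]]], ev[[nfs_cols[2]]]),
                    well_class = "test"),
      ctrl_conc
    )
  }

  rates <- screen_rates(sum(compounds$hit_any), sum(compounds$confirmed),
                        sum(compounds$evaluable), library_size)
  list(qc = qc, normalized = normalized, compounds = compounds,
       thresholds = res$thresholds, concordance = concordance,
       rates = rates, exclusions = exclusions)
}

#' Screen-level QC and hit-selection summary tables
#'
#' Aggregates per-subtype pipeline results into the two standard screening
#' summary tables — a QC summary (control-CV range, average and SD of S:B
#' and Z', plate count, evaluable compounds, percent data passing QC) and a
#' hit-selection summary (unique and both-run hits with their rates, plus
#' validation columns when efflux results are supplied) — together with the
#' cross-assay mean adjusted hit rate and mean validation rate.
#'
#' @param results Named list (by subtype) of [run_screen_pipeline()]
#'   outputs.
#' @param validation Optional named list (by subtype) of lists/tibbles with
#'   `resupplied` and `validated` counts.
#' @return List with `qc_summary`, `hit_summary` (tibbles, one row per
#'   subtype) and `cross_assay` (tibble of means across subtypes).
#' @export
report_tables <- function(results, validation = NULL) {
  if (length(results) == 0) {
    return(list(
      qc_summary = tibble::tibble(subtype = character(0), cv_min = double(0),
                                  cv_max = double(0), avg_sb = double(0),
                                  sd_sb = double(0), avg_z_prime = double(0),
                                  sd_z_prime = double(0), n_plates = integer(0),
                                  n_evaluable = integer(0),
                                  pct_data_passed_qc = double(0)),
      hit_summary = tibble::tibble(subtype = character(0),
                                   n_hits_any = integer(0),
                                   primary_hit_rate = double(0),
                                   n_hits_all = integer(0),
                                   adjusted_hit_rate = double(0),
                                   n_resupplied = integer(0),
                                   n_validated = integer(0),
                                   validation_rate = double(0)),
      cross_assay = tibble::tibble(mean_adjusted_hit_rate = double(0),
                                   mean_validation_rate = double(0))))
  }
  qc_summary <- purrr::imap(results, function(r, st) {
    tibble::tibble(
      subtype = st,
      cv_min = min(r$qc$cv_pos), cv_max = max(r$qc$cv_pos),
      avg_sb = mean(r$qc$sb_ratio), sd_sb = stats::sd(r$qc$sb_ratio),
      avg_z_prime = mean(r$qc$z_prime, na.rm = TRUE),
      sd_z_prime = stats::sd(r$qc$z_prime, na.rm = TRUE),
      n_plates = nrow(r$qc),
      n_evaluable = r$rates$n_evaluable,
      pct_data_passed_qc = r$rates$pct_data_passed_qc)
  }) |> dplyr::bind_rows()

  hit_summary <- purrr::imap(results, function(r, st) {
    v <- validation[[st]]
    tibble::tibble(
      subtype = st,
      n_hits_any = r$rates$n_hits_any,
      primary_hit_rate = r$rates$primary_hit_rate,
      n_hits_all = r$rates$n_hits_all,
      adjusted_hit_rate = r$rates$adjusted_hit_rate,
      n_resupplied = if (is.null(v)) NA_integer_ else as.integer(v$resupplied),
      n_validated = if (is.null(v)) NA_integer_ else as.integer(v$validated),
      validation_rate = if (is.null(v)) NA_real_ else
        validation_rate(v$validated, v$resupplied))
  }) |> dplyr::bind_rows()

  cross_assay <- tibble::tibble(
    mean_adjusted_hit_rate = mean(hit_summary$adjusted_hit_rate),
    mean_validation_rate = mean(hit_summary$validation_rate))
  list(qc_summary = qc_summary, hit_summary = hit_summary,
       cross_assay = cross_assay)
}
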