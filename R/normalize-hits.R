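#' Subtract the baseline read from the final read
#'
#' The dye baseline is read before compound addition and subtracted from
#' the post-compound read well-by-well. Negative net signals are kept but
#' flagged.
#'
#' @param reads Tibble with `baseline` and `final` columns.
#' @return The input with `net = final - baseline` and logical
#'   `net_negative` columns appended.
#' @export
subtract_background <- function(reads) {
  stopifnot(all(c("baseline", "final") %in% names(reads)))
  if (any(is.na(reads$baseline)) || any(is.na(reads$final))) {
    stop("missing baseline/final read", call. = FALSE)
  }
  dplyr::mutate(reads, net = .data$final - .data$baseline,
                net_negative = .data$net < 0)
}

#' Normalize plates to in-plate controls
#'
#' Rescales net signal so that, per plate, the retained zero-control mean
#' maps to NFS 0 and the retained positive-control mean to NFS 1:
#' `nfs = (net - mean_zero) / (mean_pos - mean_zero)`. Control means are
#' taken after robust outlier removal ([remove_control_outliers()]), so the
#' anchoring holds exactly on the retained wells. Percent inhibition is
#' `100 * (1 - nfs)`.
#'
#' Plates whose control means coincide are degenerate: their wells get
#' `NA` NFS and the plate must be excluded downstream.
#'
#' @param plates Tibble with `plate_id`, `role`, `net`.
#' @param outlier_k Robust outlier multiplier for control wells (default 3).
#' @return Input with `nfs`, `pct_inhibition` and logical
#'   `control_retained` (FALSE only for control wells dropped as outliers)
#'   appended.
#' @export
normalize_plates <- function(plates, outlier_k = 3) {
  stopifnot(all(c("plate_id", "role", "net") %in% names(plates)))
  plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      pos_idx <- which(df$role == "POS_CONTROL")
      zero_idx <- which(df$role == "ZERO_CONTROL")
      pos <- remove_control_outliers(df$net[pos_idx], k = outlier_k)
      zero <- remove_control_outliers(df$net[zero_idx], k = outlier_k)
      if (length(pos$retained) < 2 || length(zero$retained) < 2) {
        stop("plate ", key$plate_id,
             ": fewer than 2 retained wells in a control class", call. = FALSE)
      }
      mu_pos <- mean(pos$retained)
      mu_zero <- mean(zero$retained)
      df$control_retained <- TRUE
      df$control_retained[pos_idx[pos$removed]] <- FALSE
      df$control_retained[zero_idx[zero$removed]] <- FALSE
      if (mu_pos == mu_zero) {
        df$nfs <- NA_real_
      } else {
        df$nfs <- (df$net - mu_zero) / (mu_pos - mu_zero)
      }
      df$pct_inhibition <- 100 * (1 - df$nfs)
      df
    }) |>
    dplyr::ungroup()
}

#' Hit-selection threshold for a screening run
#'
#' The threshold is `mean(NFS) - 3 * SD(NFS)` over all test wells of the
#' run (pooled across its QC-passing plates); wells with NFS strictly below
#' it are hits.
#'
#' @param run_nfs NFS values for every test well in the run (n >= 10).
#' @param sd_multiplier Number of SDs below the mean (default 3).
#' @return The threshold (dimensionless NFS).
#' @export
#' @examples
#' hit_threshold(c(rep(0.98, 50), rep(1.02, 50)))
hit_threshold <- function(run_nfs, sd_multiplier = 3) {
  run_nfs <- run_nfs[!is.na(run_nfs)]
  if (length(run_nfs) < 10) {
    stop("hit threshold requires at least 10 test wells", call. = FALSE)
  }
  mean(run_nfs) - sd_multiplier * stats::sd(run_nfs)
}

#' Call hits against a run threshold
#'
#' A well is a hit iff its NFS is strictly lower than the threshold.
#'
#' @param nfs NFS values.
#' @param threshold Run threshold from [hit_threshold()].
#' @return Logical vector (`NA` NFS gives `FALSE`).
#' @export
call_hits <- function(nfs, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, !is.na(threshold))
  !is.na(nfs) & nfs < threshold
}

#' Replicate concordance by linear regression
#'
#' Ordinary least-squares regression of the second run's NFS on the
#' first's; returns R-squared with the fitted slope and intercept.
#'
#' @param run1,run2 Paired NFS series (>= 3 pairs).
#' @return Tibble with `r_squared`, `slope`, `intercept`, `n`.
#' @export
replicate_concordance <- function(run1, run2) {
  keep <- stats::complete.cases(run1, run2)
  x <- run1[keep]
  y <- run2[keep]
  if (length(x) < 3) {
    stop("concordance requires at least 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("concordance undefined: zero variance in run 1", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x)
  )
}

#' Summarize a duplicate-run screen per compound
#'
#' Collapses normalized well records to one row per compound with its NFS
#' in each run, per-run hit flags (each run's own mean - 3 SD threshold),
#' the confirmed flag (hit in every run), and the evaluable flag (all of
#' the compound's plates passed QC and were non-degenerate).
#'
#' @param normalized Tibble of normalized well records with `run_id`,
#'   `plate_id`, `role`, `compound_id`, `nfs`.
#' @param qc QC report from [qc_plates()] (columns `plate_id`, `passed`).
#' @param sd_multiplier SD multiplier for the hit rule (default 3).
#' @return List with `compounds` (tibble: `compound_id`, `nfs_run1`, ...,
#'   `hit_run1`, ..., `evaluable`, `hit_any`, `confirmed`) and `thresholds`
#'   (tibble: `run_id`, `threshold`, `n_wells`).
#' @export
screen_result <- function(normalized, qc, sd_multiplier = 3) {
  stopifnot(all(c("run_id", "plate_id", "role", "compound_id", "nfs") %in%
                  names(normalized)))
  passing <- qc$plate_id[qc$passed]
  test <- normalized[normalized$role == "TEST" & !is.na(normalized$compound_id), ]
  test$on_passing <- test$plate_id %in% passing

  thresholds <- test[test$on_passing, ] |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(threshold = hit_threshold(.data$nfs, sd_multiplier),
                     n_wells = dplyr::n(), .groups = "drop")

  test <- dplyr::left_join(test, thresholds, by = "run_id")
  test$hit <- test$on_passing & !is.na(test$nfs) & !is.na(test$threshold) &
    test$nfs < test$threshold

  runs <- sort(unique(test$run_id))
  per_run <- test |>
    dplyr::mutate(run_pos = match(.data$run_id, runs)) |>
    dplyr::select("compound_id", "run_pos", "nfs", "hit", "on_passing")

  wide <- per_run |>
    tidyr::pivot_wider(names_from = "run_pos",
                       values_from = c("nfs", "hit", "on_passing"),
                       names_sep = "_run")
  hit_cols <- paste0("hit_run", seq_along(runs))
  pass_cols <- paste0("on_passing_run", seq_along(runs))
  wide$evaluable <- apply(as.data.frame(wide[, pass_cols]), 1, all)
  wide$hit_any <- wide$evaluable &
    apply(as.data.frame(wide[, hit_cols]), 1, any)
  wide$confirmed <- wide$evaluable &
    apply(as.data.frame(wide[, hit_cols]), 1, all)
  wide <- dplyr::select(wide, -dplyr::all_of(pass_cols))
  list(compounds = tibble::as_tibble(wide), thresholds = thresholds)
}

#' Screen-level rates
#'
#' Primary hit rate: percent of evaluable compounds that hit in either run.
#' Adjusted hit rate: percent that hit in both runs. Percent data passed
#' QC: evaluable compounds over the library size. All rates are reported in
#' percent.
#'
#' @param n_hits_any Compounds hitting in at least one run.
#' @param n_hits_all Compounds hitting in every run.
#' @param n_evaluable Evaluable compounds (on QC-passing plates in all
#'   runs).
#' @param library_size Total screened compounds.
#' @return Tibble with `primary_hit_rate`, `adjusted_hit_rate`,
#'   `pct_data_passed_qc` (percent scale), plus the input counts.
#' @export
#' @examples
#' screen_rates(77, 36, 2258, 2298)
screen_rates <- function(n_hits_any, n_hits_all, n_evaluable, library_size) {
  if (n_evaluable <= 0) {
    stop("rates undefined: no evaluable compounds", call. = FALSE)
  }
  stopifnot(n_hits_all <= n_hits_any, n_hits_any <= n_evaluable,
            n_evaluable <= library_size)
  tibble::tibble(
    n_hits_any = n_hits_any,
    n_hits_all = n_hits_all,
    n_evaluable = n_evaluable,
    library_size = library_size,
    primary_hit_rate = 100 * n_hits_any / n_evaluable,
    adjusted_hit_rate = 100 * n_hits_all / n_evaluable,
    pct_data_passed_qc = 100 * n_evaluable / library_size
  )
}
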