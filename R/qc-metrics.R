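#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Used on the in-plate control wells to track assay robustness; the
#' screening acceptance rule requires control CV below 10%.
#'
#' @param values Numeric vector, length >= 2.
#' @return CV as a fraction.
#' @export
#' @examples
#' coefficient_of_variation(c(90, 100, 110))  # 0.1
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("CV requires at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    stop("CV undefined for zero-mean series", call. = FALSE)
  }
  stats::sd(values) / m
}

#' Signal-to-background ratio
#'
#' Ratio of the positive-control mean to the zero-control mean, computed on
#' background-subtracted signals. S:B > 4 is the conventional minimum for a
#' screening-quality assay.
#'
#' @param pos Positive-control (EC90 agonist) net signals.
#' @param zero Zero-control (DMSO) net signals.
#' @return Dimensionless ratio.
#' @export
signal_to_background <- function(pos, zero) {
  if (length(pos) == 0 || length(zero) == 0) {
    stop("both control series must be non-empty", call. = FALSE)
  }
  mz <- mean(zero)
  if (mz == 0) {
    stop("S:B undefined: zero-control mean is 0", call. = FALSE)
  }
  mean(pos) / mz
}

#' Z'-factor plate-quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_zero) / |mean_pos - mean_zero|`. Combines control
#' variability with the signal window; Z' > 0.5 denotes an excellent assay,
#' and Z' = 1 only when both controls are noiseless.
#'
#' @param pos Positive-control signals (n >= 2).
#' @param zero Zero-control signals (n >= 2).
#' @return Z' value in (-Inf, 1].
#' @export
#' @examples
#' z_prime(rep(100, 5), rep(0, 5))  # 1
z_prime <- function(pos, zero) {
  if (length(pos) < 2 || length(zero) < 2) {
    stop("Z' requires at least 2 values per control series", call. = FALSE)
  }
  sep <- abs(mean(pos) - mean(zero))
  if (sep == 0) {
    stop("Z' undefined: control means are equal (no signal separation)",
         call. = FALSE)
  }
  1 - 3 * (stats::sd(pos) + stats::sd(zero)) / sep
}

#' Row/column positional-bias diagnostics
#'
#' Screens for striping and other positional artifacts: for every plate row
#' and column with enough test wells, reports the standardized deviation of
#' its mean test-well signal from the plate grand mean,
#' `(row mean - grand mean) / grand SD`, and flags |bias| above a threshold.
#'
#' @param plate Tibble with columns `row`, `col`, `role` and the signal
#'   column named by `value`.
#' @param value Name of the signal column (default `"nfs"`).
#' @param min_wells Minimum test wells required per row/column (default 3);
#'   rows/columns below this are skipped with a warning.
#' @param flag_threshold |bias| above which a row/column is flagged
#'   (default 3).
#' @return Tibble with `axis` ("row"/"col"), `index`, `n`, `bias`,
#'   `flagged`.
#' @export
positional_bias <- function(plate, value = "nfs", min_wells = 3,
                            flag_threshold = 3) {
  stopifnot(all(c("row", "col", "role", value) %in% names(plate)))
  test <- plate[plate$role == "TEST", ]
  x <- test[[value]]
  grand_mean <- mean(x)
  grand_sd <- stats::sd(x)

  one_axis <- function(axis) {
    idx <- test[[axis]]
    counts <- table(idx)
    skipped <- names(counts)[counts < min_wells]
    if (length(skipped) > 0) {
      warning("skipping ", axis, "(s) with < ", min_wells, " test wells: ",
              paste(skipped, collapse = ", "), call. = FALSE)
    }
    keep <- as.integer(names(counts)[counts >= min_wells])
    bias <- vapply(keep, function(i) {
      if (grand_sd == 0) 0 else (mean(x[idx == i]) - grand_mean) / grand_sd
    }, numeric(1))
    tibble::tibble(axis = axis, index = keep,
                   n = as.integer(counts[counts >= min_wells]),
                   bias = bias, flagged = abs(bias) > flag_threshold)
  }
  dplyr::bind_rows(one_axis("row"), one_axis("col"))
}

#' Robust outlier removal for control wells
#'
#' Drops points further than `k` robust standard deviations
#' (1.4826 x MAD) from the median. Never removes more than 25% of the
#' series; if the rule would exceed that, only the most extreme quarter is
#' dropped. Series shorter than 4 are returned untouched with a warning.
#'
#' @param values Numeric vector.
#' @param k Deviation multiplier (default 3).
#' @return List with `retained` (values kept), `removed` (integer indices
#'   into the input that were dropped).
#' @export
#' @examples
#' remove_control_outliers(c(100, 101, 99, 100, 500))$removed  # 5
remove_control_outliers <- function(values, k = 3) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) {
    warning("fewer than 4 values: no outlier removal performed", call. = FALSE)
    return(list(retained = values, removed = integer(0)))
  }
  med <- stats::median(values)
  scale <- stats::mad(values)  # 1.4826 * MAD
  if (scale == 0) {
    # all (or half of) points identical: fall back to flagging nothing
    return(list(retained = values, removed = integer(0)))
  }
  dev <- abs(values - med) / scale
  out_idx <- which(dev > k)
  max_remove <- floor(n * 0.25)
  if (length(out_idx) > max_remove) {
    out_idx <- out_idx[order(dev[out_idx], decreasing = TRUE)][seq_len(max_remove)]
  }
  out_idx <- sort(out_idx)
  list(retained = if (length(out_idx)) values[-out_idx] else values,
       removed = out_idx)
}

#' Default QC gate thresholds
#'
#' Control CV below 10%, signal-to-background above 4, Z'-factor above 0.5;
#' all comparisons strict.
#'
#' @return Named list `cv_max`, `sb_min`, `zprime_min`.
#' @export
qc_thresholds <- function(cv_max = 0.10, sb_min = 4, zprime_min = 0.5) {
  list(cv_max = cv_max, sb_min = sb_min, zprime_min = zprime_min)
}

#' Apply the QC gate to plate metrics
#'
#' A plate passes when `cv_pos < cv_max`, `sb_ratio > sb_min` and
#' `z_prime > zprime_min` (strict inequalities).
#'
#' @param report Data frame (or single-row list) with `cv_pos`, `sb_ratio`,
#'   `z_prime`.
#' @param thresholds As from [qc_thresholds()].
#' @return Logical vector, one element per plate row.
#' @export
gate_plate <- function(report, thresholds = qc_thresholds()) {
  report$cv_pos < thresholds$cv_max &
    report$sb_ratio > thresholds$sb_min &
    report$z_prime > thresholds$zprime_min
}

#' Per-plate quality-control report
#'
#' Computes the plate QC panel from background-subtracted control signals:
#' positive- and zero-control CV (after robust outlier removal),
#' signal-to-background ratio, Z'-factor, and the pass/fail gate.
#'
#' @param plates Tibble of well records with columns `plate_id`, `role`,
#'   `net` (background-subtracted signal), plus `row`/`col` if positional
#'   diagnostics are wanted.
#' @param outlier_k Robust outlier multiplier applied to each control class
#'   (default 3).
#' @param thresholds QC gate thresholds, as [qc_thresholds()].
#' @return Tibble, one row per plate: `plate_id`, `cv_pos`, `cv_zero`,
#'   `sb_ratio`, `z_prime`, `n_outliers_removed`, `degenerate`, `passed`.
#' @export
qc_plates <- function(plates, outlier_k = 3, thresholds = qc_thresholds()) {
  stopifnot(all(c("plate_id", "role", "net") %in% names(plates)))
  plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      pos <- remove_control_outliers(df$net[df$role == "POS_CONTROL"], k = outlier_k)
      zero <- remove_control_outliers(df$net[df$role == "ZERO_CONTROL"], k = outlier_k)
      degenerate <- mean(pos$retained) == mean(zero$retained)
      tibble::tibble(
        cv_pos = coefficient_of_variation(pos$retained),
        cv_zero = coefficient_of_variation(zero$retained),
        sb_ratio = signal_to_background(pos$retained, zero$retained),
        z_prime = if (degenerate) NA_real_ else z_prime(pos$retained, zero$retained),
        n_outliers_removed = length(pos$removed) + length(zero$removed),
        degenerate = degenerate
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(passed = !.data$degenerate &
                    gate_plate(dplyr::pick(dplyr::everything()), thresholds))
}
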