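#' Specific efflux of a plate's control wells
#'
#' The channel-mediated component of tracer efflux: mean total efflux
#' (agonist only) minus mean non-specific efflux (fully blocked, or buffer
#' alone). Must be positive for the plate to be usable.
#'
#' @param total Total-efflux control counts (cpm).
#' @param nonspecific Non-specific control counts (cpm).
#' @return Specific efflux in cpm.
#' @export
specific_efflux <- function(total, nonspecific) {
  if (length(total) == 0 || length(nonspecific) == 0) {
    stop("both control series must be non-empty", call. = FALSE)
  }
  spec <- mean(total) - mean(nonspecific)
  if (spec <= 0) {
    stop("plate invalid: specific efflux is not positive", call. = FALSE)
  }
  spec
}

#' Percent inhibition of specific efflux
#'
#' Anchored to the plate controls: the no-antagonist (total) mean defines
#' 0% inhibition and the non-specific mean defines 100%. Values outside
#' [0, 100] are kept, not clipped.
#'
#' @param test Test-well counts (cpm).
#' @param total Total-efflux control counts.
#' @param nonspecific Non-specific control counts.
#' @return Percent inhibition.
#' @export
#' @examples
#' efflux_pct_inhibition(600, 1000, 200)  # 50
efflux_pct_inhibition <- function(test, total, nonspecific) {
  spec <- specific_efflux(total, nonspecific)
  100 * (mean(total) - mean(test)) / spec
}

#' Z'-factor of an efflux assay
#'
#' [z_prime()] applied to the agonist-only and non-specific efflux control
#' wells.
#'
#' @param total,nonspecific Control counts (n >= 2 each).
#' @return Z' value.
#' @export
efflux_z_prime <- function(total, nonspecific) {
  z_prime(total, nonspecific)
}

#' Validate compounds by the 3 x SD efflux rule
#'
#' A compound is validated when its mean percent inhibition of specific
#' efflux, across experiments, strictly exceeds `sd_multiplier` times the
#' spread of the no-antagonist control inhibition (which is centred on 0%
#' by construction).
#'
#' @param inhibition Per-experiment percent-inhibition values for one
#'   compound.
#' @param control_spread SD of no-antagonist control inhibition (percent).
#' @param sd_multiplier Default 3.
#' @return Tibble with `mean_pct_inhibition`, `sd_pct_inhibition`,
#'   `n_experiments`, `validated`.
#' @export
validate_compound <- function(inhibition, control_spread, sd_multiplier = 3) {
  stopifnot(length(inhibition) >= 1, control_spread >= 0)
  m <- mean(inhibition)
  tibble::tibble(
    mean_pct_inhibition = m,
    sd_pct_inhibition = if (length(inhibition) > 1) stats::sd(inhibition) else NA_real_,
    n_experiments = length(inhibition),
    validated = m > sd_multiplier * control_spread
  )
}

#' Analyze a full efflux validation experiment set
#'
#' For each experiment/plate, computes per-compound percent inhibition
#' anchored to that plate's triplicate controls; then validates each
#' compound by the 3 x SD rule, with the control spread pooled across
#' experiments (the per-well inhibition of the no-antagonist control wells
#' themselves).
#'
#' @param efflux Well-level tibble as produced by [simulate_efflux()]
#'   (columns `experiment`, `plate_id`, `role`, `compound_id`, `cpm`).
#' @param sd_multiplier SD multiplier for validation (default 3).
#' @return List with `compounds` (tibble: `compound_id`,
#'   `mean_pct_inhibition`, `sd_pct_inhibition`, `n_experiments`,
#'   `validated`), `per_experiment` (compound x experiment inhibition),
#'   `control_spread` (percent), and `z_prime` (per plate).
#' @export
efflux_validation <- function(efflux, sd_multiplier = 3) {
  stopifnot(all(c("experiment", "plate_id", "role", "compound_id", "cpm") %in%
                  names(efflux)))
  per_plate <- efflux |>
    dplyr::group_by(.data$experiment, .data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      total <- df$cpm[df$role == "TOTAL_CONTROL"]
      nonspec <- df$cpm[df$role == "NONSPECIFIC_CONTROL"]
      spec <- specific_efflux(total, nonspec)
      test <- df[df$role == "TEST", ]
      comp <- test |>
        dplyr::group_by(.data$compound_id) |>
        dplyr::summarise(
          pct_inhibition = 100 * (mean(total) - mean(.data$cpm)) / spec,
          .groups = "drop")
      # control wells pushed through the same formula give the 0% anchor
      ctrl_inh <- 100 * (mean(total) - total) / spec
      comp$zp <- z_prime(total, nonspec)
      comp$ctrl_inh <- list(ctrl_inh)
      comp
    }) |>
    dplyr::ungroup()

  control_spread <- stats::sd(unlist(
    per_plate$ctrl_inh[!duplicated(per_plate$plate_id)]))
  zp <- per_plate |>
    dplyr::distinct(.data$experiment, .data$plate_id, .data$zp)

  compounds <- per_plate |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::group_modify(function(df, key) {
      validate_compound(df$pct_inhibition, control_spread, sd_multiplier)
    }) |>
    dplyr::ungroup()

  list(compounds = compounds,
       per_experiment = per_plate[, c("experiment", "plate_id",
                                      "compound_id", "pct_inhibition")],
       control_spread = control_spread,
       z_prime = zp[, c("experiment", "plate_id", "zp")])
}

#' Validation rate
#'
#' Percent of resupplied primary hits confirmed by the orthogonal efflux
#' assay.
#'
#' @param validated Number of validated compounds.
#' @param resupplied Number of compounds resupplied and tested.
#' @return Percentage.
#' @export
#' @examples
#' validation_rate(34, 35)  # 97.142857...
validation_rate <- function(validated, resupplied) {
  if (resupplied <= 0) {
    stop("validation rate undefined: no resupplied compounds", call. = FALSE)
  }
  stopifnot(validated >= 0, validated <= resupplied)
  100 * validated / resupplied
}
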