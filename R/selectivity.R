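#' Selectivity group labels
#'
#' The six named groups plus the two mixed patterns
#' (alpha3beta4 together with exactly one beta2 subtype) needed to make the
#' classifier total over all eight flag combinations.
#'
#' @format Character vector of group labels.
#' @export
selectivity_groups <- c("A3B4_ONLY", "A4B2_ONLY", "A6_ONLY", "BOTH_B2",
                        "ALL_THREE", "NOT_VALIDATED",
                        "A3B4_AND_A4B2", "A3B4_AND_A6")

#' Classify a compound's validated-activity pattern
#'
#' Maps the three per-subtype validation flags (alpha3beta4, alpha4beta2,
#' alpha6/3beta2beta3) to a selectivity group:
#' (T,F,F) A3B4_ONLY; (F,T,F) A4B2_ONLY; (F,F,T) A6_ONLY; (F,T,T) BOTH_B2;
#' (T,T,T) ALL_THREE; (F,F,F) NOT_VALIDATED; the remaining mixed patterns
#' get explicit labels A3B4_AND_A4B2 / A3B4_AND_A6 so every combination is
#' covered.
#'
#' @param a3b4,a4b2,a6 Logical vectors of validation flags (no `NA`).
#' @return Character vector of group labels.
#' @export
#' @examples
#' classify_compound(TRUE, FALSE, FALSE)  # "A3B4_ONLY"
classify_compound <- function(a3b4, a4b2, a6) {
  if (any(is.na(a3b4)) || any(is.na(a4b2)) || any(is.na(a6))) {
    stop("validation flags must not be NA", call. = FALSE)
  }
  dplyr::case_when(
    a3b4 & !a4b2 & !a6 ~ "A3B4_ONLY",
    !a3b4 & a4b2 & !a6 ~ "A4B2_ONLY",
    !a3b4 & !a4b2 & a6 ~ "A6_ONLY",
    !a3b4 & a4b2 & a6 ~ "BOTH_B2",
    a3b4 & a4b2 & a6 ~ "ALL_THREE",
    a3b4 & a4b2 & !a6 ~ "A3B4_AND_A4B2",
    a3b4 & !a4b2 & a6 ~ "A3B4_AND_A6",
    TRUE ~ "NOT_VALIDATED"
  )
}

#' Build selectivity profiles from per-subtype validation results
#'
#' Joins the three subtypes' validation tables into one profile per
#' compound, with per-subtype validated flags and percent inhibition, and
#' the selectivity group label.
#'
#' @param a3b4,a4b2,a6 Validation tibbles (as `compounds` from
#'   [efflux_validation()]): columns `compound_id`, `validated`,
#'   `mean_pct_inhibition`.
#' @return Tibble with `compound_id`, `validated_a3b4`, `validated_a4b2`,
#'   `validated_a6`, `inh_a3b4`, `inh_a4b2`, `inh_a6`, `group`.
#' @export
selectivity_profiles <- function(a3b4, a4b2, a6) {
  pick <- function(df, suffix) {
    stopifnot(all(c("compound_id", "validated", "mean_pct_inhibition") %in%
                    names(df)))
    out <- df[, c("compound_id", "validated", "mean_pct_inhibition")]
    names(out) <- c("compound_id", paste0("validated_", suffix),
                    paste0("inh_", suffix))
    out
  }
  prof <- pick(a3b4, "a3b4") |>
    dplyr::full_join(pick(a4b2, "a4b2"), by = "compound_id") |>
    dplyr::full_join(pick(a6, "a6"), by = "compound_id")
  # a compound untested at a subtype cannot be validated there
  prof <- tidyr::replace_na(prof, list(validated_a3b4 = FALSE,
                                       validated_a4b2 = FALSE,
                                       validated_a6 = FALSE))
  prof$group <- classify_compound(prof$validated_a3b4, prof$validated_a4b2,
                                  prof$validated_a6)
  prof
}

#' Group and overlap counts of a profile set
#'
#' Per-group counts plus the per-subtype totals and pairwise/triple
#' overlaps of validated hits (the numbers a three-set Venn diagram
#' displays). Group counts always sum to the number of profiles.
#'
#' @param profiles Tibble from [selectivity_profiles()].
#' @return List with `groups` (tibble `group`, `n`, zero rows included)
#'   and `overlaps` (tibble of Venn region/total counts).
#' @export
venn_counts <- function(profiles) {
  groups <- tibble::tibble(group = selectivity_groups) |>
    dplyr::left_join(dplyr::count(profiles, .data$group), by = "group") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  v3 <- profiles$validated_a3b4
  v4 <- profiles$validated_a4b2
  v6 <- profiles$validated_a6
  overlaps <- tibble::tibble(
    region = c("A3B4_total", "A4B2_total", "A6_total",
               "A3B4_and_A4B2", "A3B4_and_A6", "A4B2_and_A6", "all_three"),
    n = c(sum(v3), sum(v4), sum(v6),
          sum(v3 & v4), sum(v3 & v6), sum(v4 & v6), sum(v3 & v4 & v6))
  )
  list(groups = groups, overlaps = overlaps)
}

#' Per-group efficacy summary
#'
#' For each selectivity group, counts compounds whose inhibition at their
#' validated subtype(s) exceeds 75% (strictly) or is at most 50%, plus the
#' median inhibition. A compound's efficacy is its maximum mean inhibition
#' across the subtypes where it validated (its inhibition overall for
#' NOT_VALIDATED compounds).
#'
#' @param profiles Tibble from [selectivity_profiles()].
#' @return Tibble with `group`, `n`, `n_above_75`, `n_at_most_50`,
#'   `median_inhibition`.
#' @export
efficacy_summary <- function(profiles) {
  inh_mat <- cbind(profiles$inh_a3b4, profiles$inh_a4b2, profiles$inh_a6)
  val_mat <- cbind(profiles$validated_a3b4, profiles$validated_a4b2,
                   profiles$validated_a6)
  eff <- vapply(seq_len(nrow(profiles)), function(i) {
    v <- val_mat[i, ]
    x <- inh_mat[i, if (any(v)) v else rep(TRUE, 3)]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else max(x)
  }, numeric(1))
  tibble::tibble(group = profiles$group, efficacy = eff) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_above_75 = sum(.data$efficacy > 75, na.rm = TRUE),
      n_at_most_50 = sum(.data$efficacy <= 50, na.rm = TRUE),
      median_inhibition = stats::median(.data$efficacy, na.rm = TRUE),
      .groups = "drop")
}
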