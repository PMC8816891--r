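#' Assay context for a receptor subtype
#'
#' Per-subtype constants for the membrane-potential screen: the EC90 agonist
#' concentration used to anchor antagonist detection (20 uM nicotine for
#' alpha3beta4; 500 nM for alpha4beta2 and alpha6/3beta2beta3, whose
#' nicotine concentration-response ranges are similar), and the fluorescence
#' floor (DMSO level) and ceiling (EC90 level) in arbitrary units. Ceilings
#' default to values whose floor ratio matches the signal-to-background
#' each assay achieves.
#'
#' @param subtype One of `"A3B4"`, `"A4B2"`, `"A6B2B3"`.
#' @param signal_floor,signal_ceiling Optional overrides (AU).
#' @return List with `subtype`, `ec90_agonist_conc`, `signal_floor`,
#'   `signal_ceiling`.
#' @export
assay_context <- function(subtype = nachr_subtypes,
                          signal_floor = NULL, signal_ceiling = NULL) {
  subtype <- match.arg(subtype)
  defaults <- list(
    A3B4   = list(ec90 = 20e-6,  floor = 100, ceiling = 14885),
    A4B2   = list(ec90 = 500e-9, floor = 100, ceiling = 6246),
    A6B2B3 = list(ec90 = 500e-9, floor = 100, ceiling = 6484)
  )[[subtype]]
  floor_ <- signal_floor %||% defaults$floor
  ceiling_ <- signal_ceiling %||% defaults$ceiling
  stopifnot(ceiling_ > floor_, floor_ > 0)
  list(subtype = subtype, ec90_agonist_conc = defaults$ec90,
       signal_floor = floor_, signal_ceiling = ceiling_)
}

#' Noise model for the synthetic screen
#'
#' Well noise is multiplicative Gaussian with coefficient of variation
#' `well_cv`; plates drift by a log-normal multiplicative factor with log-sd
#' `plate_scale_sd`; the baseline read is an independent draw around
#' `baseline_frac` of the signal floor; border wells are distorted by a
#' multiplicative `1 + edge_bias` when `edge_bias` is non-zero.
#'
#' @param well_cv Control-well CV target (default 0.05, inside the
#'   0.025-0.095 band the assays realize).
#' @param plate_scale_sd Plate-to-plate log-normal drift (default 0.05).
#' @param baseline_frac Baseline read level as a fraction of the floor
#'   (default 0.1).
#' @param edge_bias Multiplicative edge distortion (default 0 = off).
#' @param seed Integer seed.
#' @return Named list of the parameters.
#' @export
noise_model <- function(well_cv = 0.05, plate_scale_sd = 0.05,
                        baseline_frac = 0.1, edge_bias = 0, seed = 1L) {
  stopifnot(well_cv >= 0, is.finite(plate_scale_sd), is.finite(edge_bias),
            baseline_frac >= 0)
  list(well_cv = well_cv, plate_scale_sd = plate_scale_sd,
       baseline_frac = baseline_frac, edge_bias = edge_bias,
       seed = as.integer(seed))
}

#' Fractional inhibition of a compound at its screening concentration
#'
#' Four-parameter logistic inhibition with an efficacy ceiling:
#' `I = efficacy / (1 + (ic50 / conc)^hill)`; 0 for non-antagonists.
#'
#' @param ic50 IC50 in molar (`NA` for inactive compounds).
#' @param hill Hill slope (> 0).
#' @param efficacy Maximum achievable fractional inhibition in \[0, 1\].
#' @param conc Screening concentration in molar (default 10 uM).
#' @return Fractional inhibition in \[0, 1\].
#' @export
planted_inhibition <- function(ic50, hill = 1, efficacy = 1, conc = 1e-5) {
  n <- max(length(ic50), length(hill), length(efficacy), length(conc))
  ic50 <- rep_len(ic50, n)
  hill <- rep_len(hill, n)
  efficacy <- rep_len(efficacy, n)
  conc <- rep_len(conc, n)
  out <- efficacy / (1 + (ic50 / conc)^hill)
  out[is.na(ic50)] <- 0
  out
}

#' Plant ground-truth antagonist profiles in a compound library
#'
#' Assigns a selectivity group to each library compound and derives the
#' per-subtype truth table the generator consumes. Default group sizes
#' mirror the selectivity structure the screen is designed to resolve:
#' alpha3beta4-selective (26, of which 24 high-efficacy and 2 low),
#' alpha4beta2-only (6), alpha6/3beta2beta3-only (5), both-beta2 (20),
#' all-three (10), and fluorescence artifacts (15) that depress the dye
#' signal at every subtype but have no effect on channel-mediated ion flux
#' (so they fail orthogonal validation). Everything else is inactive.
#'
#' @param manifest Compound manifest ([build_manifest()]).
#' @param group_sizes Named integer vector with entries `A3B4_ONLY`,
#'   `A4B2_ONLY`, `A6_ONLY`, `BOTH_B2`, `ALL_THREE`, `ARTIFACT`.
#' @param high_efficacy,low_efficacy Fractional inhibition ceilings for the
#'   high- (> 0.75) and low- (<= 0.5) efficacy classes (defaults 0.90 and
#'   0.45).
#' @param ic50 Planted IC50 in molar for active subtype pairs
#'   (default 1 uM, well below the 10 uM screening concentration).
#' @param hill Planted Hill slope (default 1).
#' @param seed Integer seed controlling which compounds are chosen.
#' @return List with `truth` (tibble: `compound_id`, `subtype`,
#'   `is_antagonist`, `is_artifact`, `ic50_M`, `hill`, `efficacy`,
#'   `true_inhibition`, `fluor_inhibition`, `group`) and `groups` (tibble:
#'   `compound_id`, `group`).
#' @export
simulate_truth <- function(manifest,
                           group_sizes = c(A3B4_ONLY = 26, A4B2_ONLY = 6,
                                           A6_ONLY = 5, BOTH_B2 = 20,
                                           ALL_THREE = 10, ARTIFACT = 15),
                           high_efficacy = 0.90, low_efficacy = 0.45,
                           ic50 = 1e-6, hill = 1, seed = 1L) {
  required <- c("A3B4_ONLY", "A4B2_ONLY", "A6_ONLY", "BOTH_B2",
                "ALL_THREE", "ARTIFACT")
  stopifnot(all(required %in% names(group_sizes)))
  n_active <- sum(group_sizes)
  ids <- manifest$compound_id
  if (n_active > length(ids)) {
    stop("more planted actives than library compounds", call. = FALSE)
  }
  set.seed(seed)
  chosen <- sample(ids, n_active)
  group <- rep("INACTIVE", length(ids))
  names(group) <- ids
  group[chosen] <- rep(required, group_sizes[required])

  # channel-level activity per subtype by group
  active_at <- list(
    A3B4_ONLY = "A3B4", A4B2_ONLY = "A4B2", A6_ONLY = "A6B2B3",
    BOTH_B2 = c("A4B2", "A6B2B3"),
    ALL_THREE = c("A3B4", "A4B2", "A6B2B3"),
    ARTIFACT = character(0), INACTIVE = character(0)
  )
  # 24 of 26 alpha3beta4-selective compounds are high-efficacy, 2 low;
  # beta2-group antagonists are low-efficacy; all-three are high.
  a3b4_ids <- names(group)[group == "A3B4_ONLY"]
  n_low_a3b4 <- min(2L, length(a3b4_ids))
  low_a3b4 <- if (n_low_a3b4 > 0) sample(a3b4_ids, n_low_a3b4) else character(0)
  efficacy_of <- function(id, grp) {
    if (grp %in% c("A4B2_ONLY", "A6_ONLY", "BOTH_B2")) return(low_efficacy)
    if (grp == "A3B4_ONLY" && id %in% low_a3b4) return(low_efficacy)
    high_efficacy
  }

  truth <- tidyr::expand_grid(compound_id = ids, subtype = nachr_subtypes)
  truth$group <- group[truth$compound_id]
  truth$is_antagonist <- purrr::map2_lgl(
    truth$group, truth$subtype, function(g, s) s %in% active_at[[g]])
  truth$is_artifact <- truth$group == "ARTIFACT"
  truth$ic50_M <- ifelse(truth$is_antagonist | truth$is_artifact, ic50, NA_real_)
  truth$hill <- hill
  truth$efficacy <- purrr::map2_dbl(
    truth$compound_id, truth$group,
    function(id, g) if (g %in% c("INACTIVE")) 0 else efficacy_of(id, g))
  # channel-mediated inhibition (drives efflux); artifacts have none
  truth$true_inhibition <- ifelse(
    truth$is_antagonist,
    planted_inhibition(truth$ic50_M, truth$hill, truth$efficacy), 0)
  # fluorescence-read inhibition (drives the primary screen)
  truth$fluor_inhibition <- ifelse(
    truth$is_antagonist | truth$is_artifact,
    planted_inhibition(truth$ic50_M, truth$hill, truth$efficacy), 0)

  list(truth = tibble::as_tibble(truth),
       groups = tibble::tibble(compound_id = ids, group = unname(group)))
}

# mecamylamine-like parameters for the in-plate antagonist titration
antag_control_params <- function(subtype) {
  ic50 <- c(A3B4 = 1.91e-6, A4B2 = 0.54e-6, A6B2B3 = 1.67e-6)[[subtype]]
  list(ic50 = ic50, hill = 1, efficacy = 1)
}

#' Simulate a complete duplicate-run membrane-potential screen
#'
#' Generates per-well baseline and final fluorescence reads for every plate
#' of every run at one receptor subtype, under the default edge-excluded
#' layout. The expected final read of a test well is
#' `baseline + floor + (ceiling - floor) * (1 - I)`, where `I` is the
#' compound's planted fluorescence inhibition at the 10 uM screening
#' concentration; zero controls sit at the floor, positive controls at the
#' ceiling, and the antagonist-control titration follows a reference
#' 4PL inhibition curve across its 12-point series. Multiplicative
#' log-normal plate drift, per-well Gaussian noise at `well_cv`, an
#' independent baseline draw, and (optionally) edge bias are applied.
#'
#' @param manifest Compound manifest.
#' @param truth Truth list from [simulate_truth()].
#' @param ctx Assay context ([assay_context()]).
#' @param noise Noise model ([noise_model()]); its `seed` drives all draws.
#' @param n_runs Number of replicate runs (default 2).
#' @param layout Plate layout (default [default_layout()]).
#' @return List with `reads` (well-level tibble: `plate_id`, `run_id`,
#'   `subtype`, `plate_index`, `well`, `row`, `col`, `role`,
#'   `compound_id`, `conc_M`, `baseline`, `final`), `layout`, and
#'   `ground_truth` (per-compound per-subtype truth).
#' @export
simulate_screen <- function(manifest, truth, ctx, noise = noise_model(),
                            n_runs = 2, layout = default_layout()) {
  stopifnot(n_runs >= 1)
  missing_ids <- setdiff(manifest$compound_id, unique(truth$truth$compound_id))
  if (length(missing_ids) > 0) {
    stop("truth table missing compound(s): ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  plated <- assign_compounds(manifest, layout)
  sub_truth <- truth$truth[truth$truth$subtype == ctx$subtype, ]
  fluor_i <- sub_truth$fluor_inhibition[match(plated$compound_id,
                                              sub_truth$compound_id)]
  ap <- antag_control_params(ctx$subtype)

  span <- ctx$signal_ceiling - ctx$signal_floor
  expected_i <- dplyr::case_when(
    plated$role == "TEST" ~ fluor_i,
    plated$role == "ZERO_CONTROL" ~ 1,                      # no agonist signal
    plated$role == "POS_CONTROL" ~ 0,
    plated$role == "ANTAG_CONTROL" ~
      planted_inhibition(ap$ic50, ap$hill, ap$efficacy, conc = plated$conc_M),
    TRUE ~ 1                                                # edge/empty wells sit at the floor
  )
  expected_signal <- ctx$signal_floor + span * (1 - expected_i)
  baseline_level <- noise$baseline_frac * ctx$signal_floor

  set.seed(noise$seed)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    df <- plated
    df$run_id <- sprintf("run%d", r)
    df$subtype <- ctx$subtype
    df$plate_id <- sprintf("%s_run%d_p%02d", ctx$subtype, r, df$plate_index)
    n <- nrow(df)
    plate_scale <- exp(stats::rnorm(max(df$plate_index), 0, noise$plate_scale_sd))
    scale <- plate_scale[df$plate_index]
    sig <- expected_signal * scale * (1 + stats::rnorm(n, 0, noise$well_cv))
    base_true <- baseline_level * scale *
      (1 + stats::rnorm(n, 0, noise$well_cv))
    if (noise$edge_bias != 0) {
      on_edge <- df$role == "EDGE_EXCLUDED"
      sig[on_edge] <- sig[on_edge] * (1 + noise$edge_bias)
    }
    df$final <- pmax(base_true + sig, 0)
    # independent re-read of the baseline level
    df$baseline <- pmax(baseline_level * scale *
                          (1 + stats::rnorm(n, 0, noise$well_cv)), 0)
    df
  })
  reads <- dplyr::bind_rows(runs)
  cols <- c("plate_id", "run_id", "subtype", "plate_index", "well", "row",
            "col", "role", "compound_id", "conc_M", "baseline", "final")
  list(reads = tibble::as_tibble(reads[, cols]), layout = layout,
       ground_truth = sub_truth)
}

#' Simulate concentration-response data around a 4PL curve
#'
#' @param bottom,top,ec50,hill Generating 4PL parameters (`ec50` in molar).
#' @param conc Concentration grid in molar (strictly positive).
#' @param reps Replicates per concentration (default 4).
#' @param cv Multiplicative noise CV (0 gives points exactly on the curve).
#' @param seed Integer seed.
#' @param direction `"AGONIST"` (rising with concentration) or
#'   `"ANTAGONIST"` (falling).
#' @return Tibble with `conc_M`, `replicate`, `response`.
#' @export
#' @examples
#' conc <- dilution_series(100e-6, 3, 12)
#' simulate_dose_response(0, 100, 1e-7, 1, conc, reps = 4, cv = 0.05)
simulate_dose_response <- function(bottom, top, ec50, hill, conc,
                                   reps = 4, cv = 0.05, seed = 1L,
                                   direction = c("AGONIST", "ANTAGONIST")) {
  direction <- match.arg(direction)
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  stopifnot(reps >= 1, cv >= 0, ec50 > 0, hill > 0)
  frac <- 1 / (1 + (ec50 / conc)^hill)        # rising occupancy
  if (direction == "ANTAGONIST") frac <- 1 - frac
  mu <- bottom + (top - bottom) * frac
  set.seed(seed)
  out <- tidyr::expand_grid(conc_M = conc, replicate = seq_len(reps))
  mu_all <- rep(mu, each = reps)
  out$response <- mu_all * (1 + stats::rnorm(nrow(out), 0, cv))
  if (cv == 0) out$response <- mu_all
  tibble::as_tibble(out)
}

#' Serial dilution series
#'
#' @param top Highest concentration (molar).
#' @param fold Fold-dilution per step (default 3).
#' @param n Number of points (default 12).
#' @return Numeric vector, descending. A 12-point 1:3 series from 100 uM
#'   ends at about 0.56 nM.
#' @export
dilution_series <- function(top, fold = 3, n = 12) {
  stopifnot(top > 0, fold > 1, n >= 1)
  top / fold^(seq_len(n) - 1)
}

#' Simulate orthogonal rubidium-efflux experiments
#'
#' Emulates the 24-well-plate efflux design: per experiment each compound
#' is measured in triplicate alongside triplicate total-efflux controls
#' (agonist only) and triplicate non-specific controls. Expected test-well
#' counts are `nonspecific + specific * (1 - I)`, where `I` is the
#' compound's channel-level (not fluorescence) inhibition — so planted
#' fluorescence artifacts show no efflux block.
#'
#' @param compound_ids Compounds to test.
#' @param truth Truth list from [simulate_truth()].
#' @param subtype Receptor subtype assayed.
#' @param noise Noise model; `well_cv` is applied multiplicatively to
#'   counts and `seed` offsets are derived per subtype/experiment.
#' @param n_experiments Independent experiments per compound (default 3).
#' @param total_cpm,nonspecific_cpm Expected control count levels
#'   (defaults 1000 and 200 cpm).
#' @return Tibble with `experiment`, `plate_id`, `well_set`, `role`,
#'   `compound_id`, `cpm` (one row per well).
#' @export
simulate_efflux <- function(compound_ids, truth, subtype,
                            noise = noise_model(), n_experiments = 3,
                            total_cpm = 1000, nonspecific_cpm = 200) {
  sub_truth <- truth$truth[truth$truth$subtype == subtype, ]
  i_chan <- sub_truth$true_inhibition[match(compound_ids,
                                            sub_truth$compound_id)]
  if (any(is.na(i_chan))) {
    stop("truth table missing compound(s) for subtype ", subtype, call. = FALSE)
  }
  specific <- total_cpm - nonspecific_cpm
  stopifnot(specific > 0)
  set.seed(noise$seed + match(subtype, nachr_subtypes))
  out <- purrr::map(seq_len(n_experiments), function(ex) {
    # 24-well plates: 6 compounds per plate + two triplicate control sets
    n_per_plate <- 6L
    plate_of <- (seq_along(compound_ids) - 1L) %/% n_per_plate + 1L
    test <- tibble::tibble(
      experiment = ex,
      plate_id = rep(sprintf("%s_efflux_e%d_p%02d", subtype, ex, plate_of),
                     each = 3),
      role = "TEST",
      compound_id = rep(compound_ids, each = 3),
      mu = rep(nonspecific_cpm + specific * (1 - i_chan), each = 3)
    )
    ctrl <- tidyr::expand_grid(
      plate_id = unique(test$plate_id),
      role = c("TOTAL_CONTROL", "NONSPECIFIC_CONTROL"),
      rep = 1:3
    )
    ctrl$experiment <- ex
    ctrl$compound_id <- NA_character_
    ctrl$mu <- ifelse(ctrl$role == "TOTAL_CONTROL", total_cpm, nonspecific_cpm)
    ctrl$rep <- NULL
    dplyr::bind_rows(test, ctrl)
  }) |>
    dplyr::bind_rows()
  out$cpm <- pmax(out$mu * (1 + stats::rnorm(nrow(out), 0, noise$well_cv)), 0)
  out$mu <- NULL
  out$well_set <- paste0(out$plate_id, ":", dplyr::coalesce(out$compound_id, out$role))
  tibble::as_tibble(out[, c("experiment", "plate_id", "well_set", "role",
                            "compound_id", "cpm")])
}
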