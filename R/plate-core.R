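#' Well roles used on screening plates
#'
#' Role vocabulary for 384-well screening layouts: `TEST` wells receive a
#' library compound premixed with EC90 agonist; `ZERO_CONTROL` wells receive
#' DMSO only (zero-signal anchor); `POS_CONTROL` wells receive EC90 agonist
#' only (full-signal anchor); `ANTAG_CONTROL` wells carry the in-plate
#' reference-antagonist titration; `EDGE_EXCLUDED` wells lie within two rows
#' or two columns of the plate edge and are never used; `EMPTY` wells carry
#' nothing.
#'
#' @format Character vector of the six role labels.
#' @export
well_roles <- c("TEST", "ZERO_CONTROL", "POS_CONTROL", "ANTAG_CONTROL",
                "EDGE_EXCLUDED", "EMPTY")

#' nAChR subtype labels used throughout the package
#' @format Character vector: alpha3beta4, alpha4beta2, alpha6/3beta2beta3.
#' @export
nachr_subtypes <- c("A3B4", "A4B2", "A6B2B3")

# Row letters for a 16 x 24 plate (A..P).
plate_row_letters <- LETTERS[1:16]

#' Build well identifiers from row/column indices
#'
#' Wells are addressed in plate-reader convention: row letter (A-P) followed
#' by 1-based column number (1-24), e.g. `"A1"`, `"P24"`.
#'
#' @param row Integer row indices (1-16).
#' @param col Integer column indices (1-24).
#' @return Character vector of well identifiers.
#' @export
#' @examples
#' well_id(1, 1)    # "A1"
#' well_id(16, 24)  # "P24"
well_id <- function(row, col) {
  stopifnot(all(row >= 1L), all(row <= 16L), all(col >= 1L), all(col <= 24L))
  paste0(plate_row_letters[row], col)
}

#' Parse well identifiers into row/column indices
#'
#' @param well Character vector of well identifiers (`"A1"`-`"P24"`).
#' @return A tibble with columns `well`, `row`, `col`.
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well identifier(s): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- match(vapply(m, `[`, character(1), 2L), plate_row_letters)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(col < 1L | col > 24L)) {
    stop("well column out of range 1-24", call. = FALSE)
  }
  tibble::tibble(well = well, row = row, col = col)
}

#' Default 384-well screening layout
#'
#' Constructs the plate template used for antagonist screening: all wells
#' within 2 rows or 2 columns of the plate edge are `EDGE_EXCLUDED` (144
#' wells, leaving a 12 x 20 interior of 240 wells); fixed interior columns
#' hold the controls (column 3: zero-signal DMSO; column 4: positive-signal
#' EC90 agonist; column 5: reference-antagonist titration, one concentration
#' per row from `titration_top` falling `dilution`-fold per step); every
#' remaining interior well is `TEST`.
#'
#' @param n_controls Number of replicate wells for each of the zero and
#'   positive controls (default 12, one per interior row).
#' @param titration_points Number of points in the in-plate antagonist
#'   titration (default 12; 3-fold steps from 100 uM reach 0.56 nM).
#' @param titration_top Highest antagonist concentration in molar
#'   (default 1e-4).
#' @param dilution Fold-dilution between successive titration points
#'   (default 3).
#' @return A tibble with one row per well: `well`, `row`, `col`, `role`,
#'   `conc_M` (antagonist-control concentration, `NA` elsewhere).
#' @export
#' @examples
#' lay <- default_layout()
#' table(lay$role)
default_layout <- function(n_controls = 12, titration_points = 12,
                           titration_top = 1e-4, dilution = 3) {
  interior_capacity <- 12L * 20L
  if (2L * n_controls + titration_points > interior_capacity) {
    stop("requested control wells (", 2L * n_controls + titration_points,
         ") exceed the 240-well plate interior", call. = FALSE)
  }
  grid <- tidyr::expand_grid(row = 1:16, col = 1:24)
  grid$well <- well_id(grid$row, grid$col)
  is_edge <- grid$row <= 2L | grid$row >= 15L | grid$col <= 2L | grid$col >= 23L

  # interior wells in column-major order so controls fill whole columns
  interior <- grid[!is_edge, ]
  interior <- interior[order(interior$col, interior$row), ]

  role <- rep("TEST", nrow(interior))
  role[seq_len(n_controls)] <- "ZERO_CONTROL"
  role[n_controls + seq_len(n_controls)] <- "POS_CONTROL"
  role[2L * n_controls + seq_len(titration_points)] <- "ANTAG_CONTROL"
  interior$role <- role

  conc <- rep(NA_real_, nrow(interior))
  conc[interior$role == "ANTAG_CONTROL"] <-
    titration_top / dilution^(seq_len(titration_points) - 1)
  interior$conc_M <- conc

  edge <- grid[is_edge, ]
  edge$role <- "EDGE_EXCLUDED"
  edge$conc_M <- NA_real_

  out <- dplyr::bind_rows(interior, edge)
  out <- out[order(out$row, out$col), c("well", "row", "col", "role", "conc_M")]
  tibble::as_tibble(out)
}

#' Assign library compounds to test wells across plates
#'
#' Distributes a compound manifest over as many copies of the layout as
#' needed, filling `TEST` wells in row-major order. Unfilled test wells on
#' the last plate are marked `EMPTY`.
#'
#' @param manifest A compound manifest, as from [build_manifest()].
#' @param layout A plate layout tibble, as from [default_layout()].
#' @return A tibble of plated wells with columns `plate_index`, `well`,
#'   `row`, `col`, `role`, `compound_id`, `conc_M`.
#' @export
assign_compounds <- function(manifest, layout) {
  stopifnot(is.data.frame(manifest), "compound_id" %in% names(manifest))
  if (anyDuplicated(manifest$compound_id)) {
    stop("compound_ids in manifest must be unique", call. = FALSE)
  }
  n_test <- sum(layout$role == "TEST")
  n_plates <- ceiling(nrow(manifest) / n_test)
  plates <- purrr::map(seq_len(n_plates), function(p) {
    lay <- layout
    lay$plate_index <- p
    test_idx <- which(lay$role == "TEST")
    ids <- manifest$compound_id[(p - 1L) * n_test + seq_len(n_test)]
    lay$compound_id <- NA_character_
    lay$compound_id[test_idx] <- ids
    lay$role[test_idx][is.na(ids)] <- "EMPTY"
    assay_conc <- if ("assay_conc" %in% names(manifest)) {
      manifest$assay_conc[match(lay$compound_id, manifest$compound_id)]
    } else {
      ifelse(is.na(lay$compound_id), NA_real_, 1e-5)
    }
    lay$conc_M <- dplyr::coalesce(lay$conc_M, assay_conc)
    lay
  })
  out <- dplyr::bind_rows(plates)
  out[, c("plate_index", "well", "row", "col", "role", "compound_id", "conc_M")]
}

#' Build a compound manifest
#'
#' @param n Number of library compounds.
#' @param assay_conc Final screening concentration in molar (default 10 uM).
#' @param prefix Identifier prefix.
#' @return Tibble with `compound_id`, `source_well`, `stock_conc`,
#'   `assay_conc`.
#' @export
build_manifest <- function(n, assay_conc = 1e-5, prefix = "CMPD") {
  stopifnot(n >= 1, assay_conc > 0)
  tibble::tibble(
    compound_id = sprintf("%s-%05d", prefix, seq_len(n)),
    source_well = well_id((seq_len(n) - 1L) %% 16L + 1L,
                          (seq_len(n) - 1L) %/% 16L %% 24L + 1L),
    stock_conc = 1e-2,
    assay_conc = assay_conc
  )
}

#' Read a raw plate file (well, baseline, final)
#'
#' @param path Path to a CSV with columns `well`, `baseline`, `final`.
#' @param plate_id,run_id,subtype Optional identifiers attached to the
#'   returned tibble; defaults taken from columns of the same name if
#'   present in the file.
#' @return Tibble with columns `plate_id`, `run_id`, `subtype`, `well`,
#'   `row`, `col`, `baseline`, `final`.
#' @export
read_plate_csv <- function(path, plate_id = NULL, run_id = NULL, subtype = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("well", "baseline", "final")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("plate file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$well)) {
    stop("plate file ", path, " contains duplicate well(s): ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$baseline)) || any(!is.finite(df$final))) {
    stop("non-finite fluorescence values in ", path, call. = FALSE)
  }
  if (any(df$baseline < 0) || any(df$final < 0)) {
    stop("negative fluorescence values in ", path, call. = FALSE)
  }
  rc <- parse_well(df$well)
  out <- tibble::tibble(
    plate_id = plate_id %||% (if ("plate_id" %in% names(df)) as.character(df$plate_id) else NA_character_),
    run_id   = run_id   %||% (if ("run_id" %in% names(df)) as.character(df$run_id) else NA_character_),
    subtype  = subtype  %||% (if ("subtype" %in% names(df)) as.character(df$subtype) else NA_character_),
    well = df$well, row = rc$row, col = rc$col,
    baseline = as.numeric(df$baseline), final = as.numeric(df$final)
  )
  out
}

#' Write a raw plate read to CSV
#'
#' Inverse of [read_plate_csv()]; values round-trip bit-exactly (full
#' double precision is preserved).
#'
#' @param reads Tibble with at least `well`, `baseline`, `final`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(reads, path) {
  keep <- intersect(c("plate_id", "run_id", "subtype", "well", "baseline", "final"),
                    names(reads))
  df <- reads[, keep]
  # readr writes doubles at full precision, so read_plate_csv round-trips
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
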