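# Per-gene log2 fold-change profiles over the condition x timepoint grid,
# response classification, and differential-expression filtering.

#' The default condition-by-timepoint profile grid
#'
#' Profiles are ordered vectors of log2 fold changes over stress conditions
#' and sampling times, treatment versus the same-timepoint control. The
#' default grid is LT and HT at 48, 96 and 168 h (`"LT_48"`, `"LT_96"`,
#' `"LT_168"`, `"HT_48"`, `"HT_96"`, `"HT_168"`). The 0 h point is excluded
#' by construction: log2fc is identically 0 there and would anchor every
#' correlation.
#'
#' @param conditions Character vector of stress conditions.
#' @param timepoints Numeric vector of timepoints (hours).
#' @return Character vector of grid labels, condition-major.
#' @export
profile_grid <- function(conditions = c("LT", "HT"),
                         timepoints = c(48, 96, 168)) {
  as.vector(vapply(conditions,
                   function(cc) paste0(cc, "_", timepoints),
                   character(length(timepoints))))
}

#' Assemble per-gene expression profiles
#'
#' Pivots long expression records (one row per gene, condition, timepoint
#' with a `log2fc`) onto a fixed grid. Genes with a value for every grid
#' point are flagged `complete`; incomplete genes are retained in the output
#' but excluded from network analysis by default (see
#' [build_network()]).
#'
#' @param records Tibble with columns `gene`, `condition`, `timepoint`,
#'   `log2fc` (e.g. from [ddct_log2fc()]).
#' @param grid Grid labels from [profile_grid()].
#' @return Tibble with `gene`, one column per grid point, and `complete`.
#' @export
build_profiles <- function(records, grid = profile_grid()) {
  need <- c("gene", "condition", "timepoint", "log2fc")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort_lipid(paste0("Expression records lack columns: ",
                       paste(missing_cols, collapse = ", ")),
                "lipidnet_input_error")
  }
  records <- records |>
    dplyr::mutate(point = paste0(.data$condition, "_", .data$timepoint))
  dup <- records |>
    dplyr::count(.data$gene, .data$point) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_lipid(
      paste0("Duplicate (condition, timepoint) record for gene '",
             dup$gene[1], "' at ", dup$point[1]),
      "lipidnet_ambiguous_record"
    )
  }
  off_grid <- setdiff(unique(records$point), grid)
  if (length(off_grid) > 0) {
    rlang::warn(paste0("Dropping records outside the profile grid: ",
                       paste(off_grid, collapse = ", ")))
    records <- records |> dplyr::filter(.data$point %in% grid)
  }
  wide <- records |>
    dplyr::select("gene", "point", "log2fc") |>
    tidyr::pivot_wider(names_from = "point", values_from = "log2fc")
  for (g in setdiff(grid, names(wide))) wide[[g]] <- NA_real_
  wide <- wide[, c("gene", grid)]
  wide$complete <- stats::complete.cases(wide[, grid])
  wide
}

#' Profile matrix from a profile table
#'
#' @param profiles Tibble from [build_profiles()].
#' @param grid Grid labels (defaults to all non-`gene`/`complete` columns).
#' @param complete_only Drop incomplete profiles (default `TRUE`).
#' @return Numeric matrix, genes in rows (rownames), grid points in columns.
#' @export
profile_matrix <- function(profiles, grid = NULL, complete_only = TRUE) {
  if (is.null(grid)) grid <- setdiff(names(profiles), c("gene", "complete"))
  if (complete_only && "complete" %in% names(profiles)) {
    dropped <- profiles$gene[!profiles$complete]
    if (length(dropped) > 0) {
      rlang::warn(paste0("Excluding incomplete profiles: ",
                         paste(dropped, collapse = ", ")))
    }
    profiles <- profiles |> dplyr::filter(.data$complete)
  }
  m <- as.matrix(profiles[, grid])
  rownames(m) <- profiles$gene
  m
}

#' Classify temperature responses of a profile
#'
#' Labels every (condition, timepoint) value `up` when `log2fc >=
#' threshold`, `down` when `log2fc <= -threshold`, else `unchanged`. The
#' boundary `|log2fc| == threshold` counts as a response. The default
#' threshold 1 reflects the common `|log2FC| < 1` "no obvious change"
#' convention.
#'
#' @param records Long records (`gene`, `condition`, `timepoint`, `log2fc`)
#'   or a wide profile table from [build_profiles()].
#' @param threshold Nonnegative log2 fold-change cutoff (default 1).
#' @return Long tibble with `gene`, `condition`, `timepoint`, `log2fc`,
#'   `response`.
#' @export
classify_response <- function(records, threshold = 1) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  if (!"log2fc" %in% names(records)) {
    # wide profile table: melt back to long
    grid <- setdiff(names(records), c("gene", "complete"))
    records <- records |>
      dplyr::select(dplyr::all_of(c("gene", grid))) |>
      tidyr::pivot_longer(-"gene", names_to = "point",
                          values_to = "log2fc") |>
      tidyr::separate_wider_delim("point", delim = "_",
                                  names = c("condition", "timepoint")) |>
      dplyr::mutate(timepoint = as.numeric(.data$timepoint))
  }
  records |>
    dplyr::mutate(response = dplyr::case_when(
      is.na(.data$log2fc) ~ NA_character_,
      .data$log2fc >= threshold ~ "up",
      .data$log2fc <= -threshold ~ "down",
      TRUE ~ "unchanged"
    ))
}

#' Filter a differential-expression table by q-value
#'
#' Retains records with `q_value` strictly below `q_max`; fold-change
#' direction passes through unmodified.
#'
#' @param de Tibble with at least `gene` and `q_value` columns.
#' @param q_max Strict upper bound on q (default 0.05).
#' @return The retained rows.
#' @export
filter_de <- function(de, q_max = 0.05) {
  if (!"q_value" %in% names(de)) {
    abort_lipid("DE table needs a 'q_value' column.", "lipidnet_input_error")
  }
  if (nrow(de) > 0 &&
      (any(!is.finite(de$q_value)) || any(de$q_value < 0 | de$q_value > 1))) {
    abort_lipid("q-values must lie in [0, 1].", "lipidnet_malformed_record")
  }
  de |> dplyr::filter(.data$q_value < q_max)
}

#' Read a wide log2 fold-change table
#'
#' Genes in rows (first column), one column per grid point named
#' `<condition>_<timepoint>`. `.xlsx` supported via readxl; text input is
#' TSV/CSV.
#'
#' @param path File path.
#' @return Long tibble with `gene`, `condition`, `timepoint`, `log2fc`,
#'   suitable for [build_profiles()].
#' @export
read_log2fc_wide <- function(path) {
  wide <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_lipid("Reading .xlsx requires the readxl package.",
                  "lipidnet_input_error")
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else {
    read_delim_auto(path)
  }
  names(wide)[1] <- "gene"
  wide |>
    tidyr::pivot_longer(-"gene", names_to = "point", values_to = "log2fc") |>
    tidyr::separate_wider_delim("point", delim = "_",
                                names = c("condition", "timepoint")) |>
    dplyr::mutate(timepoint = as.numeric(.data$timepoint))
}
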