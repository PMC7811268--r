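# Long-format lipidome tables: validation and I/O.

#' Validate a long-format lipidome table
#'
#' A lipidome table has one row per (species, condition, replicate) with the
#' measured amount in nmol per mg dry weight. Columns: `species` (shorthand
#' name), `condition` (e.g. `"LT"`, `"NT"`, `"HT"`), `replicate` (index) and
#' `amount` (nonnegative). Species names must parse (see
#' [parse_lipid_species()]) and be internally unique per sample.
#'
#' @param df A data frame in the long lipidome layout.
#' @return The input as a tibble, invisibly augmented with parsed `class`,
#'   `carbons`, `double_bonds`, `chains` and `category` columns (added when
#'   absent).
#' @export
as_lipidome <- function(df) {
  need <- c("species", "condition", "replicate", "amount")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort_lipid(paste0("Lipidome table lacks columns: ",
                       paste(missing_cols, collapse = ", ")),
                "lipidnet_input_error")
  }
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    abort_lipid("Lipidome table is empty.", "lipidnet_empty_input")
  }
  if (any(!is.finite(df$amount)) || any(df$amount < 0)) {
    abort_lipid("Amounts must be finite and nonnegative.",
                "lipidnet_input_error")
  }
  dup <- df |>
    dplyr::count(.data$species, .data$condition, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_lipid(
      paste0("Duplicate species within a sample, e.g. '", dup$species[1], "'"),
      "lipidnet_input_error"
    )
  }
  if (!all(c("class", "carbons", "double_bonds") %in% names(df))) {
    key <- parse_lipid_species(unique(df$species))
    df <- df |>
      dplyr::left_join(
        key |> dplyr::select("name", "class", "carbons", "double_bonds",
                             "chains", "category"),
        by = c(species = "name")
      )
  }
  df
}

#' Read a long-format lipidome table
#'
#' Reads a TSV/CSV with columns `species`, `condition`, `replicate`,
#' `amount` and validates it with [as_lipidome()].
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` means comma, anything else tab).
#' @return A validated lipidome tibble.
#' @export
read_lipidome <- function(path) {
  df <- read_delim_auto(path)
  as_lipidome(df)
}

#' Read a wide-format lipidome spreadsheet
#'
#' Reads a species-by-sample table (first column species names, remaining
#' columns named `<condition>_<replicate>`, e.g. `LT_1`) and pivots it to
#' the long layout. `.xlsx` input is supported when the readxl package is
#' installed; text input is TSV/CSV.
#'
#' @param path File path.
#' @return A validated lipidome tibble.
#' @export
read_lipidome_wide <- function(path) {
  wide <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_lipid("Reading .xlsx requires the readxl package.",
                  "lipidnet_input_error")
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else {
    read_delim_auto(path)
  }
  names(wide)[1] <- "species"
  long <- wide |>
    tidyr::pivot_longer(-"species", names_to = "sample",
                        values_to = "amount") |>
    tidyr::separate_wider_delim("sample", delim = "_",
                                names = c("condition", "replicate")) |>
    dplyr::mutate(replicate = as.integer(.data$replicate))
  as_lipidome(long)
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
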