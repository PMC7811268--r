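# Lipidome summary statistics: class totals, mol%, fold changes, DBI,
# fatty-acid composition.

SCOPES <- c("total_glycerolipids", "within_class",
            "phospholipids_only", "membrane_lipids_only")

# rows of the lipidome belonging to a denominator scope
scope_filter <- function(df, scope) {
  switch(scope,
    total_glycerolipids = df,
    within_class = df,
    phospholipids_only = df |>
      dplyr::filter(.data$category == "phospholipid"),
    membrane_lipids_only = df |>
      dplyr::filter(.data$category != "neutral"),
    abort_lipid(paste0("Unknown scope '", scope, "'"), "lipidnet_input_error")
  )
}

#' Per-class, per-sample lipid totals
#'
#' Sums species amounts within each lipid class for every
#' (condition, replicate) sample. Class totals conserve mass: their sum per
#' sample equals the sum of all species amounts.
#'
#' @param df A lipidome table (see [as_lipidome()]).
#' @return Tibble with columns `class`, `condition`, `replicate`, `total`
#'   (nmol per mg dry weight).
#' @export
lipid_class_totals <- function(df) {
  df <- as_lipidome(df)
  df |>
    dplyr::group_by(.data$class, .data$condition, .data$replicate) |>
    dplyr::summarise(total = sum(.data$amount), .groups = "drop")
}

#' Class or species mol% composition under a denominator scope
#'
#' Computes, per condition, the molar percentage of each class (or species)
#' relative to a denominator scope: all glycerolipids, phospholipids only,
#' membrane lipids only (everything except the neutral TAG/DAG/MAG), or —
#' for species only — within that species' own class. Amounts are averaged
#' across replicates per condition before forming the percentage, and mol%
#' values over the scope members sum to 100 within each condition.
#'
#' @param df A lipidome table.
#' @param scope One of `"total_glycerolipids"`, `"phospholipids_only"`,
#'   `"membrane_lipids_only"`, `"within_class"` (species level only).
#' @param level `"class"` or `"species"`.
#' @return Tibble with columns `unit` (class or canonical species name; plus
#'   `class` at species level), `condition`, `mean_amount`, `sd_amount`
#'   and `mol_percent`.
#' @export
lipid_mol_percent <- function(df, scope = "total_glycerolipids",
                              level = c("class", "species")) {
  df <- as_lipidome(df)
  level <- match.arg(level)
  scope <- match.arg(scope, SCOPES)
  if (scope == "within_class" && level == "class") {
    abort_lipid("Scope 'within_class' is only meaningful at species level.",
                "lipidnet_input_error")
  }
  sub <- scope_filter(df, scope)
  if (nrow(sub) == 0) {
    abort_lipid("No species fall inside the requested scope.",
                "lipidnet_degenerate_scope")
  }
  unit_col <- if (level == "class") "class" else "species"
  if (level == "class") {
    # per-replicate class totals first: SD then reflects biological replicates
    means <- sub |>
      dplyr::group_by(.data$class, .data$condition, .data$replicate) |>
      dplyr::summarise(total = sum(.data$amount), .groups = "drop") |>
      dplyr::group_by(.data$class, .data$condition) |>
      dplyr::summarise(mean_amount = mean(.data$total),
                       sd_amount = stats::sd(.data$total), .groups = "drop")
  } else {
    means <- sub |>
      dplyr::group_by(.data$class, .data$species, .data$condition) |>
      dplyr::summarise(mean_amount = mean(.data$amount),
                       sd_amount = stats::sd(.data$amount), .groups = "drop")
  }
  denom_by <- if (scope == "within_class") c("class", "condition") else "condition"
  out <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(denom_by))) |>
    dplyr::mutate(scope_total = sum(.data$mean_amount)) |>
    dplyr::ungroup()
  if (any(out$scope_total <= 0)) {
    abort_lipid("Scope total amount is zero for at least one condition.",
                "lipidnet_degenerate_scope")
  }
  out |>
    dplyr::mutate(mol_percent = 100 * .data$mean_amount / .data$scope_total,
                  unit = .data[[unit_col]]) |>
    dplyr::select(dplyr::any_of(c("unit", "class", "condition",
                                  "mean_amount", "sd_amount", "mol_percent")))
}

#' Fold change of lipid amounts between two conditions
#'
#' Ratio of replicate-mean amounts, treatment over control, per class or per
#' species. Computed on absolute contents (nmol per mg DW), not on mol%.
#' Units with a zero control mean are reported as `NA` (with a warning),
#' never as infinity.
#'
#' @param df A lipidome table.
#' @param level `"class"` or `"species"`.
#' @param treatment,control Condition labels.
#' @return Tibble with columns `unit`, `mean_treatment`, `mean_control`,
#'   `fold_change`.
#' @export
lipid_fold_change <- function(df, level = c("class", "species"),
                              treatment, control) {
  df <- as_lipidome(df)
  level <- match.arg(level)
  conds <- unique(df$condition)
  if (!all(c(treatment, control) %in% conds)) {
    abort_lipid("Both treatment and control conditions must be present.",
                "lipidnet_input_error")
  }
  unit_col <- if (level == "class") "class" else "species"
  cond_mean <- function(cond) {
    df |>
      dplyr::filter(.data$condition == cond) |>
      dplyr::group_by(unit = .data[[unit_col]], .data$replicate) |>
      dplyr::summarise(total = sum(.data$amount), .groups = "drop") |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(mean_amount = mean(.data$total), .groups = "drop")
  }
  out <- dplyr::full_join(
    cond_mean(treatment) |> dplyr::rename(mean_treatment = "mean_amount"),
    cond_mean(control) |> dplyr::rename(mean_control = "mean_amount"),
    by = "unit"
  ) |>
    tidyr::replace_na(list(mean_treatment = 0, mean_control = 0)) |>
    dplyr::mutate(fold_change = dplyr::if_else(
      .data$mean_control > 0,
      .data$mean_treatment / .data$mean_control,
      NA_real_
    ))
  if (anyNA(out$fold_change)) {
    rlang::warn("Some units have zero control mean; fold change reported as NA.")
  }
  out
}

#' Double-bond index (DBI)
#'
#' The DBI of a scope is the mol-fraction-weighted mean number of C=C double
#' bonds per lipid molecule: `sum(x_i * db_i)` where `x_i` is the mol
#' fraction of species *i* within the scope (from replicate-mean amounts)
#' and `db_i` its total double bonds. A fully saturated scope has DBI 0.
#'
#' @param df A lipidome table.
#' @param scope Denominator scope (see [lipid_mol_percent()]); use
#'   `"within_class"` to obtain one DBI per class.
#' @return Tibble with `condition`, `dbi` (plus `class` for
#'   `"within_class"`).
#' @export
lipid_dbi <- function(df, scope = "membrane_lipids_only") {
  df <- as_lipidome(df)
  scope <- match.arg(scope, SCOPES)
  sub <- scope_filter(df, scope)
  if (nrow(sub) == 0) {
    abort_lipid("No species fall inside the requested scope.",
                "lipidnet_degenerate_scope")
  }
  grp <- if (scope == "within_class") c("class", "condition") else "condition"
  means <- sub |>
    dplyr::group_by(.data$class, .data$species, .data$double_bonds,
                    .data$condition) |>
    dplyr::summarise(mean_amount = mean(.data$amount), .groups = "drop")
  out <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      scope_total = sum(.data$mean_amount),
      dbi = if (sum(.data$mean_amount) > 0)
        sum(.data$mean_amount * .data$double_bonds) / sum(.data$mean_amount)
      else NA_real_,
      .groups = "drop"
    )
  if (any(out$scope_total <= 0)) {
    abort_lipid("Scope total amount is zero for at least one condition.",
                "lipidnet_degenerate_scope")
  }
  out |> dplyr::select(-"scope_total")
}

#' Per-class relative DBI change between conditions
#'
#' `100 * (DBI_treatment - DBI_control) / DBI_control` per lipid class
#' (within-class scope). Classes with zero control DBI are reported as `NA`.
#'
#' @param df A lipidome table.
#' @param treatment,control Condition labels.
#' @return Tibble with `class`, `dbi_treatment`, `dbi_control`,
#'   `pct_change`.
#' @export
lipid_dbi_change <- function(df, treatment, control) {
  per_class <- lipid_dbi(df, scope = "within_class")
  if (!all(c(treatment, control) %in% per_class$condition)) {
    abort_lipid("Both treatment and control conditions must be present.",
                "lipidnet_input_error")
  }
  pick <- function(cond, col) {
    d <- per_class |>
      dplyr::filter(.data$condition == cond) |>
      dplyr::select("class", "dbi")
    names(d)[2] <- col
    d
  }
  dplyr::full_join(pick(treatment, "dbi_treatment"),
                   pick(control, "dbi_control"), by = "class") |>
    dplyr::mutate(pct_change = dplyr::if_else(
      .data$dbi_control > 0,
      100 * (.data$dbi_treatment - .data$dbi_control) / .data$dbi_control,
      NA_real_
    ))
}

#' Fatty-acid mol% composition of a lipid class
#'
#' Decomposes every species of a class into its annotated acyl chains; each
#' chain occurrence contributes the species' replicate-mean amount once. The
#' mol% of a fatty acid (e.g. `"18:3"`) is its chain-weighted amount over the
#' class's total chain-weighted amount, per condition. All species of the
#' class must carry resolved chains.
#'
#' @param df A lipidome table.
#' @param lipid_class Class token, e.g. `"MGDG"`.
#' @return Tibble with `fa` (as `"C:D"`), `condition`, `mol_percent`.
#' @export
lipid_fa_composition <- function(df, lipid_class) {
  df <- as_lipidome(df)
  sub <- df |> dplyr::filter(.data$class == lipid_class)
  if (nrow(sub) == 0) {
    abort_lipid(paste0("No species of class '", lipid_class, "' present."),
                "lipidnet_input_error")
  }
  unresolved <- purrr::map_lgl(sub$chains, is.null)
  if (any(unresolved)) {
    abort_lipid(
      paste0("Species without resolved chains in class '", lipid_class,
             "', e.g. '", sub$species[unresolved][1], "'"),
      "lipidnet_unresolved_chains"
    )
  }
  means <- sub |>
    dplyr::group_by(.data$species, .data$condition) |>
    dplyr::summarise(mean_amount = mean(.data$amount), .groups = "drop") |>
    dplyr::left_join(
      sub |> dplyr::distinct(.data$species, .keep_all = TRUE) |>
        dplyr::select("species", "chains"),
      by = "species"
    )
  expanded <- means |>
    dplyr::mutate(chains = purrr::map(.data$chains, function(ch) {
      tibble::tibble(fa = paste0(ch$carbons, ":", ch$double_bonds))
    })) |>
    tidyr::unnest("chains")
  expanded |>
    dplyr::group_by(.data$condition, .data$fa) |>
    dplyr::summarise(weight = sum(.data$mean_amount), .groups = "drop_last") |>
    dplyr::mutate(mol_percent = 100 * .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::select("fa", "condition", "mol_percent")
}

#' Kruskal-Wallis tests across conditions for each lipid unit
#'
#' Runs [kw_test()] on the per-sample totals of every class (or amounts of
#' every species) across the conditions present in the table.
#'
#' @param df A lipidome table.
#' @param level `"class"` or `"species"`.
#' @param exact Use the exact permutation null (total n must be at most 12).
#' @return Tibble with one row per unit: `unit`, `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
lipid_kw_test <- function(df, level = c("class", "species"), exact = FALSE) {
  df <- as_lipidome(df)
  level <- match.arg(level)
  unit_col <- if (level == "class") "class" else "species"
  totals <- df |>
    dplyr::group_by(unit = .data[[unit_col]], .data$condition,
                    .data$replicate) |>
    dplyr::summarise(total = sum(.data$amount), .groups = "drop")
  totals |>
    dplyr::group_by(.data$unit) |>
    dplyr::group_modify(function(d, key) {
      kw_test(d$total, d$condition, exact = exact)
    }) |>
    dplyr::ungroup()
}
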