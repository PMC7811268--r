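# RT-qPCR relative quantification: Livak 2^-ddCt.

#' Log2 fold changes from Ct values (2^-ddCt)
#'
#' Livak relative quantification. Per replicate, the target Ct is
#' normalised against the mean Ct of the reference gene(s) measured in the
#' same sample (`dCt = Ct_target - mean(Ct_ref)`). The condition effect is
#' then `ddCt = mean(dCt_treatment) - mean(dCt_control)` at the same
#' timepoint, and `log2fc = -ddCt` (fold change `2^log2fc`). With several
#' reference genes the per-replicate reference Ct is their arithmetic mean
#' by default; `ref_aggregate = "geometric"` averages the reference
#' *expression* levels instead (mean of Ct in log space is exactly the
#' arithmetic mean of Ct, so the geometric option aggregates `2^-Ct`).
#'
#' @param ct Tibble with columns `gene`, `role` (`"target"` or
#'   `"reference"`), `condition`, `timepoint`, `replicate`, `ct`.
#' @param control Control condition label (default `"NT"`).
#' @param ref_aggregate `"arithmetic"` (mean Ct) or `"geometric"`
#'   (mean of linear expression, i.e. -log2 of mean 2^-Ct).
#' @return Tibble with one row per (gene, condition, timepoint) for every
#'   non-control condition: `gene`, `condition`, `timepoint`, `log2fc`,
#'   `fold_change`.
#' @export
ddct_log2fc <- function(ct, control = "NT",
                        ref_aggregate = c("arithmetic", "geometric")) {
  ref_aggregate <- match.arg(ref_aggregate)
  need <- c("gene", "role", "condition", "timepoint", "replicate", "ct")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols) > 0) {
    abort_lipid(paste0("Ct table lacks columns: ",
                       paste(missing_cols, collapse = ", ")),
                "lipidnet_input_error")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort_lipid("Ct values must be finite and positive.",
                "lipidnet_input_error")
  }
  refs <- ct |> dplyr::filter(.data$role == "reference")
  if (nrow(refs) == 0) {
    abort_lipid("No reference-gene observations found.",
                "lipidnet_missing_reference")
  }
  ref_ct <- refs |>
    dplyr::group_by(.data$condition, .data$timepoint, .data$replicate) |>
    dplyr::summarise(
      ref_ct = if (ref_aggregate == "arithmetic") mean(.data$ct)
               else -log2(mean(2^-.data$ct)),
      .groups = "drop"
    )
  targets <- ct |> dplyr::filter(.data$role == "target")
  joined <- targets |>
    dplyr::left_join(ref_ct, by = c("condition", "timepoint", "replicate"))
  if (anyNA(joined$ref_ct)) {
    miss <- joined |> dplyr::filter(is.na(.data$ref_ct))
    abort_lipid(
      paste0("No reference observation for condition ", miss$condition[1],
             ", timepoint ", miss$timepoint[1],
             ", replicate ", miss$replicate[1]),
      "lipidnet_missing_reference"
    )
  }
  dct <- joined |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct) |>
    dplyr::group_by(.data$gene, .data$condition, .data$timepoint) |>
    dplyr::summarise(mean_dct = mean(.data$dct), .groups = "drop")
  ctrl <- dct |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select("gene", "timepoint", ctrl_dct = "mean_dct")
  trt <- dct |> dplyr::filter(.data$condition != control)
  if (nrow(trt) == 0) {
    abort_lipid("No treatment conditions present.", "lipidnet_input_error")
  }
  out <- trt |> dplyr::left_join(ctrl, by = c("gene", "timepoint"))
  if (anyNA(out$ctrl_dct)) {
    miss <- out |> dplyr::filter(is.na(.data$ctrl_dct))
    abort_lipid(
      paste0("Missing control ('", control, "') baseline for gene ",
             miss$gene[1], " at timepoint ", miss$timepoint[1]),
      "lipidnet_missing_baseline"
    )
  }
  out |>
    dplyr::mutate(log2fc = -(.data$mean_dct - .data$ctrl_dct),
                  fold_change = 2^.data$log2fc) |>
    dplyr::select("gene", "condition", "timepoint", "log2fc", "fold_change")
}

#' Read a Ct table
#'
#' TSV/CSV with columns `gene`, `role`, `condition`, `timepoint`,
#' `replicate`, `ct`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_ct <- function(path) {
  read_delim_auto(path)
}
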