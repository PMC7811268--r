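# End-to-end orchestration: config, lipidome summary run, network run,
# simulation run. Each run writes tidy TSVs plus a provenance manifest.

#' Read a pipeline configuration file
#'
#' YAML with any of the fields understood by [run_lipidome_summary()],
#' [run_network()] and [run_simulate()]; command-line style overrides can
#' be supplied as a named list.
#'
#' @param path YAML file path.
#' @param overrides Named list merged over the file contents.
#' @return Named list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  config <- if (!is.null(path)) yaml::read_yaml(path) else list()
  utils::modifyList(config, overrides)
}

default_config <- function(config) {
  utils::modifyList(
    list(
      control = "NT",
      scopes = c("total_glycerolipids", "phospholipids_only",
                 "membrane_lipids_only"),
      r_min = 0.9, p_max = 0.05, sign = "positive", boundary = "inclusive",
      exact_kw = FALSE,
      out_dir = ".",
      seed = 1
    ),
    config
  )
}

write_manifest <- function(out_dir, step, config, inputs, outputs) {
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("lipidnet")),
    config = config[setdiff(names(config), "out_dir")],
    inputs = purrr::map(inputs, function(p) {
      list(path = p,
           md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs
  )
  yaml::write_yaml(manifest, file.path(out_dir, paste0(step, "_manifest.yaml")))
}

tsv_with_header <- function(df, path, header_lines) {
  body <- readr::format_tsv(df)
  writeLines(c(paste0("# ", header_lines), sub("\n$", "", body)), path)
  invisible(path)
}

#' Run the lipidome summary pipeline
#'
#' Reads a long-format lipidome table and writes class totals, mol% under
#' each configured scope, per-condition membrane DBI and per-class DBI
#' changes, class fold changes of every non-control condition, and
#' Kruskal-Wallis results — each as a tidy TSV with a units/scope header
#' line — plus a run manifest with input checksums.
#'
#' @param config Named list (or path handled by
#'   [read_pipeline_config()]): needs `lipidome` (input path); optional
#'   `control`, `scopes`, `exact_kw`, `out_dir`.
#' @return Named list of output paths, invisibly.
#' @export
run_lipidome_summary <- function(config) {
  config <- default_config(config)
  if (is.null(config$lipidome)) {
    abort_lipid("Config needs a 'lipidome' input path.", "lipidnet_input_error")
  }
  df <- read_lipidome(config$lipidome)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()

  totals <- lipid_class_totals(df) |>
    dplyr::group_by(.data$class, .data$condition) |>
    dplyr::summarise(mean = mean(.data$total), sd = stats::sd(.data$total),
                     .groups = "drop")
  outputs$class_totals <- file.path(out_dir, "class_totals.tsv")
  tsv_with_header(totals, outputs$class_totals,
                  "class totals, nmol per mg dry weight (mean/sd over replicates)")

  for (scope in config$scopes) {
    mp <- lipid_mol_percent(df, scope = scope, level = "class")
    p <- file.path(out_dir, paste0("mol_percent_", scope, ".tsv"))
    tsv_with_header(mp, p, paste0("class mol%; denominator scope: ", scope))
    outputs[[paste0("mol_percent_", scope)]] <- p
  }

  dbi <- lipid_dbi(df, scope = "membrane_lipids_only")
  outputs$dbi <- file.path(out_dir, "dbi_membrane.tsv")
  tsv_with_header(dbi, outputs$dbi,
                  "double-bond index; scope: membrane_lipids_only")

  conds <- setdiff(unique(df$condition), config$control)
  fc <- purrr::map_dfr(conds, function(cond) {
    lipid_fold_change(df, level = "class", treatment = cond,
                      control = config$control) |>
      dplyr::mutate(treatment = cond, control = config$control)
  })
  outputs$fold_changes <- file.path(out_dir, "class_fold_changes.tsv")
  tsv_with_header(fc, outputs$fold_changes,
                  "class fold changes of mean content (treatment/control)")

  dbic <- purrr::map_dfr(conds, function(cond) {
    lipid_dbi_change(df, treatment = cond, control = config$control) |>
      dplyr::mutate(treatment = cond, control = config$control)
  })
  outputs$dbi_changes <- file.path(out_dir, "dbi_class_changes.tsv")
  tsv_with_header(dbic, outputs$dbi_changes,
                  "per-class DBI relative change, % (within_class scope)")

  kw <- lipid_kw_test(df, level = "class", exact = isTRUE(config$exact_kw))
  outputs$kruskal_wallis <- file.path(out_dir, "kruskal_wallis.tsv")
  tsv_with_header(kw, outputs$kruskal_wallis,
                  "Kruskal-Wallis tests on per-sample class totals across conditions")

  write_manifest(out_dir, "lipidome_summary", config,
                 list(lipidome = config$lipidome),
                 purrr::map_chr(outputs, identity))
  invisible(outputs)
}

#' Run the co-expression network pipeline
#'
#' Reads wide log2FC tables for TFs and genes, assembles profiles
#' (excluding incomplete ones with a warning), builds the thresholded
#' network and writes SIF, GraphML, an edge TSV and a hub report.
#'
#' @param config Named list: needs `tf_log2fc` and `gene_log2fc` (paths to
#'   wide tables); optional `r_min`, `p_max`, `sign`, `boundary`,
#'   `out_dir`.
#' @return The `coexpression_network`, invisibly.
#' @export
run_network <- function(config) {
  config <- default_config(config)
  if (is.null(config$tf_log2fc) || is.null(config$gene_log2fc)) {
    abort_lipid("Config needs 'tf_log2fc' and 'gene_log2fc' input paths.",
                "lipidnet_input_error")
  }
  tf_profiles <- build_profiles(read_log2fc_wide(config$tf_log2fc))
  gene_profiles <- build_profiles(read_log2fc_wide(config$gene_log2fc))
  net <- build_network(tf_profiles, gene_profiles,
                       r_min = config$r_min, p_max = config$p_max,
                       sign = config$sign, boundary = config$boundary)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(
    sif = file.path(out_dir, "network.sif"),
    graphml = file.path(out_dir, "network.graphml"),
    edges = file.path(out_dir, "network_edges.tsv"),
    hubs = file.path(out_dir, "hub_report.tsv")
  )
  write_network_sif(net, outputs$sif)
  write_network_graphml(net, outputs$graphml)
  write_network_edges(net, outputs$edges)
  th <- net$thresholds
  tsv_with_header(
    hub_summary(net), outputs$hubs,
    paste0("hub degrees; criterion: r ",
           if (th$boundary == "inclusive") ">= " else "> ", th$r_min,
           " (", th$sign, "), p < ", th$p_max)
  )
  write_manifest(out_dir, "network", config,
                 list(tf_log2fc = config$tf_log2fc,
                      gene_log2fc = config$gene_log2fc),
                 purrr::map_chr(outputs, identity))
  invisible(net)
}

#' Run the simulators and write fixture datasets
#'
#' Generates the default synthetic lipidome and expression time-course at
#' the configured seed and writes the long lipidome TSV, wide TF/gene
#' log2FC TSVs, and YAML truth files.
#'
#' @param config Named list: optional `seed`, `out_dir`, plus a
#'   `lipidome_spec`/`expression_spec` created with the `*_sim_spec()`
#'   constructors.
#' @return Named list of output paths, invisibly.
#' @export
run_simulate <- function(config) {
  config <- default_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lip_spec <- config$lipidome_spec %||% lipidome_sim_spec()
  expr_spec <- config$expression_spec %||% expression_sim_spec()
  lip <- simulate_lipidome(lip_spec, seed = config$seed)
  expr <- simulate_expression(expr_spec, seed = config$seed)
  outputs <- list(
    lipidome = file.path(out_dir, "synthetic_lipidome.tsv"),
    lipidome_truth = file.path(out_dir, "synthetic_lipidome_truth.yaml"),
    tf_log2fc = file.path(out_dir, "synthetic_tf_log2fc.tsv"),
    gene_log2fc = file.path(out_dir, "synthetic_gene_log2fc.tsv"),
    expression_truth = file.path(out_dir, "synthetic_expression_truth.yaml")
  )
  readr::write_tsv(
    lip$lipidome[, c("species", "condition", "replicate", "amount")],
    outputs$lipidome, progress = FALSE
  )
  write_truth(lip$truth, outputs$lipidome_truth)
  wide_out <- function(profiles) {
    profiles |> dplyr::select(-dplyr::any_of("complete"))
  }
  readr::write_tsv(wide_out(expr$tf_profiles), outputs$tf_log2fc,
                   progress = FALSE)
  readr::write_tsv(wide_out(expr$gene_profiles), outputs$gene_log2fc,
                   progress = FALSE)
  write_truth(expr$truth, outputs$expression_truth)
  write_manifest(out_dir, "simulate", config, list(),
                 purrr::map_chr(outputs, identity))
  invisible(outputs)
}
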