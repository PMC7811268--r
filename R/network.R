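# TF -> lipid-gene co-expression network: Pearson correlation over log2FC
# profiles, thresholded edges, hub summaries, Cytoscape-ready exports.

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, with
#' `p = 2 * P(T_{n-2} >= |t|)`. Perfect correlations (`|r| = 1`) are
#' reported as `p = 0`.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (at least 3).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
pearson_p <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1 + 1e-12))
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(
    abs(r) >= 1, 0,
    2 * stats::pt(-abs(r) * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2)
  )
  p
}

#' Edge-criterion presets
#'
#' Two printed forms of the same network construction circulate for this
#' analysis: a main-text criterion (`|R| > 0.9` strict, `P < 0.05`) and a
#' figure-caption criterion (`R >= 0.9` inclusive, `P < 0.005`). Both are
#' exposed; `"results_text"` is the default used by [build_network()].
#'
#' @param preset `"results_text"` or `"figure_caption"`.
#' @return Named list with `r_min`, `p_max`, `sign`, `boundary`.
#' @export
network_preset <- function(preset = c("results_text", "figure_caption")) {
  preset <- match.arg(preset)
  switch(preset,
    results_text = list(r_min = 0.9, p_max = 0.05,
                        sign = "positive", boundary = "strict"),
    figure_caption = list(r_min = 0.9, p_max = 0.005,
                          sign = "positive", boundary = "inclusive")
  )
}

#' Build a thresholded TF-gene co-expression network
#'
#' Evaluates the Pearson correlation of every TF profile against every gene
#' profile over a shared grid and retains the pairs meeting the correlation
#' and significance thresholds. The result is bipartite: edges run only
#' from TFs to genes, and an identifier may not appear on both sides.
#'
#' @param tf_profiles,gene_profiles Profile tables from [build_profiles()]
#'   (or numeric matrices with genes in rows). Incomplete profiles are
#'   excluded with a warning.
#' @param r_min Correlation threshold (default 0.9).
#' @param p_max Significance threshold (default 0.05).
#' @param sign `"positive"` keeps only positively correlated pairs (the
#'   default, matching the published network's red positive edges);
#'   `"both"` applies the thresholds to `|r|`.
#' @param boundary `"inclusive"` retains `|r| >= r_min` (default),
#'   `"strict"` requires `|r| > r_min`. `p < p_max` is always strict.
#' @return A `coexpression_network` object: list with `edges` (tibble
#'   `tf`, `gene`, `r`, `p_value`, `n`), `tfs`, `genes`, `thresholds`.
#' @seealso [network_preset()], [hub_summary()], [write_network_sif()]
#' @export
build_network <- function(tf_profiles, gene_profiles,
                          r_min = 0.9, p_max = 0.05,
                          sign = c("positive", "both"),
                          boundary = c("inclusive", "strict")) {
  sign <- match.arg(sign)
  boundary <- match.arg(boundary)
  tf_m <- if (is.matrix(tf_profiles)) tf_profiles else profile_matrix(tf_profiles)
  g_m <- if (is.matrix(gene_profiles)) gene_profiles else profile_matrix(gene_profiles)
  if (nrow(tf_m) == 0 || nrow(g_m) == 0) {
    abort_lipid("Empty profile set.", "lipidnet_empty_input")
  }
  if (ncol(tf_m) != ncol(g_m) ||
      !identical(colnames(tf_m), colnames(g_m))) {
    abort_lipid("TF and gene profiles are not on the same grid.",
                "lipidnet_grid_mismatch")
  }
  overlap <- intersect(rownames(tf_m), rownames(g_m))
  if (length(overlap) > 0) {
    abort_lipid(paste0("Identifiers on both sides break the bipartite ",
                       "contract: ", paste(overlap, collapse = ", ")),
                "lipidnet_input_error")
  }
  n <- ncol(tf_m)
  if (n < 3) {
    abort_lipid("Profiles need at least 3 grid points.",
                "lipidnet_input_error")
  }
  const_tf <- apply(tf_m, 1, function(x) stats::sd(x) == 0)
  const_g <- apply(g_m, 1, function(x) stats::sd(x) == 0)
  if (any(const_tf) || any(const_g)) {
    rlang::warn(paste0(
      "Constant profiles excluded (correlation undefined): ",
      paste(c(rownames(tf_m)[const_tf], rownames(g_m)[const_g]),
            collapse = ", ")))
    tf_m <- tf_m[!const_tf, , drop = FALSE]
    g_m <- g_m[!const_g, , drop = FALSE]
  }
  if (nrow(tf_m) == 0 || nrow(g_m) == 0) {
    abort_lipid("No usable profiles after exclusions.",
                "lipidnet_empty_input")
  }
  rmat <- stats::cor(t(tf_m), t(g_m))
  edges <- tibble::tibble(
    tf = rep(rownames(rmat), times = ncol(rmat)),
    gene = rep(colnames(rmat), each = nrow(rmat)),
    r = as.vector(rmat),
    n = n
  ) |>
    dplyr::mutate(p_value = pearson_p(.data$r, .data$n))
  r_eff <- if (sign == "positive") edges$r else abs(edges$r)
  keep_r <- if (boundary == "inclusive") r_eff >= r_min else r_eff > r_min
  edges <- edges[keep_r & edges$p_value < p_max, ] |>
    dplyr::select("tf", "gene", "r", "p_value", "n")
  structure(
    list(
      edges = edges,
      tfs = rownames(tf_m),
      genes = rownames(g_m),
      thresholds = list(r_min = r_min, p_max = p_max, sign = sign,
                        boundary = boundary)
    ),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  th <- x$thresholds
  cat("Co-expression network:", length(x$tfs), "TFs x", length(x$genes),
      "genes,", nrow(x$edges), "edges\n")
  cat("  criterion: r", if (th$boundary == "inclusive") ">=" else ">",
      th$r_min, "(", th$sign, "), p <", th$p_max, "\n")
  hs <- hub_summary(x)
  if (nrow(hs) > 0) {
    cat("  hub TFs:", nrow(hs), "| distinct target genes:",
        length(unique(x$edges$gene)), "\n")
  }
  invisible(x)
}

#' Per-TF degree table for a network
#'
#' @param network A `coexpression_network`.
#' @return Tibble `tf`, `degree` (edge count), sorted by decreasing degree;
#'   only TFs with at least one edge appear.
#' @export
hub_summary <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  network$edges |>
    dplyr::count(.data$tf, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$tf)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edge list of a co-expression network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return The edge tibble (`tf`, `gene`, `r`, `p_value`, `n`).
#' @export
tidy.coexpression_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a co-expression network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return Tibble with `n_tfs`, `n_genes`, `n_edges`, `n_hub_tfs` (TFs with
#'   at least one edge), `n_target_genes` (distinct genes with at least one
#'   edge), `max_degree`, and the thresholds used.
#' @export
glance.coexpression_network <- function(x, ...) {
  hs <- hub_summary(x)
  tibble::tibble(
    n_tfs = length(x$tfs),
    n_genes = length(x$genes),
    n_edges = nrow(x$edges),
    n_hub_tfs = nrow(hs),
    n_target_genes = length(unique(x$edges$gene)),
    max_degree = if (nrow(hs) > 0) hs$degree[1] else 0L,
    r_min = x$thresholds$r_min,
    p_max = x$thresholds$p_max,
    sign = x$thresholds$sign,
    boundary = x$thresholds$boundary
  )
}

network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("tf", "gene", "r", "p_value")],
    directed = TRUE,
    vertices = tibble::tibble(
      name = c(network$tfs, network$genes),
      type = rep(c("TF", "gene"),
                 c(length(network$tfs), length(network$genes)))
    )
  )
  g
}

#' Export a network in SIF format
#'
#' One line per edge: `tf <tab> coexpressed_with <tab> gene`, directly
#' importable into Cytoscape.
#'
#' @param network A `coexpression_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  lines <- sprintf("%s\tcoexpressed_with\t%s",
                   network$edges$tf, network$edges$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry a `type` attribute (`TF`/`gene`); edges carry `r` and
#' `p_value`.
#'
#' @param network A `coexpression_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::write_graph(network_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export the edge list as TSV
#'
#' @param network A `coexpression_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' Plot a co-expression network
#'
#' Bipartite layout: TFs on the left, target genes on the right, one
#' segment per retained edge coloured by correlation strength. Only nodes
#' with at least one edge are drawn.
#'
#' @param object A `coexpression_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  edges <- object$edges
  if (nrow(edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
             ggplot2::theme_void())
  }
  tfs <- sort(unique(edges$tf))
  genes <- sort(unique(edges$gene))
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = tfs, type = "TF", x = 0,
                   y = seq_along(tfs) / (length(tfs) + 1)),
    tibble::tibble(name = genes, type = "gene", x = 1,
                   y = seq_along(genes) / (length(genes) + 1))
  )
  seg <- edges |>
    dplyr::left_join(nodes |> dplyr::select(tf = "name", x0 = "x", y0 = "y"),
                     by = "tf") |>
    dplyr::left_join(nodes |> dplyr::select(gene = "name", x1 = "x", y1 = "y"),
                     by = "gene")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$r),
      alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x + ifelse(.data$x == 0, -0.05, 0.05),
                   y = .data$y, label = .data$name,
                   hjust = ifelse(.data$x == 0, 1, 0)),
      size = 3
    ) +
    ggplot2::scale_colour_gradient(low = "grey70", high = "firebrick") +
    ggplot2::scale_shape_manual(values = c(TF = 16, gene = 15)) +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Pearson r") +
    ggplot2::theme_void()
}
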