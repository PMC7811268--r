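# Seeded synthetic data: lipidomes with planted class fold changes and
# unsaturation shifts, and expression time-courses with planted TF->gene
# edges. Every generated dataset carries its ground truth.

#' Default lipid class inventory for simulation
#'
#' Fourteen glycerolipid classes totalling 287 species, mirroring the shape
#' of a temperature-stress microalgal lipidome: TAG dominates the molar
#' pool (48% at the control condition), PC is the major phospholipid (>64%
#' of phospholipids), MGDG exceeds DGDG and PG among the photosynthetic
#' lipids, and DGTS is the scarcest class. `share` is the class's fraction
#' of total moles at the control condition; `n_species` the number of
#' molecular species drawn for the class.
#'
#' @return Tibble with `class`, `n_species`, `share`.
#' @export
default_class_inventory <- function() {
  tibble::tribble(
    ~class, ~n_species, ~share,
    "TAG",  75, 0.480,
    "DAG",  25, 0.025,
    "MAG",   6, 0.004,
    "MGDG", 20, 0.038,
    "DGDG", 18, 0.022,
    "DGTS", 12, 0.003,
    "PC",   40, 0.275,
    "PE",   30, 0.065,
    "PG",   20, 0.030,
    "PI",   15, 0.033,
    "PS",    8, 0.008,
    "PA",    6, 0.006,
    "CL",    6, 0.006,
    "LPE",   6, 0.005
  )
}

#' Specification for a synthetic lipidome
#'
#' Defines the study conditions a simulated lipidome embodies. The defaults
#' reproduce the published temperature-stress design: three conditions
#' (LT/NT/HT) with four biological replicates, 287 species over 14 classes,
#' TAG content planted at 2.3-fold (LT) and 3.4-fold (HT) over NT — which,
#' with TAG at 48 mol% at NT, puts TAG at 68.0 and 75.8 mol% of total
#' glycerolipids — a membrane double-bond index planted at 2.46 (NT/HT) and
#' 3.41 (LT) by exponential tilting of within-class species abundances, six
#' dominant polyunsaturated TAG species holding ~80% of the TAG pool, and
#' lognormal replicate noise at 10% CV.
#'
#' @param inventory Class inventory tibble (see
#'   [default_class_inventory()]).
#' @param conditions Condition labels; the first is the control.
#' @param n_replicates Biological replicates per condition.
#' @param class_fold Named list: per condition, a named numeric vector of
#'   class fold changes over the control (classes absent from the vector
#'   fold 1).
#' @param membrane_dbi Named numeric: target membrane-lipid DBI per
#'   condition (achieved by tilting within-class species weights; class
#'   totals are preserved).
#' @param six_tag_share Combined control-condition share of the six
#'   dominant TAG species within the TAG class.
#' @param galacto_di183_share Control-condition within-class share of the
#'   di-18:3 (36:6) species in MGDG and DGDG; under the LT unsaturation
#'   tilt this species rises to clear dominance of its class, as cold
#'   stress drives it to in the organism.
#' @param cv Replicate coefficient of variation (lognormal, multiplicative).
#' @param total_nt Total glycerolipid content at the control condition,
#'   nmol per mg DW.
#' @return A `lipidome_sim_spec` list.
#' @export
lipidome_sim_spec <- function(inventory = default_class_inventory(),
                              conditions = c("NT", "LT", "HT"),
                              n_replicates = 4,
                              class_fold = list(LT = c(TAG = 2.3),
                                                HT = c(TAG = 3.4)),
                              membrane_dbi = c(NT = 2.46, LT = 3.41,
                                               HT = 2.46),
                              six_tag_share = 0.806,
                              galacto_di183_share = 0.62,
                              cv = 0.10,
                              total_nt = 30) {
  spec <- list(inventory = inventory, conditions = conditions,
               n_replicates = n_replicates, class_fold = class_fold,
               membrane_dbi = membrane_dbi, six_tag_share = six_tag_share,
               galacto_di183_share = galacto_di183_share,
               cv = cv, total_nt = total_nt)
  validate_lipidome_spec(spec)
  spec
}

validate_lipidome_spec <- function(spec) {
  inv <- spec$inventory
  if (!all(c("class", "n_species", "share") %in% names(inv)) ||
      any(inv$n_species < 1) || any(inv$share <= 0)) {
    abort_lipid("Invalid class inventory.", "lipidnet_spec_error")
  }
  if (!all(inv$class %in% LIPID_CLASSES)) {
    abort_lipid("Inventory classes must be in the vocabulary.",
                "lipidnet_spec_error")
  }
  if (spec$cv < 0) abort_lipid("CV must be >= 0.", "lipidnet_spec_error")
  if (spec$n_replicates < 1) {
    abort_lipid("Need at least one replicate.", "lipidnet_spec_error")
  }
  folds <- unlist(spec$class_fold)
  if (length(folds) > 0 && any(folds <= 0)) {
    abort_lipid("Class fold changes must be positive.", "lipidnet_spec_error")
  }
  invisible(spec)
}

# Acyl-chain palette for classes emitted with resolved chains.
FA_PALETTE <- c("16:0", "16:1", "16:2", "16:3",
                "18:0", "18:1", "18:2", "18:3")

# Draw (carbons, double_bonds) compositions for a class; galactolipids and
# DGTS get resolved chain pairs from the palette, other classes only totals.
sim_species_for_class <- function(class, n) {
  if (class %in% c("MGDG", "DGDG", "DGTS")) {
    fa <- do.call(rbind, strsplit(FA_PALETTE, ":"))
    fa <- data.frame(c = as.integer(fa[, 1]), d = as.integer(fa[, 2]))
    pairs <- expand.grid(i = seq_len(nrow(fa)), j = seq_len(nrow(fa)))
    pairs <- pairs[pairs$i <= pairs$j, ]
    # put the di-18:3 species first so it is always present
    key <- which(pairs$i == 8 & pairs$j == 8)
    ord <- c(key, setdiff(order(fa$d[pairs$i] + fa$d[pairs$j],
                                decreasing = TRUE), key))
    pairs <- pairs[ord, ][seq_len(min(n, nrow(pairs))), ]
    tibble::tibble(
      class = class,
      carbons = fa$c[pairs$i] + fa$c[pairs$j],
      double_bonds = fa$d[pairs$i] + fa$d[pairs$j],
      chain1 = paste0(fa$c[pairs$i], ":", fa$d[pairs$i]),
      chain2 = paste0(fa$c[pairs$j], ":", fa$d[pairs$j])
    )
  } else {
    ranges <- list(
      TAG = list(c = seq(44, 58, 2), d = 0:9),
      DAG = list(c = seq(32, 40, 2), d = 0:6),
      MAG = list(c = 16:22, d = 0:3),
      PC = list(c = seq(30, 40, 2), d = 0:6),
      PE = list(c = seq(32, 40, 2), d = 0:6),
      PG = list(c = seq(32, 38, 2), d = 0:6),
      PI = list(c = seq(32, 38, 2), d = 0:6),
      PS = list(c = seq(34, 40, 2), d = 0:5),
      PA = list(c = seq(32, 38, 2), d = 0:4),
      CL = list(c = seq(68, 72, 2), d = 0:8),
      LPE = list(c = 16:18, d = 0:3)
    )[[class]]
    grid <- expand.grid(carbons = ranges$c, double_bonds = ranges$d)
    grid <- grid[grid$double_bonds < grid$carbons, ]
    idx <- sample(nrow(grid), min(n, nrow(grid)))
    tibble::tibble(class = class,
                   carbons = grid$carbons[idx],
                   double_bonds = grid$double_bonds[idx],
                   chain1 = NA_character_, chain2 = NA_character_)
  }
}

# Dialect-mixing name emitter: exercises the parser's tolerance.
emit_species_names <- function(tbl) {
  n <- nrow(tbl)
  dialect <- sample(c("tight", "space", "paren"), n, replace = TRUE)
  comp <- paste0(tbl$carbons, ":", tbl$double_bonds)
  base <- ifelse(dialect == "tight", paste0(tbl$class, comp),
          ifelse(dialect == "space", paste0(tbl$class, " ", comp),
                 paste0(tbl$class, "(", comp, ")")))
  has_chain <- !is.na(tbl$chain1)
  # chain annotation only combines with non-paren composition forms
  base[has_chain & dialect == "paren"] <-
    paste0(tbl$class, comp)[has_chain & dialect == "paren"]
  ifelse(has_chain,
         paste0(base, "(", tbl$chain1, "/", tbl$chain2, ")"),
         base)
}

# Solve the common within-class exponential tilt t so that the
# membrane-scope DBI of the tilted class-preserving weights hits `target`.
# Tilting multiplies species weights by exp(t * db) and renormalises within
# each class, so class totals are untouched while unsaturated species gain
# (t > 0) or lose (t < 0) share.
solve_dbi_tilt <- function(weights, dbs, classes, class_totals, target) {
  dbi_at <- function(t) {
    w <- weights * exp(t * dbs)
    scaled <- unsplit(
      lapply(split(seq_along(w), classes), function(ix) {
        w[ix] / sum(w[ix]) * class_totals[[classes[ix[1]]]]
      }),
      classes
    )
    sum(scaled * dbs) / sum(scaled)
  }
  lo <- -20; hi <- 20
  if (target <= dbi_at(lo) || target >= dbi_at(hi)) {
    abort_lipid("Membrane DBI target is outside the achievable range.",
                "lipidnet_spec_error")
  }
  stats::uniroot(function(t) dbi_at(t) - target, c(lo, hi),
                 tol = 1e-10)$root
}

#' Simulate a lipidome with planted ground truth
#'
#' Draws baseline species abundances lognormally within each class, scales
#' class totals by the planted per-condition fold changes, redistributes
#' within-class abundance by an exponential unsaturation tilt solved to hit
#' the planted membrane DBI target of each condition, and finally applies
#' multiplicative lognormal replicate noise (mean-preserving) at the
#' specified CV. Fully reproducible from `seed`.
#'
#' @param spec A [lipidome_sim_spec()].
#' @param seed Integer seed.
#' @return List of class `lipidome_sim` with elements `lipidome` (a long
#'   lipidome tibble, see [as_lipidome()]) and `truth` (planted parameters:
#'   spec fields, the solved tilts, and per-condition expected class totals).
#' @export
simulate_lipidome <- function(spec = lipidome_sim_spec(), seed = 1) {
  validate_lipidome_spec(spec)
  set.seed(seed)
  inv <- spec$inventory
  control <- spec$conditions[1]

  species <- purrr::map2_dfr(inv$class, inv$n_species, sim_species_for_class)
  species$name <- emit_species_names(species)
  stopifnot(!anyDuplicated(species$name))

  # baseline (control) species mean amounts: lognormal within class,
  # normalised to the class share of the total pool
  base_raw <- stats::rlnorm(nrow(species), meanlog = 0, sdlog = 1)
  shares <- stats::setNames(inv$share / sum(inv$share), inv$class)
  class_total_nt <- shares * spec$total_nt
  w <- unsplit(
    lapply(split(seq_len(nrow(species)), species$class), function(ix) {
      cls <- species$class[ix[1]]
      v <- base_raw[ix]
      plant_share <- function(v, dom, s) {
        v2 <- v
        v2[dom] <- v[dom] / sum(v[dom]) * s
        v2[-dom] <- v[-dom] / sum(v[-dom]) * (1 - s)
        v2
      }
      if (cls == "TAG") {
        # six dominant polyunsaturated TAG species share a planted ~80%
        dom <- order(species$double_bonds[ix] >= 2 &
                       species$carbons[ix] >= 52, decreasing = TRUE)[1:6]
        v <- plant_share(v, dom, spec$six_tag_share)
      }
      if (cls %in% c("MGDG", "DGDG")) {
        # di-18:3 (36:6) species holds a planted baseline share; the LT
        # tilt then drives it to class dominance
        dom <- which(!is.na(species$chain1[ix]) &
                       species$chain1[ix] == "18:3" &
                       species$chain2[ix] == "18:3")
        if (length(dom) == 1) {
          v <- plant_share(v, dom, spec$galacto_di183_share)
        }
      }
      v / sum(v) * class_total_nt[[cls]]
    }),
    species$class
  )

  membrane <- is_membrane_lipid(species$class)
  cond_means <- list()
  tilts <- stats::setNames(numeric(length(spec$conditions)), spec$conditions)
  for (cond in spec$conditions) {
    folds <- spec$class_fold[[cond]]
    fold_vec <- stats::setNames(rep(1, nrow(inv)), inv$class)
    if (!is.null(folds)) fold_vec[names(folds)] <- folds
    ct <- class_total_nt * fold_vec
    means <- unsplit(
      lapply(split(seq_len(nrow(species)), species$class), function(ix) {
        cls <- species$class[ix[1]]
        w[ix] / sum(w[ix]) * ct[[cls]]
      }),
      species$class
    )
    target <- spec$membrane_dbi[[cond]]
    if (!is.null(target) && !is.na(target)) {
      mem_ix <- which(membrane)
      t_hat <- solve_dbi_tilt(
        means[mem_ix], species$double_bonds[mem_ix],
        species$class[mem_ix],
        ct[unique(species$class[mem_ix])], target
      )
      tilts[[cond]] <- t_hat
      tw <- means[mem_ix] * exp(t_hat * species$double_bonds[mem_ix])
      means[mem_ix] <- unsplit(
        lapply(split(seq_along(mem_ix), species$class[mem_ix]), function(jx) {
          cls <- species$class[mem_ix][jx[1]]
          tw[jx] / sum(tw[jx]) * ct[[cls]]
        }),
        species$class[mem_ix]
      )
    }
    cond_means[[cond]] <- means
  }

  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- purrr::map_dfr(spec$conditions, function(cond) {
    purrr::map_dfr(seq_len(spec$n_replicates), function(rep_i) {
      noise <- if (spec$cv > 0) {
        stats::rlnorm(nrow(species), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, nrow(species))
      tibble::tibble(
        species = species$name,
        condition = cond,
        replicate = rep_i,
        amount = cond_means[[cond]] * noise
      )
    })
  })

  truth <- list(
    seed = seed,
    conditions = spec$conditions,
    control = control,
    n_replicates = spec$n_replicates,
    cv = spec$cv,
    class_fold = spec$class_fold,
    membrane_dbi = as.list(spec$membrane_dbi),
    six_tag_share = spec$six_tag_share,
    tilts = as.list(tilts),
    class_totals = purrr::map(
      stats::setNames(spec$conditions, spec$conditions),
      function(cond) as.list(tapply(cond_means[[cond]], species$class, sum))
    ),
    n_species = nrow(species)
  )
  structure(list(lipidome = as_lipidome(rows), truth = truth),
            class = "lipidome_sim")
}

#' Specification for a synthetic expression time-course
#'
#' Defaults mirror the published network's inputs: 17 TFs and 32
#' lipid-metabolism genes profiled over the six-point LT/HT x 48/96/168 h
#' grid, with a planted bipartite adjacency of 16 regulated genes over 7
#' hub TFs (degrees 8, 3, 1, 1, 1, 1, 1 — the largest hub regulating 8
#' genes) and the remaining genes and TFs independent decoys. Planted
#' targets follow their TF profile linearly with additive Gaussian noise;
#' the default noise SD 0.4 against a TF profile SD of 2 puts the expected
#' planted correlation near 0.98, the strong-coupling regime of hub-driven
#' targets.
#'
#' @param n_tf,n_gene Numbers of TFs and genes.
#' @param grid Profile grid labels.
#' @param edges Planted edge tibble (`tf`, `gene`, `slope`), or `NULL` for
#'   the default hub layout (set `n_planted = 0` for decoys only).
#' @param n_planted Number of planted target genes when `edges` is `NULL`.
#' @param hub_degrees Degree sequence for default hub layout.
#' @param tf_sd SD of TF profile values.
#' @param noise_sd Additive noise SD on planted targets.
#' @param slope Regulatory slope for default edges.
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_tf = 17, n_gene = 32,
                                grid = profile_grid(),
                                edges = NULL,
                                n_planted = 16,
                                hub_degrees = c(8, 3, 1, 1, 1, 1, 1),
                                tf_sd = 2, noise_sd = 0.4, slope = 1) {
  if (noise_sd < 0 || tf_sd <= 0) {
    abort_lipid("tf_sd must be positive and noise_sd nonnegative.",
                "lipidnet_spec_error")
  }
  tf_ids <- sprintf("TF%02d", seq_len(n_tf))
  gene_ids <- sprintf("G%02d", seq_len(n_gene))
  if (is.null(edges)) {
    if (n_planted > 0) {
      degs <- hub_degrees[cumsum(hub_degrees) <= n_planted]
      if (sum(degs) < n_planted) {
        degs <- c(degs, n_planted - sum(degs))
      }
      if (length(degs) > n_tf) {
        abort_lipid("More hubs than TFs.", "lipidnet_spec_error")
      }
      edges <- tibble::tibble(
        tf = rep(tf_ids[seq_along(degs)], degs),
        gene = gene_ids[seq_len(n_planted)],
        slope = slope
      )
    } else {
      edges <- tibble::tibble(tf = character(), gene = character(),
                              slope = numeric())
    }
  }
  if (!all(edges$tf %in% tf_ids) || !all(edges$gene %in% gene_ids)) {
    abort_lipid("Planted edges reference unknown TF/gene ids.",
                "lipidnet_spec_error")
  }
  if (anyDuplicated(edges$gene) > 0) {
    abort_lipid("Each planted gene may have a single driving TF.",
                "lipidnet_spec_error")
  }
  list(n_tf = n_tf, n_gene = n_gene, grid = grid, edges = edges,
       tf_ids = tf_ids, gene_ids = gene_ids,
       tf_sd = tf_sd, noise_sd = noise_sd)
}

#' Simulate expression profiles with planted regulatory edges
#'
#' TF profiles are drawn i.i.d. normal over the grid; each planted target
#' gene follows `slope * TF + noise`; decoy genes are independent draws.
#' Reproducible from `seed`.
#'
#' @param spec An [expression_sim_spec()].
#' @param seed Integer seed.
#' @return List of class `expression_sim` with `tf_profiles` and
#'   `gene_profiles` (wide profile tibbles as from [build_profiles()]) and
#'   `truth` (the planted edge tibble plus generator parameters).
#' @export
simulate_expression <- function(spec = expression_sim_spec(), seed = 1) {
  set.seed(seed)
  np <- length(spec$grid)
  tf_m <- matrix(stats::rnorm(spec$n_tf * np, 0, spec$tf_sd),
                 nrow = spec$n_tf,
                 dimnames = list(spec$tf_ids, spec$grid))
  g_m <- matrix(stats::rnorm(spec$n_gene * np, 0, spec$tf_sd),
                nrow = spec$n_gene,
                dimnames = list(spec$gene_ids, spec$grid))
  if (nrow(spec$edges) > 0) {
    for (i in seq_len(nrow(spec$edges))) {
      e <- spec$edges[i, ]
      g_m[e$gene, ] <- e$slope * tf_m[e$tf, ] +
        stats::rnorm(np, 0, spec$noise_sd)
    }
  }
  as_profile_tbl <- function(m) {
    out <- tibble::as_tibble(m, rownames = "gene")
    out$complete <- TRUE
    out
  }
  truth <- list(
    seed = seed,
    edges = spec$edges,
    tf_sd = spec$tf_sd,
    noise_sd = spec$noise_sd,
    grid = spec$grid,
    tf_ids = spec$tf_ids,
    gene_ids = spec$gene_ids
  )
  structure(
    list(tf_profiles = as_profile_tbl(tf_m),
         gene_profiles = as_profile_tbl(g_m),
         truth = truth),
    class = "expression_sim"
  )
}

#' Write / read a ground-truth file
#'
#' Truth objects are serialised as YAML so they round-trip unchanged
#' through plain text.
#'
#' @param truth Truth list from a simulator.
#' @param path File path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  if (!is.null(truth$edges) && inherits(truth$edges, "data.frame")) {
    truth$edges <- lapply(as.list(as.data.frame(truth$edges)), unname)
  }
  # named atomic vectors must become maps, not bare scalars
  listify <- function(x) {
    if (is.list(x)) return(lapply(x, listify))
    if (is.atomic(x) && !is.null(names(x))) return(lapply(as.list(x), listify))
    x
  }
  yaml::write_yaml(listify(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- yaml::read_yaml(path)
  if (!is.null(truth$edges)) {
    truth$edges <- tibble::as_tibble(truth$edges)
  }
  truth
}
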