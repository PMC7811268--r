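test_that("class totals sum species per sample and conserve mass", {
  df <- fixture_abc()
  totals <- lipid_class_totals(df)
  one <- totals[totals$class == "TAG" & totals$condition == "NT" &
                  totals$replicate == 1, ]
  expect_equal(one$total, 4)
  # addition within a class
  df2 <- tiny_lipidome(tibble::tibble(
    species = c("PC 34:1", "PC 36:2", "PI 34:2"),
    condition = "NT",
    amounts = list(c(1, 1), c(2, 2), c(3, 3))
  ))
  t2 <- lipid_class_totals(df2)
  expect_equal(t2$total[t2$class == "PC"], c(3, 3))
  expect_equal(t2$total[t2$class == "PI"], c(3, 3))
  # conservation per sample
  sim <- simulate_lipidome(seed = 5)
  by_sample_species <- sim$lipidome |>
    dplyr::group_by(condition, replicate) |>
    dplyr::summarise(s = sum(amount), .groups = "drop")
  by_sample_class <- lipid_class_totals(sim$lipidome) |>
    dplyr::group_by(condition, replicate) |>
    dplyr::summarise(s = sum(total), .groups = "drop")
  expect_equal(by_sample_class$s, by_sample_species$s)
  expect_error(lipid_class_totals(fixture_abc()[0, ]),
               class = "lipidnet_empty_input")
})

test_that("mol% does forced arithmetic and sums to 100 in every scope", {
  one <- tiny_lipidome(tibble::tibble(
    species = "PC 34:1", condition = "NT", amounts = list(c(2, 2))
  ))
  expect_equal(lipid_mol_percent(one, "total_glycerolipids",
                                 "species")$mol_percent, 100)
  df <- fixture_abc()  # NT class means: TAG 4, PC 1, PI 3 -> 50/12.5/37.5
  mp <- lipid_mol_percent(df, "total_glycerolipids", "class")
  nt <- mp[mp$condition == "NT", ]
  expect_equal(nt$mol_percent[nt$unit == "TAG"], 50)
  expect_equal(nt$mol_percent[nt$unit == "PC"], 12.5)
  expect_equal(nt$mol_percent[nt$unit == "PI"], 37.5)
  # 1,1,2 forced case
  df3 <- tiny_lipidome(tibble::tibble(
    species = c("PC 34:1", "PE 34:1", "PI 34:2"), condition = "NT",
    amounts = list(c(1, 1), c(1, 1), c(2, 2))
  ))
  mp3 <- lipid_mol_percent(df3, "total_glycerolipids", "class")
  expect_equal(sort(mp3$mol_percent), c(25, 25, 50))
  # normalization across scopes and conditions on a full simulation
  sim <- simulate_lipidome(seed = 5)
  for (scope in c("total_glycerolipids", "phospholipids_only",
                  "membrane_lipids_only")) {
    for (level in c("class", "species")) {
      mp <- lipid_mol_percent(sim$lipidome, scope, level)
      sums <- tapply(mp$mol_percent, mp$condition, sum)
      expect_equal(as.vector(sums), rep(100, length(sums)),
                   tolerance = 1e-9)
    }
  }
  wc <- lipid_mol_percent(sim$lipidome, "within_class", "species")
  sums <- tapply(wc$mol_percent, paste(wc$class, wc$condition), sum)
  expect_equal(as.vector(sums), rep(100, length(sums)), tolerance = 1e-9)
  expect_error(lipid_mol_percent(sim$lipidome, "within_class", "class"),
               class = "lipidnet_input_error")
})

test_that("membrane scope excludes neutral classes; degenerate scopes error", {
  df <- fixture_abc()
  mem <- lipid_mol_percent(df, "membrane_lipids_only", "class")
  expect_false("TAG" %in% mem$unit)
  phos <- lipid_mol_percent(df, "phospholipids_only", "class")
  expect_setequal(unique(phos$unit), c("PC", "PI"))
  neutral_only <- tiny_lipidome(tibble::tibble(
    species = "TAG 52:3", condition = "NT", amounts = list(c(1, 1))
  ))
  expect_error(lipid_mol_percent(neutral_only, "membrane_lipids_only",
                                 "class"),
               class = "lipidnet_degenerate_scope")
})

test_that("fold change is the ratio of replicate means on absolute amounts", {
  df <- fixture_abc()
  fc_id <- lipid_fold_change(df, "class", treatment = "NT", control = "NT")
  expect_equal(fc_id$fold_change, rep(1, nrow(fc_id)))
  fc <- lipid_fold_change(
    tiny_lipidome(tibble::tibble(
      species = rep("TAG 52:3", 2), condition = c("NT", "LT"),
      amounts = list(c(2, 2), c(4.6, 4.6))
    )),
    "class", treatment = "LT", control = "NT"
  )
  expect_equal(fc$fold_change, 2.3)
  # zero control -> NA with warning, never Inf
  zero <- tiny_lipidome(tibble::tibble(
    species = rep("PC 34:1", 2), condition = c("NT", "LT"),
    amounts = list(c(0, 0), c(1, 1))
  ))
  expect_warning(
    fc0 <- lipid_fold_change(zero, "class", treatment = "LT",
                             control = "NT"),
    "zero control"
  )
  expect_true(is.na(fc0$fold_change))
  expect_error(lipid_fold_change(df, "class", "HT", "NT"),
               class = "lipidnet_input_error")
})

test_that("DBI is the mol-fraction-weighted double-bond count", {
  saturated <- tiny_lipidome(tibble::tibble(
    species = c("PC 34:0", "PE 36:0"), condition = "NT",
    amounts = list(c(1, 1), c(2, 2))
  ))
  expect_equal(lipid_dbi(saturated, "membrane_lipids_only")$dbi, 0)
  midpoint <- tiny_lipidome(tibble::tibble(
    species = c("PC 34:2", "PC 34:4"), condition = "NT",
    amounts = list(c(1, 1), c(1, 1))
  ))
  expect_equal(lipid_dbi(midpoint, "membrane_lipids_only")$dbi, 3)
  # bounds: min db <= DBI <= max db within scope
  sim <- simulate_lipidome(seed = 9)
  mem <- sim$lipidome[sim$lipidome$category != "neutral", ]
  d <- lipid_dbi(sim$lipidome, "membrane_lipids_only")
  expect_true(all(d$dbi >= min(mem$double_bonds)))
  expect_true(all(d$dbi <= max(mem$double_bonds)))
  per_class <- lipid_dbi(sim$lipidome, "within_class")
  rng <- mem |>
    dplyr::group_by(class) |>
    dplyr::summarise(lo = min(double_bonds), hi = max(double_bonds))
  joined <- dplyr::left_join(
    per_class[per_class$class %in% rng$class, ], rng, by = "class"
  )
  expect_true(all(joined$dbi >= joined$lo & joined$dbi <= joined$hi))
})

test_that("per-class DBI change does the stated arithmetic", {
  df <- tiny_lipidome(tibble::tibble(
    species = rep(c("PC 34:2", "PC 34:4"), each = 2),
    condition = rep(c("NT", "LT"), 2),
    amounts = list(c(1, 1), c(1, 1), c(1, 1), c(3, 3))
  ))
  # NT DBI: (2+4)/2 = 3; LT DBI: (2*1 + 4*3)/4 = 3.5 -> +16.666%
  ch <- lipid_dbi_change(df, treatment = "LT", control = "NT")
  expect_equal(ch$dbi_control, 3)
  expect_equal(ch$dbi_treatment, 3.5)
  expect_equal(ch$pct_change, 100 * 0.5 / 3)
  same <- lipid_dbi_change(df, treatment = "NT", control = "NT")
  expect_equal(same$pct_change, 0)
})

test_that("mol%, DBI and fold changes are invariant to amount rescaling", {
  sim <- simulate_lipidome(seed = 13)
  df <- sim$lipidome
  df_scaled <- df |> dplyr::mutate(amount = amount * 7.3)
  expect_equal(
    lipid_mol_percent(df_scaled, "total_glycerolipids", "class")$mol_percent,
    lipid_mol_percent(df, "total_glycerolipids", "class")$mol_percent
  )
  expect_equal(lipid_dbi(df_scaled, "membrane_lipids_only")$dbi,
               lipid_dbi(df, "membrane_lipids_only")$dbi)
  expect_equal(
    lipid_fold_change(df_scaled, "class", "LT", "NT")$fold_change,
    lipid_fold_change(df, "class", "LT", "NT")$fold_change
  )
})

test_that("fatty-acid composition weighs each chain occurrence by amount", {
  single <- tiny_lipidome(tibble::tibble(
    species = "MGDG36:6(18:3/18:3)", condition = "NT", amounts = list(c(2, 2))
  ))
  fa <- lipid_fa_composition(single, "MGDG")
  expect_equal(fa$fa, "18:3")
  expect_equal(fa$mol_percent, 100)
  two <- tiny_lipidome(tibble::tibble(
    species = c("DGDG34:1(16:0/18:1)", "DGDG36:2(18:1/18:1)"),
    condition = "NT", amounts = list(c(1, 1), c(1, 1))
  ))
  fa2 <- lipid_fa_composition(two, "DGDG")
  expect_equal(fa2$mol_percent[fa2$fa == "16:0"], 25)
  expect_equal(fa2$mol_percent[fa2$fa == "18:1"], 75)
  # per-condition normalisation to 100
  sim <- simulate_lipidome(seed = 2)
  fam <- lipid_fa_composition(sim$lipidome, "MGDG")
  sums <- tapply(fam$mol_percent, fam$condition, sum)
  expect_equal(as.vector(sums), rep(100, length(sums)), tolerance = 1e-9)
  # species without chains
  bare <- tiny_lipidome(tibble::tibble(
    species = "PC 34:1", condition = "NT", amounts = list(c(1, 1))
  ))
  expect_error(lipid_fa_composition(bare, "PC"),
               class = "lipidnet_unresolved_chains")
})
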