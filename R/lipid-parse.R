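# Glycerolipid shorthand nomenclature: parsing, formatting, categories.

# Controlled vocabulary of glycerolipid classes. SQDG is deliberately absent:
# the sulfolipid is not covered by the analysis this package targets.
LIPID_CLASSES <- c(
  "TAG", "DAG", "MAG", "MGDG", "DGDG",
  "PC", "PI", "PE", "PG", "PS", "CL", "PA", "LPE", "DGTS"
)

# Export-dialect synonyms applied before the vocabulary check.
LIPID_CLASS_SYNONYMS <- c(
  TG = "TAG", DG = "DAG", MG = "MAG", LYSOPE = "LPE"
)

LIPID_CATEGORY_MAP <- c(
  TAG = "neutral", DAG = "neutral", MAG = "neutral",
  MGDG = "galactolipid", DGDG = "galactolipid",
  PC = "phospholipid", PI = "phospholipid", PE = "phospholipid",
  PG = "phospholipid", PS = "phospholipid", CL = "phospholipid",
  PA = "phospholipid", LPE = "phospholipid",
  DGTS = "betaine"
)

abort_lipid <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "lipidnet_error"), ...)
}

#' Parse glycerolipid shorthand names
#'
#' Parses species names such as `"TAG 52:3"`, `"TAG(52:3)"`, `"TAG52:3"` or
#' `"MGDG36:6(18:3/18:3)"` into a structured record: lipid class, total acyl
#' carbons, total double bonds and (when annotated) the resolved acyl chains.
#' Common export dialects are accepted: the separator between the class token
#' and the `C:D` block may be nothing, whitespace or parentheses, and an
#' optional trailing parenthesised chain list `(a:b/c:d...)` resolves the
#' individual fatty acyl chains. Class synonyms `TG`, `DG`, `MG` and `LysoPE`
#' are normalised to `TAG`, `DAG`, `MAG` and `LPE` before the vocabulary
#' check. Ether/oxidised notations (`O-`, `P-`) are rejected.
#'
#' @param x Character vector of species names.
#' @return A tibble with one row per input name and columns `name` (input),
#'   `class`, `carbons`, `double_bonds`, `chains` (list column: a tibble of
#'   per-chain `carbons`/`double_bonds`, or `NULL` when unannotated),
#'   `category` (see [lipid_category()]) and `canonical` (the canonical
#'   rendering, see [format_lipid_species()]).
#' @details Errors are classed so callers can distinguish failure modes:
#'   `lipidnet_unknown_class` (class token not in the vocabulary),
#'   `lipidnet_malformed_species` (no parseable `C:D` block, or chain
#'   double-bond count not below chain carbons), and
#'   `lipidnet_inconsistent_chains` (annotated chains do not sum to the
#'   stated totals).
#' @examples
#' parse_lipid_species(c("TAG 52:3", "MGDG36:6(18:3/18:3)", "PC 34:0"))
#' @export
parse_lipid_species <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(
      name = character(), class = character(), carbons = integer(),
      double_bonds = integer(), chains = list(), category = character(),
      canonical = character()
    ))
  }
  stopifnot(is.character(x))
  if (anyNA(x) || any(!nzchar(trimws(x)))) {
    abort_lipid("Species names must be non-empty strings.",
                "lipidnet_malformed_species")
  }
  rows <- purrr::map(x, parse_one_species)
  out <- tibble::tibble(
    name = purrr::map_chr(rows, "name"),
    class = purrr::map_chr(rows, "class"),
    carbons = purrr::map_int(rows, "carbons"),
    double_bonds = purrr::map_int(rows, "double_bonds"),
    chains = purrr::map(rows, "chain_tbl")
  )
  out$category <- lipid_category(out$class)
  out$canonical <- format_lipid_species(out)
  out[, c("name", "class", "carbons", "double_bonds", "chains",
          "category", "canonical")]
}

parse_one_species <- function(name) {
  s <- trimws(name)
  if (grepl("\\b[OP]-", s)) {
    abort_lipid(
      paste0("Ether/oxidised lipid notation is not supported: '", name, "'"),
      "lipidnet_malformed_species"
    )
  }
  # leading class token: letters only
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*(.*)$", s))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    abort_lipid(paste0("Cannot find a class token in '", name, "'"),
                "lipidnet_malformed_species")
  }
  cls <- toupper(m[2])
  if (cls %in% names(LIPID_CLASS_SYNONYMS)) cls <- LIPID_CLASS_SYNONYMS[[cls]]
  if (!cls %in% LIPID_CLASSES) {
    abort_lipid(paste0("Unknown lipid class '", m[2], "' in '", name, "'"),
                "lipidnet_unknown_class")
  }
  rest <- trimws(m[3])
  # composition block, optionally parenthesised, optional chain annotation
  comp <- regmatches(
    rest,
    regexec("^\\(?\\s*(\\d+)\\s*:\\s*(\\d+)\\s*\\)?\\s*(\\(([0-9:/ ]+)\\))?\\s*$",
            rest)
  )[[1]]
  if (length(comp) == 0) {
    abort_lipid(paste0("Malformed carbon:double-bond block in '", name, "'"),
                "lipidnet_malformed_species")
  }
  carbons <- as.integer(comp[2])
  dbs <- as.integer(comp[3])
  if (carbons <= 0 || dbs < 0 || dbs >= carbons) {
    abort_lipid(
      paste0("Implausible composition ", carbons, ":", dbs, " in '", name, "'"),
      "lipidnet_malformed_species"
    )
  }
  chain_tbl <- NULL
  if (nzchar(comp[4])) {
    chain_tbl <- parse_chain_block(comp[5], name)
    if (sum(chain_tbl$carbons) != carbons ||
        sum(chain_tbl$double_bonds) != dbs) {
      abort_lipid(
        paste0("Acyl chains (", paste0(chain_tbl$carbons, ":",
                                       chain_tbl$double_bonds, collapse = "/"),
               ") do not sum to ", carbons, ":", dbs, " in '", name, "'"),
        "lipidnet_inconsistent_chains"
      )
    }
  }
  list(name = name, class = cls, carbons = carbons, double_bonds = dbs,
       chain_tbl = chain_tbl)
}

parse_chain_block <- function(block, name) {
  parts <- strsplit(trimws(block), "/", fixed = TRUE)[[1]]
  parsed <- purrr::map(parts, function(p) {
    cm <- regmatches(p, regexec("^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*$", p))[[1]]
    if (length(cm) == 0) {
      abort_lipid(paste0("Malformed acyl chain '", p, "' in '", name, "'"),
                  "lipidnet_malformed_species")
    }
    c(carbons = as.integer(cm[2]), double_bonds = as.integer(cm[3]))
  })
  tbl <- tibble::tibble(
    carbons = purrr::map_int(parsed, "carbons"),
    double_bonds = purrr::map_int(parsed, "double_bonds")
  )
  bad <- tbl$carbons < 2 | tbl$double_bonds < 0 | tbl$double_bonds >= tbl$carbons
  if (any(bad)) {
    abort_lipid(paste0("Implausible acyl chain in '", name, "'"),
                "lipidnet_malformed_species")
  }
  tbl
}

#' Lipid category of a class
#'
#' Maps lipid classes onto the four glycerolipid categories used for
#' composition scopes: neutral lipids (TAG, DAG, MAG), galactolipids
#' (MGDG, DGDG), phospholipids (PC, PI, PE, PG, PS, CL, PA, LPE) and the
#' betaine lipid DGTS. Membrane lipids are all categories except `neutral`.
#'
#' @param class Character vector of class tokens (must be in the vocabulary).
#' @return Character vector of categories.
#' @examples
#' lipid_category(c("TAG", "DGTS", "PA"))
#' @export
lipid_category <- function(class) {
  bad <- setdiff(unique(class), names(LIPID_CATEGORY_MAP))
  if (length(bad) > 0) {
    abort_lipid(paste0("Unknown lipid class: ", paste(bad, collapse = ", ")),
                "lipidnet_unknown_class")
  }
  unname(LIPID_CATEGORY_MAP[class])
}

#' Is a class a membrane lipid?
#'
#' @param class Character vector of class tokens.
#' @return Logical vector: `TRUE` for every non-neutral class.
#' @export
is_membrane_lipid <- function(class) {
  lipid_category(class) != "neutral"
}

#' Canonical rendering of parsed species
#'
#' Formats parsed species back to the canonical shorthand `"CLASS C:D"` or
#' `"CLASS C:D(a:b/...)"`; re-parsing the canonical form reproduces the
#' parsed record exactly.
#'
#' @param parsed A tibble from [parse_lipid_species()] (or any data frame
#'   with `class`, `carbons`, `double_bonds` and a `chains` list column).
#' @return Character vector of canonical names.
#' @export
format_lipid_species <- function(parsed) {
  base <- paste0(parsed$class, " ", parsed$carbons, ":", parsed$double_bonds)
  chain_part <- purrr::map_chr(parsed$chains, function(ch) {
    if (is.null(ch) || nrow(ch) == 0) return("")
    paste0("(", paste0(ch$carbons, ":", ch$double_bonds, collapse = "/"), ")")
  })
  paste0(base, chain_part)
}
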