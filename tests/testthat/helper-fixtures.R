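# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# tiny long-format lipidome from a compact description:
# species = named numeric vector of per-condition mean amounts is too rigid,
# so take a data frame of (species, condition, amounts-per-replicate).
tiny_lipidome <- function(rows) {
  purrr::pmap_dfr(rows, function(species, condition, amounts) {
    tibble::tibble(species = species, condition = condition,
                   replicate = seq_along(amounts), amount = amounts)
  })
}

# a 3-species, 2-condition lipidome with exact round numbers
fixture_abc <- function() {
  tiny_lipidome(tibble::tibble(
    species = rep(c("TAG 52:3", "PC 34:1", "PI 34:2"), each = 2),
    condition = rep(c("NT", "LT"), times = 3),
    amounts = list(c(4, 4), c(4, 4), c(1, 1), c(2, 2), c(3, 3), c(2, 2))
  ))
}

# independent brute-force Pearson correlation: direct two-pass evaluation of
# the covariance / variance formula, no stats:: shortcuts
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# independent exact Kruskal-Wallis oracle: enumerate group splits with
# explicit nested combn loops and evaluate H from rank sums written out
# directly (tie-corrected), counting the tail.
kw_exact_oracle <- function(values, sizes) {
  n <- sum(sizes)
  stopifnot(length(values) == n)
  r <- rank(values)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(list(h = 0, p = 1))
  h_of <- function(split_list) {
    s <- 0
    for (g in seq_along(split_list)) {
      s <- s + sum(r[split_list[[g]]])^2 / length(split_list[[g]])
    }
    (12 / (n * (n + 1)) * s - 3 * (n + 1)) / corr
  }
  obs <- h_of(split(seq_len(n), rep(seq_along(sizes), sizes)))
  splits <- list(list())
  enumerate <- function(avail, remaining) {
    if (length(remaining) == 1) return(list(list(avail)))
    out <- list()
    for (pick in utils::combn(avail, remaining[1], simplify = FALSE)) {
      for (rest in enumerate(setdiff(avail, pick), remaining[-1])) {
        out[[length(out) + 1]] <- c(list(pick), rest)
      }
    }
    out
  }
  all_splits <- enumerate(seq_len(n), sizes)
  hs <- vapply(all_splits, h_of, numeric(1))
  list(h = obs, p = mean(hs >= obs - 1e-12), n_splits = length(all_splits))
}
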