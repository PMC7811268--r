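# Kruskal-Wallis rank test with an optional exact permutation null.

#' Kruskal-Wallis test with optional exact permutation p-value
#'
#' Computes the Kruskal-Wallis H statistic on ranks with the usual tie
#' correction. By default the p-value comes from the chi-square
#' approximation with k-1 degrees of freedom; with `exact = TRUE` the
#' p-value is the exact permutation tail: the proportion of all distinct
#' assignments of the observed ranks to groups of the observed sizes whose
#' H is at least the observed H. Exact mode enumerates every assignment and
#' is limited to total n of at most 12 (34650 assignments for three groups
#' of four).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least two groups,
#'   each with at least two observations.
#' @param exact Logical; use the exact permutation null.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `method`,
#'   `n`, `n_groups`.
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6, 7, 8), rep(c("a", "b"), each = 4), exact = TRUE)
#' @export
kw_test <- function(values, groups, exact = FALSE) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) {
    abort_lipid("Kruskal-Wallis needs at least two groups.",
                "lipidnet_insufficient_replicates")
  }
  if (any(sizes < 2)) {
    abort_lipid("Every group needs at least two observations.",
                "lipidnet_insufficient_replicates")
  }
  n <- length(values)
  k <- length(sizes)
  r <- rank(values)
  h <- kw_h(r, groups, sizes)
  if (!exact) {
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  } else {
    if (n > 12) {
      abort_lipid("Exact mode enumerates all rank assignments; n must be <= 12.",
                  "lipidnet_exact_too_large")
    }
    p <- kw_exact_p(r, as.integer(sizes), h)
    method <- "exact permutation"
  }
  tibble::tibble(statistic = h, df = k - 1, p_value = p, method = method,
                 n = n, n_groups = k)
}

# H on ranks with tie correction
kw_h <- function(r, groups, sizes = table(groups)) {
  n <- length(r)
  rg <- tapply(r, groups, sum)
  h <- 12 / (n * (n + 1)) * sum(rg^2 / as.numeric(sizes[names(rg)])) -
    3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)  # all values tied: no rank separation
  h / corr
}

# exact tail probability by full enumeration of group assignments.
# Assignments are generated recursively: choose which rank positions fall in
# group 1, then group 2 from the remainder, and so on; the last group is
# forced. H is invariant to within-group order, so each multiset split is
# counted once and all splits are equally likely under the null.
kw_exact_p <- function(r, sizes, h_obs) {
  n <- length(r)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(1)
  const <- 12 / (n * (n + 1))
  k <- length(sizes)
  count <- 0L
  total <- 0L
  recurse <- function(avail, gi, acc) {
    if (gi == k) {
      stat <- const * (acc + sum(r[avail])^2 / sizes[k]) - 3 * (n + 1)
      stat <- stat / corr
      total <<- total + 1L
      if (stat >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
    for (p in picks) {
      recurse(setdiff(avail, p), gi + 1L, acc + sum(r[p])^2 / sizes[gi])
    }
  }
  recurse(seq_len(n), 1L, 0)
  count / total
}
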