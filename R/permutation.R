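# Permutation test for gene-set overlap, with an exact hypergeometric oracle.

#' Permutation test for overlap between two gene sets
#'
#' Observed statistic is `|set_a intersect set_b|`. Each permutation draws a
#' uniform random subset of the universe of size `|set_b|` and records its
#' overlap with `set_a`; the p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (n_perm + 1)`, which never returns zero.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes (typically all
#'   genes expressed in the single-cell dataset).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List of class `overlap_test`: `observed`, `null_overlaps`,
#'   `p_value`, `universe_size`, `set_a_size`, `set_b_size`, `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(set_a, set_b, universe,
                                     n_perm = 1000, seed = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set_a is not contained in the universe")
  if (!all(set_b %in% universe)) stop("set_b is not contained in the universe")
  set.seed(as.integer(seed))
  in_a <- universe %in% set_a
  observed <- sum(set_b %in% set_a)
  nb <- length(set_b); nu <- length(universe)
  null <- vapply(seq_len(n_perm),
                 function(i) sum(in_a[sample.int(nu, nb)]),
                 integer(1))
  structure(list(observed = observed, null_overlaps = null,
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 universe_size = nu, set_a_size = length(set_a),
                 set_b_size = nb, n_perm = n_perm, seed = seed),
            class = "overlap_test")
}

#' Exact hypergeometric upper tail
#'
#' `P(X >= observed)` for `X ~ Hypergeometric(universe_size, k_a, k_b)` (the
#' overlap of a uniform random `k_b`-subset with a fixed `k_a`-subset),
#' computed by summing the mass function. Exact oracle for
#' [overlap_permutation_test()].
#'
#' @param universe_size,k_a,k_b Universe and set sizes.
#' @param observed Observed overlap.
#' @return Upper-tail probability (1 when `observed <= 0`, 0 when `observed`
#'   exceeds `min(k_a, k_b)`).
#' @export
hypergeometric_tail <- function(universe_size, k_a, k_b, observed) {
  if (any(c(universe_size, k_a, k_b) < 0) || k_a > universe_size ||
      k_b > universe_size || observed < 0)
    stop("invalid counts")
  hi <- min(k_a, k_b)
  if (observed == 0) return(1)
  if (observed > hi) return(0)
  sum(stats::dhyper(observed:hi, k_a, universe_size - k_a, k_b))
}
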