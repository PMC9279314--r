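#' Jaccard (Tanimoto) similarity of two selections
#'
#' `|A ∩ B| / |A ∪ B|`, the standard measure of spatial overlap between two
#' priority-area selections compared as unit id-sets. Defined as 0 when
#' both sets are empty.
#'
#' @param a,b character vectors of unit ids (duplicates ignored).
#' @return numeric in `[0, 1]`.
#' @export
jaccard_coefficient <- function(a, b) {
  a <- unique(selected_ids(a)); b <- unique(selected_ids(b))
  un <- length(union(a, b))
  if (un == 0) return(0)
  length(intersect(a, b)) / un
}

#' Expected Jaccard similarity of independent random selections
#'
#' Expectation of J over two independent uniform random subsets of fixed
#' sizes from a universe of `universe_n` units — the reference point for
#' "more/less overlap than expected". The exact method sums over the
#' hypergeometric distribution of the intersection size,
#' `E[J] = sum_k P(X = k) * k / (size_a + size_b - k)`, which is the exact
#' enumeration over all subset pairs collapsed by symmetry; Monte Carlo
#' draws seeded random subset pairs.
#'
#' @param size_a,size_b subset sizes.
#' @param universe_n universe size.
#' @param method `"exact"` (default for `universe_n <= 12`, valid for any
#'   size) or `"monte_carlo"`.
#' @param n_draws Monte Carlo draws.
#' @param seed Monte Carlo seed.
#' @return expected Jaccard coefficient.
#' @export
expected_jaccard <- function(size_a, size_b, universe_n,
                             method = c("exact", "monte_carlo"),
                             n_draws = 10000, seed = 1) {
  method <- match.arg(method)
  if (size_a > universe_n || size_b > universe_n) {
    stop("subset sizes exceed the universe size", call. = FALSE)
  }
  if (size_a == 0 && size_b == 0) return(0)
  if (method == "exact") {
    k <- max(0, size_a + size_b - universe_n):min(size_a, size_b)
    pk <- stats::dhyper(k, size_a, universe_n - size_a, size_b)
    return(sum(pk * k / (size_a + size_b - k)))
  }
  set.seed(seed)
  mean(replicate(n_draws, {
    a <- sample.int(universe_n, size_a)
    b <- sample.int(universe_n, size_b)
    length(intersect(a, b)) / length(union(a, b))
  }))
}

#' Permutation test for overlap between two selections
#'
#' Tests whether two priority-area selections overlap more (or less) than
#' expected for independent uniform random subsets of the same sizes from
#' the same unit universe. The null distribution is generated by seeded
#' random subset pairs with the observed marginal sizes; the p-value uses
#' the add-one correction `p = (1 + #{J_null at least as extreme}) /
#' (1 + n_permutations)`, so it is never exactly 0. `two_sided` doubles the
#' smaller tail (capped at 1).
#'
#' @param a,b selections (character id vectors or `selection` objects).
#' @param universe character vector of all unit ids.
#' @param n_permutations number of null draws (default 999).
#' @param seed RNG seed (the test is deterministic given it).
#' @param alternative `"greater"` (more overlap than expected), `"less"`, or
#'   `"two_sided"`.
#' @return list of class `overlap_result`: `jaccard`, `expected_jaccard`,
#'   `p_value`, `alternative`, `n_permutations`, `seed`.
#' @export
jaccard_permutation_test <- function(a, b, universe, n_permutations = 999,
                                     seed = 1,
                                     alternative = c("greater", "less",
                                                     "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  a <- unique(selected_ids(a)); b <- unique(selected_ids(b))
  out_a <- setdiff(a, universe); out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    stop("selection ids outside the universe: ",
         paste(c(out_a, out_b), collapse = ", "), call. = FALSE)
  }
  stopifnot(n_permutations >= 1)
  j_obs <- jaccard_coefficient(a, b)
  n <- length(universe)
  na <- length(a); nb <- length(b)
  set.seed(seed)
  j_null <- vapply(seq_len(n_permutations), function(i) {
    pa <- sample.int(n, na)
    pb <- sample.int(n, nb)
    un <- length(union(pa, pb))
    if (un == 0) 0 else length(intersect(pa, pb)) / un
  }, numeric(1))
  eps <- 1e-12
  p_greater <- (1 + sum(j_null >= j_obs - eps)) / (1 + n_permutations)
  p_less <- (1 + sum(j_null <= j_obs + eps)) / (1 + n_permutations)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(jaccard = j_obs,
                 expected_jaccard = expected_jaccard(na, nb, n),
                 p_value = p, alternative = alternative,
                 n_permutations = n_permutations, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Jaccard overlap J = %.3f (expected %.3f), p = %.4g [%s, %d permutations]\n",
              x$jaccard, x$expected_jaccard, x$p_value, x$alternative,
              x$n_permutations))
  invisible(x)
}

#' Pairwise Jaccard matrix of a list of selections
#'
#' @param selections named list of selections.
#' @return symmetric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(selections) {
  k <- length(selections)
  m <- matrix(1, k, k, dimnames = list(names(selections), names(selections)))
  if (k < 2) return(m)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- jaccard_coefficient(selections[[i]], selections[[j]])
  }
  m
}
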