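#' Compound-pair functional-relationship score Q
#'
#' Scores the functional relationship of two compounds from their ontology
#' annotation: Q is the arithmetic mean of the shortest-path hop distance
#' `d(t1, t2)` over the full Cartesian product of the two term sets,
#'
#' \deqn{Q(c_1, c_2) = \mathrm{Mean}\{\, d(t_1, t_2) : t_1 \in T(c_1),\,
#'   t_2 \in T(c_2) \,\}.}{Q(c1,c2) = Mean{ d(t1,t2) : t1 in T(c1), t2 in T(c2) }.}
#'
#' The smaller Q, the stronger the functional relationship. Duplicate
#' distances count as often as they occur (multiset mean). Q is kept as an
#' exact integer fraction — the sum of hop counts over the pair count — so
#' that the exact-tie comparisons in nearest-neighbor selection never depend
#' on floating-point rounding. If any cross pair of terms is unreachable
#' (different connected components), Q is undefined and the value is `NA`.
#'
#' @param g An [ontology_graph][parse_obo].
#' @param terms_a,terms_b Non-empty character vectors of term ids; every
#'   term must exist in `g`.
#'
#' @return A `compound_q` object: list with `value` (numeric mean, `NA` if
#'   undefined), `numerator` (integer sum of hop counts), `denominator`
#'   (number of term pairs) and `defined` (logical).
#'
#' @examples
#' g <- parse_obo(c("[Term]", "id: A", "[Term]", "id: B", "is_a: A",
#'                  "[Term]", "id: C", "is_a: B"))
#' compound_similarity(g, "A", "C")$value  # 2
#' @export
compound_similarity <- function(g, terms_a, terms_b) {
  stopifnot(inherits(g, "ontology_graph"))
  if (length(terms_a) == 0L || length(terms_b) == 0L) {
    stop("both term sets must be non-empty", call. = FALSE)
  }
  d <- term_distance_matrix(g, terms_a, terms_b)
  q_from_distances(d)
}

q_from_distances <- function(d) {
  n <- length(d)
  if (any(is.infinite(d))) {
    structure(list(value = NA_real_, numerator = NA_real_,
                   denominator = n, defined = FALSE),
              class = "compound_q")
  } else {
    s <- sum(d)
    structure(list(value = s / n, numerator = s, denominator = n,
                   defined = TRUE),
              class = "compound_q")
  }
}

#' @export
print.compound_q <- function(x, ...) {
  if (x$defined) {
    cat("Q = ", x$numerator, "/", x$denominator, " = ",
        format(x$value), "\n", sep = "")
  } else {
    cat("Q undefined (some term pair unreachable; ",
        x$denominator, " pairs)\n", sep = "")
  }
  invisible(x)
}

# Exact comparison of two Q fractions by cross-multiplication.
# Returns -1, 0, 1. All quantities are small integers; products are exact.
q_compare <- function(num1, den1, num2, den2) {
  lhs <- num1 * den2
  rhs <- num2 * den1
  (lhs > rhs) - (lhs < rhs)
}
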