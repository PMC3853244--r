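#' Nearest training drugs by ontology distance
#'
#' Scores the query term set against every training drug with the
#' compound-pair score Q ([compound_similarity()]) and returns all training
#' drugs attaining the exact minimum:
#'
#' \deqn{Q(d_q, d_1) = \cdots = Q(d_q, d_s) = \min_{d \in S'} Q(d_q, d).}{
#'   Q(dq,d1) = ... = Q(dq,ds) = min over d in S' of Q(dq,d).}
#'
#' Ties are exact: Q values are compared as integer fractions, so drugs in
#' the neighbor set share the minimum bit-for-bit, not to a floating-point
#' tolerance. Training drugs whose Q is undefined (some term unreachable
#' from the query's terms) are excluded; if every training drug is
#' undefined, the neighbor set is empty — a "no prediction" outcome, which
#' [vote()] and the evaluation protocols surface explicitly.
#'
#' @param g An [ontology_graph][parse_obo].
#' @param query_terms Non-empty character vector of the query drug's terms.
#' @param train A drug table tibble (the reference collection S').
#'
#' @return A `neighbor_set` object: list with `members` (tibble `drug_id`,
#'   `group`, `score`, `numerator`, `denominator`), `criterion` (`"min_Q"`)
#'   and `n_candidates` (training drugs with a defined score).
#' @seealso [nearest_by_interaction()], [vote()], [predict_target()]
#' @export
nearest_by_ontology <- function(g, query_terms, train) {
  stopifnot(inherits(g, "ontology_graph"))
  if (nrow(train) == 0L) stop("training set is empty", call. = FALSE)
  if (length(query_terms) == 0L) {
    stop("query term set must be non-empty", call. = FALSE)
  }

  all_terms <- unique(unlist(train$terms, use.names = FALSE))
  d <- term_distance_matrix(g, query_terms, all_terms)

  num <- den <- numeric(nrow(train))
  defined <- logical(nrow(train))
  for (i in seq_len(nrow(train))) {
    sub <- d[, match(train$terms[[i]], all_terms), drop = FALSE]
    den[i] <- length(sub)
    defined[i] <- all(is.finite(sub))
    num[i] <- if (defined[i]) sum(sub) else NA_real_
  }

  new_neighbor_set(train, num, den, defined, criterion = "min_Q")
}

# Shared argmin/argmax-with-exact-ties construction. Scores are fractions
# num/den; for max_I, den is 1 and larger is better.
new_neighbor_set <- function(train, num, den, defined, criterion) {
  idx <- which(defined)
  if (length(idx) == 0L) {
    return(empty_neighbor_set(criterion, n_candidates = 0L))
  }
  sign <- if (criterion == "min_Q") 1 else -1
  best <- idx[1]
  for (i in idx[-1]) {
    if (sign * q_compare(num[i], den[i], num[best], den[best]) < 0) best <- i
  }
  ties <- idx[vapply(idx, function(i) {
    q_compare(num[i], den[i], num[best], den[best]) == 0
  }, logical(1))]

  structure(
    list(
      members = tibble::tibble(
        drug_id = train$drug_id[ties],
        group = train$group[ties],
        score = num[ties] / den[ties],
        numerator = num[ties],
        denominator = den[ties]
      ),
      criterion = criterion,
      n_candidates = length(idx)
    ),
    class = "neighbor_set"
  )
}

empty_neighbor_set <- function(criterion, n_candidates = 0L) {
  structure(
    list(
      members = tibble::tibble(
        drug_id = character(), group = character(), score = numeric(),
        numerator = numeric(), denominator = numeric()
      ),
      criterion = criterion,
      n_candidates = n_candidates
    ),
    class = "neighbor_set"
  )
}

#' Build a neighbor set from a table of tied records
#'
#' Wraps a drug table as a `neighbor_set` whose members all share one
#' optimal score, for feeding externally determined neighbor lists (for
#' example a published worked example) straight into the voting stage.
#'
#' @param drugs A drug table tibble (`drug_id`, `group`; `terms` ignored).
#' @param score The shared score (default 0).
#' @param criterion `"min_Q"` or `"max_I"`.
#' @return A `neighbor_set`.
#' @examples
#' nb <- read_drug_table(
#'   system.file("extdata", "neighbors_D00146.tsv", package = "ontarget")
#' ) |> as_neighbor_set()
#' vote(nb, seed = 1)
#' @export
as_neighbor_set <- function(drugs, score = 0, criterion = c("min_Q", "max_I")) {
  criterion <- match.arg(criterion)
  structure(
    list(
      members = tibble::tibble(
        drug_id = drugs$drug_id,
        group = drugs$group,
        score = score,
        numerator = score,
        denominator = rep(1, nrow(drugs))
      ),
      criterion = criterion,
      n_candidates = nrow(drugs)
    ),
    class = "neighbor_set"
  )
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("<neighbor_set> criterion ", x$criterion, ", ",
      nrow(x$members), " member(s) of ", x$n_candidates,
      " scored candidate(s)\n", sep = "")
  if (nrow(x$members) > 0L) print(x$members)
  invisible(x)
}

#' Nearest training drugs by chemical-interaction score
#'
#' Returns the training drugs attaining the maximum interaction score I with
#' the query:
#'
#' \deqn{I(d_q, d_1) = \cdots = I(d_q, d_s) = \max_{d \in S'} I(d_q, d).}{
#'   I(dq,d1) = ... = I(dq,ds) = max over d in S' of I(dq,d).}
#'
#' A score of 0 encodes non-interaction and carries no evidence, so a
#' maximum of exactly 0 — the query interacts with no training drug — yields
#' an empty neighbor set (a "no prediction" outcome) rather than an
#' all-drugs tie.
#'
#' @param interactions An interaction table ([read_interactions()]).
#' @param query_id Chemical id of the query drug.
#' @param train A drug table tibble.
#'
#' @return A `neighbor_set` with `criterion = "max_I"`; `score` holds the
#'   interaction scores.
#' @export
nearest_by_interaction <- function(interactions, query_id, train) {
  if (nrow(train) == 0L) stop("training set is empty", call. = FALSE)
  s <- interaction_score(interactions, query_id, train$drug_id)
  defined <- s > 0
  if (!any(defined)) {
    return(empty_neighbor_set("max_I", n_candidates = 0L))
  }
  new_neighbor_set(train, num = s, den = rep(1, length(s)),
                   defined = defined, criterion = "max_I")
}

#' Majority vote over a neighbor set
#'
#' Tallies the target groups of all optimal-score neighbors; the group with
#' the most votes is the prediction. When several groups tie for the most
#' votes, one is chosen uniformly at random under the supplied seed, and the
#' outcome records that randomness was used (`tie_broken`). An empty
#' neighbor set yields a no-prediction outcome (`predicted_group` is `NA`).
#'
#' @param neighbors A `neighbor_set` ([nearest_by_ontology()],
#'   [nearest_by_interaction()]).
#' @param seed Integer seed for tie-breaking.
#' @param drug_id Optional query drug id carried into the result.
#'
#' @return A `target_prediction` object: list with `drug_id`,
#'   `predicted_group` (`NA_character_` on no-prediction), `votes` (named
#'   integer vector, descending), `neighbors` and `tie_broken` (logical).
#'
#' @examples
#' \dontrun{
#' vote(nearest_by_ontology(g, c("CHEBI:3892"), train), seed = 1)
#' }
#' @export
vote <- function(neighbors, seed, drug_id = NA_character_) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  if (nrow(neighbors$members) == 0L) {
    return(structure(
      list(drug_id = drug_id, predicted_group = NA_character_,
           votes = integer(), neighbors = neighbors, tie_broken = FALSE),
      class = "target_prediction"
    ))
  }
  tally <- sort(table(neighbors$members$group), decreasing = TRUE)
  votes <- stats::setNames(as.integer(tally), names(tally))
  top <- names(votes)[votes == max(votes)]
  tie_broken <- length(top) > 1L
  predicted <- if (tie_broken) {
    withr::with_seed(seed, sample(top, 1L))
  } else {
    top
  }
  structure(
    list(drug_id = drug_id, predicted_group = predicted, votes = votes,
         neighbors = neighbors, tie_broken = tie_broken),
    class = "target_prediction"
  )
}

#' @export
print.target_prediction <- function(x, ...) {
  if (!is.na(x$drug_id)) cat("Query drug:", x$drug_id, "\n")
  if (is.na(x$predicted_group)) {
    cat("No prediction (no training drug with a defined/positive score)\n")
  } else {
    cat("Predicted target group:", x$predicted_group,
        if (x$tie_broken) "(tie broken at random)" else "", "\n")
    cat("Votes:\n")
    for (g in names(x$votes)) cat("  ", g, ": ", x$votes[[g]], "\n", sep = "")
  }
  invisible(x)
}

#' Predict a drug's target group
#'
#' End-to-end prediction for one query drug: find the optimal-score
#' neighbors in the training set under the chosen backend, then take the
#' majority vote of their target groups. The `"ontology"` backend minimizes
#' the mean term-distance score Q and needs the term graph `g`; the
#' `"interaction"` backend maximizes the chemical-interaction score I and
#' needs `interactions` plus `query_id`. Deterministic given its inputs and
#' `seed`. A query drug also present in the training set is *not* excluded
#' here — leave-one-out exclusion is the evaluation protocol's job
#' ([jackknife()]).
#'
#' @param train A drug table tibble.
#' @param query_terms Query drug's ontology terms (ontology backend).
#' @param query_id Query drug id (required for the interaction backend;
#'   otherwise only carried into the result).
#' @param backend `"ontology"` or `"interaction"`.
#' @param g An [ontology_graph][parse_obo] (ontology backend).
#' @param interactions An interaction table (interaction backend).
#' @param seed Integer seed for tie-breaking.
#'
#' @return A `target_prediction` ([vote()]).
#' @export
predict_target <- function(train, query_terms = NULL, query_id = NA_character_,
                           backend = c("ontology", "interaction"),
                           g = NULL, interactions = NULL, seed = 1L) {
  backend <- match.arg(backend)
  neighbors <- if (backend == "ontology") {
    if (is.null(g)) stop("ontology backend needs the term graph `g`",
                         call. = FALSE)
    nearest_by_ontology(g, query_terms, train)
  } else {
    if (is.null(interactions) || is.na(query_id)) {
      stop("interaction backend needs `interactions` and `query_id`",
           call. = FALSE)
    }
    nearest_by_interaction(interactions, query_id, train)
  }
  vote(neighbors, seed = seed, drug_id = query_id)
}

#' @rdname tidy.target_eval
#' @export
tidy.target_prediction <- function(x, ...) {
  tibble::tibble(
    group = names(x$votes),
    votes = as.integer(x$votes),
    predicted = !is.na(x$predicted_group) & names(x$votes) == x$predicted_group
  )
}
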