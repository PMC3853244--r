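# Independent oracles and fixture builders used across the suite.
# Nothing here calls the package's graph/search code paths: distances come
# from a Floyd-Warshall recursion on an adjacency matrix, and neighbor sets
# from exhaustive scans over that matrix.

# All-pairs shortest-path hop counts by Floyd-Warshall on an adjacency
# matrix (dimnames = node ids). Inf where unreachable, 0 on the diagonal.
oracle_all_pairs <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# Mean hop distance over the full cross product of two term sets, from the
# oracle matrix; NA if any pair is unreachable.
oracle_q <- function(d, terms_a, terms_b) {
  sub <- d[terms_a, terms_b, drop = FALSE]
  if (any(is.infinite(sub))) NA_real_ else mean(sub)
}

# Exhaustive argmin scan for the ontology backend: every training drug with
# a defined Q equal (as an exact fraction) to the minimum.
oracle_nearest_q <- function(d, query_terms, train) {
  num <- den <- numeric(nrow(train))
  ok <- logical(nrow(train))
  for (i in seq_len(nrow(train))) {
    sub <- d[query_terms, train$terms[[i]], drop = FALSE]
    den[i] <- length(sub)
    ok[i] <- all(is.finite(sub))
    num[i] <- if (ok[i]) sum(sub) else NA_real_
  }
  if (!any(ok)) return(character())
  ratio_min <- NULL
  for (i in which(ok)) {
    if (is.null(ratio_min) ||
        num[i] * ratio_min[2] < ratio_min[1] * den[i]) {
      ratio_min <- c(num[i], den[i])
    }
  }
  train$drug_id[ok & num * ratio_min[2] == ratio_min[1] * den]
}

# Exhaustive argmax scan for the interaction backend; empty when the best
# score is 0 (non-interaction everywhere).
oracle_nearest_i <- function(interactions, query_id, train) {
  s <- vapply(train$drug_id, function(id) {
    hit <- (interactions$chemical_a == pmin(query_id, id) &
              interactions$chemical_b == pmax(query_id, id))
    if (any(hit)) max(interactions$score[hit]) else 0
  }, numeric(1))
  if (max(s) == 0) character() else train$drug_id[s == max(s)]
}

# Random connected undirected graph as (OBO text, adjacency matrix).
# A random spanning tree guarantees connectivity; extra edges are sprinkled
# with probability p_extra.
random_graph_fixture <- function(n, p_extra = 0.08, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("T:%03d", seq_len(n))
    adj <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in 2:n) {
      j <- sample.int(i - 1L, 1L)
      adj[i, j] <- adj[j, i] <- 1L
    }
    extra <- which(upper.tri(adj) & adj == 0L & stats::runif(n * n) < p_extra)
    adj[extra] <- 1L
    adj <- pmax(adj, t(adj))

    obo <- character()
    for (i in seq_len(n)) {
      parents <- ids[which(adj[i, ] > 0 & seq_len(n) < i)]
      obo <- c(obo, "[Term]", paste0("id: ", ids[i]),
               paste0("is_a: ", parents), "")
    }
    list(ids = ids, adj = adj, obo = obo)
  })
}

# Random drug table over the node ids of a graph fixture.
random_drug_table <- function(ids, n_drugs, groups, max_terms = 4, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      drug_id = sprintf("DR%03d", seq_len(n_drugs)),
      group = sample(groups, n_drugs, replace = TRUE),
      terms = lapply(seq_len(n_drugs), function(i) {
        sample(ids, sample.int(max_terms, 1L))
      })
    )
  })
}

# Tiny chain ontology A - B - C - D used by several unit tests.
chain_graph <- function(n = 4) {
  ids <- LETTERS[seq_len(n)]
  obo <- c("[Term]", paste0("id: ", ids[1]))
  for (i in 2:n) {
    obo <- c(obo, "", "[Term]", paste0("id: ", ids[i]),
             paste0("is_a: ", ids[i - 1]))
  }
  parse_obo(obo)
}

# Drug table with two identical-term twins per group: every held-out drug's
# twin sits at Q = 0, forcing a correct jackknife prediction.
twin_drug_table <- function(branches, groups) {
  rows <- lapply(seq_along(groups), function(b) {
    pool <- branches$term_id[branches$group == groups[b]]
    tibble::tibble(
      drug_id = sprintf("TW%d%d", b, 1:2),
      group = groups[b],
      terms = rep(list(pool[1:2]), 2)
    )
  })
  dplyr::bind_rows(rows)
}
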