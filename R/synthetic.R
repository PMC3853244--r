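#' Configuration for the synthetic benchmark generator
#'
#' Bundles the knobs of the synthetic benchmark: a rooted multi-branch term
#' ontology, a labeled drug table whose annotation clusters by class, and a
#' sparse symmetric interaction-score table. Defaults describe the standard
#' desk-scale benchmark used throughout the package's tests: 4 target
#' groups with 50 drugs each, ontology branches of 12 terms at each of 3
#' levels, 2 terms per drug, 5% of drugs carrying one off-branch (noise)
#' term, and within-/cross-group interaction rates of 0.30/0.05.
#'
#' @param n_groups Number of target groups (= ontology branches).
#' @param terms_per_branch Terms per level within a branch.
#' @param branch_depth Number of levels per branch.
#' @param drugs_per_group Drugs generated per group.
#' @param terms_per_drug Ontology terms annotated to each drug.
#' @param cross_branch_noise Fraction of drugs whose term set has one term
#'   replaced by a term from another group's branch.
#' @param interaction_within_group_rate,interaction_cross_group_rate
#'   Probability that a within-group (cross-group) drug pair receives a
#'   positive interaction score.
#' @param groups Group labels; defaults to [target_groups()] (recycled or
#'   truncated to `n_groups`).
#' @param seed Integer seed; every generator is deterministic per seed.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_groups = 4L,
                         terms_per_branch = 12L,
                         branch_depth = 3L,
                         drugs_per_group = 50L,
                         terms_per_drug = 2L,
                         cross_branch_noise = 0.05,
                         interaction_within_group_rate = 0.30,
                         interaction_cross_group_rate = 0.05,
                         groups = NULL,
                         seed = 7L) {
  stopifnot(
    n_groups >= 1, terms_per_branch >= 1, branch_depth >= 1,
    drugs_per_group >= 1, terms_per_drug >= 1,
    terms_per_drug <= terms_per_branch * branch_depth,
    cross_branch_noise >= 0, cross_branch_noise <= 1,
    interaction_within_group_rate >= 0, interaction_within_group_rate <= 1,
    interaction_cross_group_rate >= 0, interaction_cross_group_rate <= 1
  )
  if (is.null(groups)) {
    groups <- if (n_groups <= length(target_groups())) {
      target_groups()[seq_len(n_groups)]
    } else {
      c(target_groups(),
        sprintf("Group %d", seq_len(n_groups - length(target_groups()))))
    }
  }
  stopifnot(length(groups) == n_groups, !anyDuplicated(groups))
  structure(
    list(
      n_groups = as.integer(n_groups),
      terms_per_branch = as.integer(terms_per_branch),
      branch_depth = as.integer(branch_depth),
      drugs_per_group = as.integer(drugs_per_group),
      terms_per_drug = as.integer(terms_per_drug),
      cross_branch_noise = cross_branch_noise,
      interaction_within_group_rate = interaction_within_group_rate,
      interaction_cross_group_rate = interaction_cross_group_rate,
      groups = groups,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

synth_term_id <- function(i) sprintf("SYN:%07d", i)

#' Generate a synthetic ontology
#'
#' Builds a rooted term DAG with one branch per target group, serialized as
#' valid OBO 1.2 text. Each branch has `branch_depth` levels of
#' `terms_per_branch` terms; the first term of each level is that level's
#' hub. The level-1 hub attaches to the root, deeper hubs attach to the hub
#' above, and every other term attaches to its level's hub, so branches
#' meet only at the root: within-branch term distances are bounded by the
#' spine length while cross-branch distances grow with the levels of both
#' endpoints. At depth >= 2 (and >= 2 terms per level) each branch also
#' gains one `relationship:`-typed shortcut edge between its deepest
#' non-hub term and a level-1 non-hub term, exercising non-is_a edges
#' without connecting branches.
#'
#' The construction is purely structural — no random choices — so the
#' output is byte-identical for a given configuration.
#'
#' @param cfg A [synth_config()].
#' @return A list with `obo` (character vector of OBO lines), `edges` (the
#'   ground-truth edge tibble: `from`, `to`, `relation`), and `branches` (a
#'   tibble `term_id`, `group` mapping every non-root term to its branch;
#'   the root belongs to no branch).
#' @export
generate_synthetic_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  root <- synth_term_id(0L)
  per_branch <- cfg$terms_per_branch * cfg$branch_depth

  edges <- list()
  branches <- list()
  for (b in seq_len(cfg$n_groups)) {
    base <- (b - 1L) * per_branch
    tid <- function(level, j) {
      synth_term_id(base + (level - 1L) * cfg$terms_per_branch + j)
    }
    for (level in seq_len(cfg$branch_depth)) {
      hub <- tid(level, 1L)
      parent_hub <- if (level == 1L) root else tid(level - 1L, 1L)
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = hub, to = parent_hub, relation = "is_a")
      if (cfg$terms_per_branch > 1L) {
        others <- vapply(2:cfg$terms_per_branch, function(j) tid(level, j),
                         character(1))
        edges[[length(edges) + 1L]] <-
          tibble::tibble(from = others, to = hub, relation = "is_a")
      }
    }
    if (cfg$branch_depth >= 2L && cfg$terms_per_branch >= 2L) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        from = tid(cfg$branch_depth, cfg$terms_per_branch),
        to = tid(1L, cfg$terms_per_branch),
        relation = "has_functional_parent"
      )
    }
    branches[[b]] <- tibble::tibble(
      term_id = synth_term_id(base + seq_len(per_branch)),
      group = cfg$groups[b]
    )
  }
  edges <- dplyr::bind_rows(edges)
  branches <- dplyr::bind_rows(branches)

  obo <- c(
    "format-version: 1.2",
    "ontology: synthetic-benchmark",
    "",
    "[Term]",
    paste0("id: ", root),
    "name: synthetic root"
  )
  all_terms <- branches$term_id
  by_child <- split(edges, edges$from)
  for (t in all_terms) {
    stanza <- c("", "[Term]", paste0("id: ", t),
                paste0("name: synthetic term ", t))
    e <- by_child[[t]]
    if (!is.null(e)) {
      is_a <- e$to[e$relation == "is_a"]
      rel <- e[e$relation != "is_a", ]
      stanza <- c(stanza,
                  paste0("is_a: ", is_a),
                  if (nrow(rel) > 0L) {
                    paste0("relationship: ", rel$relation, " ", rel$to)
                  })
    }
    obo <- c(obo, stanza)
  }
  list(obo = obo, edges = edges, branches = branches)
}

#' Generate a synthetic labeled drug table
#'
#' Draws `drugs_per_group` drugs for each group, annotating each with
#' `terms_per_drug` distinct terms sampled uniformly from the group's own
#' ontology branch. A `cross_branch_noise` fraction of drugs (rounded to
#' the nearest count per group) has one term replaced by a term drawn from
#' a different group's branch, emulating annotation that does not respect
#' class boundaries. Deterministic per `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param branches The `branches` map from [generate_synthetic_ontology()].
#' @return A drug table tibble (`drug_id`, `group`, `terms`).
#' @export
generate_synthetic_drugs <- function(cfg, branches) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    rows <- purrr::imap(cfg$groups, function(grp, b) {
      pool <- branches$term_id[branches$group == grp]
      off_pool <- branches$term_id[branches$group != grp]
      n_noisy <- floor(cfg$cross_branch_noise * cfg$drugs_per_group + 0.5)
      purrr::map(seq_len(cfg$drugs_per_group), function(k) {
        terms <- sample(pool, cfg$terms_per_drug)
        if (k <= n_noisy && length(off_pool) > 0L) {
          terms[1L] <- sample(off_pool, 1L)
        }
        tibble::tibble(
          drug_id = sprintf("D%02d%03d", b, k),
          group = grp,
          terms = list(sort(terms))
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Generate a synthetic interaction-score table
#'
#' Assigns positive STITCH-style integer scores to drug pairs: each
#' within-group pair is interactive with probability
#' `interaction_within_group_rate` and each cross-group pair with
#' probability `interaction_cross_group_rate`. Interactive within-group
#' pairs draw scores uniformly from 500–999 and cross-group pairs from
#' 1–499, reflecting the premise that compounds sharing functional features
#' interact more strongly. Non-interactive pairs are simply absent (score
#' 0). The table is canonical/symmetric. Deterministic per `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param drugs A drug table tibble.
#' @return An interaction table tibble (`chemical_a`, `chemical_b`,
#'   `score`), as produced by [read_interactions()].
#' @export
generate_synthetic_interactions <- function(cfg, drugs) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- nrow(drugs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- drugs$group[pairs[, 1]] == drugs$group[pairs[, 2]]
  withr::with_seed(cfg$seed + 1L, {
    rate <- ifelse(same, cfg$interaction_within_group_rate,
                   cfg$interaction_cross_group_rate)
    keep <- stats::runif(nrow(pairs)) < rate
    score <- ifelse(same[keep],
                    sample(500:999, sum(keep), replace = TRUE),
                    sample(1:499, sum(keep), replace = TRUE))
    a <- drugs$drug_id[pairs[keep, 1]]
    b <- drugs$drug_id[pairs[keep, 2]]
    tibble::tibble(
      chemical_a = pmin(a, b),
      chemical_b = pmax(a, b),
      score = as.numeric(score)
    ) |>
      dplyr::arrange(.data$chemical_a, .data$chemical_b)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper running all three generators and parsing the
#' ontology, so downstream code gets ready-to-use objects.
#'
#' @param cfg A [synth_config()].
#' @return A list with `graph` (parsed [ontology_graph][parse_obo]), `obo`
#'   (OBO text lines), `edges`, `branches`, `drugs` (drug table) and
#'   `interactions` (interaction table).
#' @examples
#' bench <- generate_benchmark(synth_config(drugs_per_group = 5))
#' bench$graph
#' group_counts(bench$drugs)
#' @export
generate_benchmark <- function(cfg = synth_config()) {
  onto <- generate_synthetic_ontology(cfg)
  drugs <- generate_synthetic_drugs(cfg, onto$branches)
  interactions <- generate_synthetic_interactions(cfg, drugs)
  list(
    graph = parse_obo(onto$obo),
    obo = onto$obo,
    edges = onto$edges,
    branches = onto$branches,
    drugs = drugs,
    interactions = interactions
  )
}
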