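test_that("a query sharing its exact terms with one training drug gets that drug as sole neighbor", {
  bench <- generate_benchmark(synth_config(drugs_per_group = 5, seed = 3))
  train <- bench$drugs
  # distinct singleton annotation per drug: Q = 0 occurs only against the
  # drug whose term set equals the query's
  train$terms <- as.list(bench$branches$term_id[seq_len(nrow(train))])
  nb <- nearest_by_ontology(bench$graph, train$terms[[7]], train)
  expect_equal(nb$members$drug_id, train$drug_id[7])
  expect_equal(nb$members$score, 0)
  expect_equal(nb$criterion, "min_Q")
})

test_that("ontology neighbor sets equal the exhaustive-scan argmin on random instances", {
  groups <- target_groups()
  for (seed in 1:30) {
    fx <- random_graph_fixture(n = 25 + (seed %% 3) * 10, seed = seed)
    g <- parse_obo(fx$obo)
    d_oracle <- oracle_all_pairs(fx$adj)
    train <- random_drug_table(fx$ids, n_drugs = 10 + (seed %% 4) * 10,
                               groups = groups, seed = seed + 100)
    query <- withr::with_seed(seed, sample(fx$ids, sample.int(3, 1)))
    nb <- nearest_by_ontology(g, query, train)
    expect_setequal(nb$members$drug_id, oracle_nearest_q(d_oracle, query, train))
    # all members share the exact minimum as a fraction
    expect_equal(dplyr::n_distinct(nb$members$numerator /
                                     nb$members$denominator), 1)
  }
})

test_that("a disconnected query yields a no-prediction neighbor set", {
  g <- parse_obo(c("[Term]", "id: A", "", "[Term]", "id: B", "is_a: A",
                   "", "[Term]", "id: LONE"))
  train <- tibble::tibble(
    drug_id = c("D1", "D2"),
    group = c("Enzymes", "Ion Channels"),
    terms = list("A", "B")
  )
  nb <- nearest_by_ontology(g, "LONE", train)
  expect_equal(nrow(nb$members), 0)
  p <- vote(nb, seed = 1, drug_id = "Q")
  expect_true(is.na(p$predicted_group))
  expect_false(p$tie_broken)
})

test_that("interaction neighbors take the positive maximum and abstain at all-zero", {
  train <- tibble::tibble(
    drug_id = c("D1", "D2", "D3"),
    group = c("Enzymes", "Ion Channels", "Enzymes"),
    terms = list("A", "B", "C")
  )
  tab <- read_interactions(c("chemical1\tchemical2\tcombined_score",
                             "Q\tD2\t400"))
  nb <- nearest_by_interaction(tab, "Q", train)
  expect_equal(nb$members$drug_id, "D2")
  expect_equal(nb$members$score, 400)
  expect_equal(nb$criterion, "max_I")

  # noninteractive everywhere: I = 0 carries no evidence
  none <- nearest_by_interaction(tab, "OTHER", train)
  expect_equal(nrow(none$members), 0)
})

test_that("interaction neighbor sets equal the exhaustive-scan argmax on random sparse tables", {
  groups <- target_groups()
  for (seed in 1:20) {
    train <- random_drug_table(sprintf("T:%03d", 1:10),
                               n_drugs = 15 + seed, groups = groups,
                               seed = seed)
    ids <- c("QRY", train$drug_id)
    tab <- withr::with_seed(seed, {
      pairs <- t(utils::combn(ids, 2))
      keep <- stats::runif(nrow(pairs)) < 0.2
      tibble::tibble(
        chemical_a = pmin(pairs[keep, 1], pairs[keep, 2]),
        chemical_b = pmax(pairs[keep, 1], pairs[keep, 2]),
        score = sample(1:1000, sum(keep), replace = TRUE)
      )
    })
    nb <- nearest_by_interaction(tab, "QRY", train)
    expect_setequal(nb$members$drug_id, oracle_nearest_i(tab, "QRY", train))
  }
})

test_that("voting tallies groups, picks the mode, and reports tie-breaking", {
  nb <- as_neighbor_set(tibble::tibble(
    drug_id = sprintf("D%d", 1:5),
    group = c(rep("Enzymes", 3), rep("Ion Channels", 2))
  ))
  p <- vote(nb, seed = 1)
  expect_equal(p$predicted_group, "Enzymes")
  expect_equal(unname(p$votes[c("Enzymes", "Ion Channels")]), c(3L, 2L))
  expect_equal(sum(p$votes), nrow(nb$members))
  expect_false(p$tie_broken)
})

test_that("tied votes break reproducibly per seed and uniformly across seeds", {
  nb <- as_neighbor_set(tibble::tibble(
    drug_id = c("D1", "D2"),
    group = c("Enzymes", "Ion Channels")
  ))
  p1 <- vote(nb, seed = 17)
  expect_true(p1$tie_broken)
  expect_identical(p1$predicted_group, vote(nb, seed = 17)$predicted_group)

  picks <- vapply(1:2000, function(s) vote(nb, seed = s)$predicted_group,
                  character(1))
  frac <- mean(picks == "Enzymes")
  # binomial: sd of the fraction at n = 2000 is ~0.011; allow 4 sd
  expect_gt(frac, 0.5 - 0.045)
  expect_lt(frac, 0.5 + 0.045)
})

test_that("end-to-end prediction recovers the generating class on branch-structured data", {
  bench <- generate_benchmark(synth_config(seed = 7))
  parts <- split_train_test(bench$drugs, 0.2, seed = 7)
  preds <- vapply(seq_len(nrow(parts$test)), function(i) {
    predict_target(parts$train, query_terms = parts$test$terms[[i]],
                   query_id = parts$test$drug_id[i],
                   backend = "ontology", g = bench$graph,
                   seed = i)$predicted_group
  }, character(1))
  expect_gte(mean(preds == parts$test$group), 0.90)
})

test_that("prediction is invariant to training-set row order except through seeded ties", {
  bench <- generate_benchmark(synth_config(drugs_per_group = 8, seed = 9))
  train <- bench$drugs
  shuffled <- train[withr::with_seed(1, sample.int(nrow(train))), ]
  for (i in c(2, 13, 27)) {
    p1 <- predict_target(train[-i, ], query_terms = train$terms[[i]],
                         backend = "ontology", g = bench$graph, seed = 5)
    p2 <- predict_target(shuffled[shuffled$drug_id != train$drug_id[i], ],
                         query_terms = train$terms[[i]],
                         backend = "ontology", g = bench$graph, seed = 5)
    expect_equal(sort(p1$neighbors$members$drug_id),
                 sort(p2$neighbors$members$drug_id))
    expect_equal(p1$votes[sort(names(p1$votes))],
                 p2$votes[sort(names(p2$votes))])
    if (!p1$tie_broken) expect_identical(p1$predicted_group, p2$predicted_group)
  }
})

test_that("a training twin of the query forces its group to win or tie", {
  bench <- generate_benchmark(synth_config(drugs_per_group = 6, seed = 13))
  train <- bench$drugs
  query_terms <- train$terms[[1]]
  # plant a twin with the query's exact terms under a different group
  twin <- tibble::tibble(drug_id = "TWIN", group = "Nuclear Receptors",
                         terms = list(query_terms))
  train2 <- dplyr::bind_rows(train[-1, ], twin)
  p <- predict_target(train2, query_terms = query_terms,
                      backend = "ontology", g = bench$graph, seed = 1)
  expect_true("TWIN" %in% p$neighbors$members$drug_id)
  expect_equal(max(p$votes), p$votes[["Nuclear Receptors"]])
})

test_that("tidy on a prediction exposes the vote tally", {
  nb <- as_neighbor_set(tibble::tibble(
    drug_id = sprintf("D%d", 1:3),
    group = c("Enzymes", "Enzymes", "Ion Channels")
  ))
  td <- tidy(vote(nb, seed = 1))
  expect_equal(td$votes[td$group == "Enzymes"], 2L)
  expect_true(td$predicted[td$group == "Enzymes"])
})
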