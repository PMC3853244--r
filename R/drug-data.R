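#' Default target-group labels
#'
#' The four KEGG target-protein groups used throughout: G Protein-coupled
#' Receptors, Nuclear Receptors, Ion Channels and Enzymes. (A fifth KEGG
#' group, Cytokine Receptors, is conventionally excluded from benchmarks of
#' this kind for having too few annotated drugs to model.)
#'
#' @return A character vector of group labels.
#' @export
target_groups <- function() {
  c("G Protein-coupled Receptors", "Nuclear Receptors",
    "Ion Channels", "Enzymes")
}

#' Read a labeled drug table
#'
#' Reads a tab-separated drug table with header columns `drug_id`, `group`
#' and `terms` (ontology term ids joined by semicolons) and validates it:
#' drug ids must be unique, every group label must belong to `groups`, and
#' every drug must carry at least one ontology term (drugs without ontology
#' annotation cannot be scored and are excluded upstream by
#' [apply_benchmark_filters()]).
#'
#' @param x Path to a TSV file, or a character vector of TSV text lines.
#' @param groups Allowed group labels. Defaults to [target_groups()].
#'
#' @return A tibble with columns `drug_id` (character), `group` (character)
#'   and `terms` (list of character vectors), one row per drug.
#' @seealso [write_drug_table()], [split_train_test()]
#' @export
read_drug_table <- function(x, groups = target_groups()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty drug table", call. = FALSE)

  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("drug_id", "group", "terms")
  if (!all(required %in% header)) {
    stop("drug table header must contain columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  get_col <- function(name) {
    i <- match(name, header)
    vapply(fields, function(f) if (length(f) >= i) f[i] else "", character(1))
  }
  drugs <- tibble::tibble(
    drug_id = trimws(get_col("drug_id")),
    group   = trimws(get_col("group")),
    terms   = purrr::map(get_col("terms"), parse_term_list)
  )
  validate_drug_table(drugs, groups = groups)
}

parse_term_list <- function(x) {
  t <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  t[nzchar(t)]
}

validate_drug_table <- function(drugs, groups = target_groups()) {
  dup <- drugs$drug_id[duplicated(drugs$drug_id)]
  if (length(dup) > 0L) {
    stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- !drugs$group %in% groups
  if (any(bad_group)) {
    stop("unknown group label at row(s) ",
         paste(which(bad_group), collapse = ", "), ": ",
         paste(unique(drugs$group[bad_group]), collapse = ", "),
         call. = FALSE)
  }
  no_terms <- lengths(drugs$terms) == 0L
  if (any(no_terms)) {
    stop("drug(s) without ontology terms: ",
         paste(drugs$drug_id[no_terms], collapse = ", "), call. = FALSE)
  }
  drugs
}

#' Write a drug table to TSV
#'
#' Inverse of [read_drug_table()]: columns `drug_id`, `group`, `terms` with
#' terms semicolon-joined. Reading the written file back reproduces the
#' input exactly.
#'
#' @param drugs A drug table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(drugs, path) {
  out <- data.frame(
    drug_id = drugs$drug_id,
    group = drugs$group,
    terms = vapply(drugs$terms, paste, character(1), collapse = ";")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group counts of a drug table
#'
#' @param drugs A drug table tibble.
#' @return A tibble with columns `group` and `n`.
#' @export
group_counts <- function(drugs) {
  dplyr::count(drugs, .data$group, name = "n")
}

#' Apply the benchmark-construction filters to a raw drug list
#'
#' Benchmark datasets for target-group prediction are built by screening a
#' raw drug list with three rules, applied in order: (1) drugs without any
#' ontology annotation are excluded; (2) drugs assigned to more than one
#' target group are excluded; (3) drugs in explicitly excluded groups (for
#' example a group too small to model) are excluded. Filtering is total:
#' every record either survives or is counted against exactly one rule.
#'
#' @param raw A tibble with columns `drug_id` (character), `groups` (list of
#'   character vectors: all groups the drug maps to) and `terms` (list of
#'   character vectors).
#' @param excluded_groups Group labels removed by rule 3. Default none.
#'
#' @return A list with `drugs` (a validated drug table of survivors, whose
#'   single group is unlisted from `groups`) and `rejections` (a tibble with
#'   columns `filter` = `no_terms` / `multi_group` / `excluded_group` and
#'   `n`, the count each rule removed).
#' @export
apply_benchmark_filters <- function(raw, excluded_groups = character()) {
  stopifnot(all(c("drug_id", "groups", "terms") %in% names(raw)))
  n_terms <- lengths(raw$terms)
  n_groups <- lengths(raw$groups)

  f1 <- n_terms == 0L
  f2 <- !f1 & n_groups != 1L
  single <- vapply(raw$groups, function(g) if (length(g) == 1L) g else NA_character_,
                   character(1))
  f3 <- !f1 & !f2 & single %in% excluded_groups
  keep <- !(f1 | f2 | f3)

  drugs <- tibble::tibble(
    drug_id = raw$drug_id[keep],
    group = single[keep],
    terms = raw$terms[keep]
  )
  list(
    drugs = drugs,
    rejections = tibble::tibble(
      filter = c("no_terms", "multi_group", "excluded_group"),
      n = c(sum(f1), sum(f2), sum(f3))
    )
  )
}

#' Split a drug table into training and test partitions
#'
#' Draws `round(test_fraction * n)` drugs (round half up) uniformly at random
#' without replacement as the test set; the remainder is the training set.
#' The same seed always reproduces the same partition. Sampling is
#' unstratified: group proportions in the test set vary by draw.
#'
#' @param drugs A drug table tibble.
#' @param test_fraction Fraction of records for the test set, in (0, 1).
#' @param seed Integer seed fixing the draw.
#'
#' @return A list with drug-table tibbles `train` and `test`.
#' @examples
#' \dontrun{
#' parts <- split_train_test(benchmark, test_fraction = 0.10, seed = 1)
#' nrow(parts$test)  # 10% of the benchmark, round half up
#' }
#' @export
split_train_test <- function(drugs, test_fraction, seed) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(drugs)
  n_test <- floor(test_fraction * n + 0.5)
  idx <- withr::with_seed(seed, sample.int(n, n_test))
  list(
    train = drugs[-idx, , drop = FALSE],
    test = drugs[idx, , drop = FALSE]
  )
}

#' Read a chemical-chemical interaction table
#'
#' Reads a STITCH-style tab-separated interaction file: two chemical-id
#' columns followed by one or more score columns (by convention the last,
#' `combined_score`, integrates the individual evidence channels). Two
#' chemicals are interactive if and only if the designated score is strictly
#' positive: rows with score <= 0 are dropped, so an absent pair means an
#' interaction score of 0. Scores are stored once per unordered pair; when a
#' file carries both orientations (or repeats a pair) with conflicting
#' scores, the larger is kept with a warning.
#'
#' @param x Path to a TSV file, or a character vector of TSV text lines.
#'   The first two columns are taken as the chemical ids.
#' @param score_column Name of the score column defining interactivity.
#'
#' @return An interaction table: a tibble with columns `chemical_a`,
#'   `chemical_b` (canonical order, `chemical_a < chemical_b`) and `score`
#'   (positive numeric).
#' @seealso [interaction_score()], [write_interactions()]
#' @export
read_interactions <- function(x, score_column = "combined_score") {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty interaction table", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  si <- match(score_column, header)
  if (is.na(si)) {
    stop("score column '", score_column, "' not found; columns are: ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  score_raw <- vapply(fields, `[`, character(1), si)
  score <- suppressWarnings(as.numeric(score_raw))
  if (anyNA(score)) {
    stop("non-numeric score at row(s) ",
         paste(which(is.na(score)), collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(
    chemical_a = pmin(vapply(fields, `[`, character(1), 1L),
                      vapply(fields, `[`, character(1), 2L)),
    chemical_b = pmax(vapply(fields, `[`, character(1), 1L),
                      vapply(fields, `[`, character(1), 2L)),
    score = score
  ) |>
    dplyr::filter(.data$score > 0)

  dup <- tab |>
    dplyr::group_by(.data$chemical_a, .data$chemical_b) |>
    dplyr::filter(dplyr::n() > 1L, dplyr::n_distinct(.data$score) > 1L) |>
    dplyr::ungroup()
  if (nrow(dup) > 0L) {
    warning("conflicting duplicate interaction rows for ",
            dplyr::n_distinct(paste(dup$chemical_a, dup$chemical_b)),
            " pair(s); keeping the larger score", call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$chemical_a, .data$chemical_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Look up interaction scores
#'
#' Symmetric lookup into an interaction table; pairs not present in the
#' table are non-interactive and score 0. `a` and `b` are recycled to a
#' common length.
#'
#' @param interactions An interaction table from [read_interactions()].
#' @param a,b Chemical ids.
#' @return A numeric vector of scores (0 for absent pairs).
#' @export
interaction_score <- function(interactions, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(interactions$chemical_a, interactions$chemical_b, sep = "\r")
  s <- interactions$score[match(key, tab_key)]
  s[is.na(s)] <- 0
  s
}

#' Write an interaction table to TSV
#'
#' Writes the canonical one-row-per-unordered-pair form with a
#' STITCH-style header (`chemical1`, `chemical2`, `combined_score`);
#' [read_interactions()] on the output reproduces the table exactly.
#'
#' @param interactions An interaction table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  out <- data.frame(
    chemical1 = interactions$chemical_a,
    chemical2 = interactions$chemical_b,
    combined_score = interactions$score
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
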