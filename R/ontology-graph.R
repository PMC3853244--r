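#' Parse an OBO ontology into an undirected term graph
#'
#' Reads OBO 1.2 flat-file text and builds the term graph used for all
#' distance computations: every `[Term]` stanza contributes a node, and every
#' `is_a:` or `relationship: <type> <target>` line contributes one undirected
#' edge between the stanza's term and the referenced term. Edge direction is
#' discarded because the compound-pair score built on these distances is
#' symmetric. Parallel assertions between the same unordered pair of terms
#' (for example an `is_a` plus a `relationship`) collapse to a single edge;
#' self-referential assertions are dropped. Terms referenced on an edge line
#' but lacking a stanza of their own still become nodes.
#'
#' Only `[Term]` stanzas and their `id:`, `is_a:`, `relationship:` and
#' `is_obsolete:` lines are interpreted; trailing `! comment` text after a
#' target id is stripped; every other line (including `[Typedef]` stanzas) is
#' ignored.
#'
#' @param x Path to an OBO file, or a character vector of OBO text lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @param drop_obsolete Drop terms flagged `is_obsolete: true`, together with
#'   their edges? Default `FALSE`: obsolete terms stay in the graph.
#'
#' @return An `ontology_graph` object: a list with elements `graph` (the
#'   underlying [igraph::igraph] object), `edges` (a tibble of the
#'   deduplicated edges with columns `from`, `to`, `relation`), `n_terms` and
#'   `n_edges`.
#'
#' @examples
#' obo <- c(
#'   "[Term]", "id: X:1", "",
#'   "[Term]", "id: X:2", "is_a: X:1 ! parent"
#' )
#' g <- parse_obo(obo)
#' g$n_terms
#' term_distance(g, "X:1", "X:2")
#' @export
parse_obo <- function(x, drop_obsolete = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  stanzas <- parse_obo_stanzas(lines)
  build_ontology_graph(stanzas, drop_obsolete = drop_obsolete)
}

# Split OBO lines into [Term] stanzas; returns a list of records with
# id, line (stanza start), parents (edge targets), relations, obsolete.
parse_obo_stanzas <- function(lines) {
  lines <- sub("\r$", "", lines)
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0L) {
    return(list())
  }
  heads <- which(grepl("^\\[.+\\]\\s*$", trimws(lines)))
  ends <- vapply(starts, function(s) {
    nxt <- heads[heads > s]
    if (length(nxt) == 0L) length(lines) else min(nxt) - 1L
  }, integer(1))

  purrr::map2(starts, ends, function(s, e) {
    body <- lines[seq(s + 1L, length.out = max(0L, e - s))]
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]*:", "", body))

    id <- vals[tags == "id"]
    if (length(id) == 0L || !nzchar(id[1])) {
      stop("OBO [Term] stanza starting at line ", s, " has no id: line",
           call. = FALSE)
    }

    is_a <- strip_obo_comment(vals[tags == "is_a"])
    rel_raw <- strip_obo_comment(vals[tags == "relationship"])
    rel_parts <- strsplit(rel_raw, "\\s+")
    rel_type <- vapply(rel_parts, function(p) p[1], character(1))
    rel_target <- vapply(rel_parts,
                         function(p) if (length(p) >= 2L) p[2] else NA_character_,
                         character(1))

    obsolete <- any(tolower(vals[tags == "is_obsolete"]) == "true")

    list(
      id = id[1],
      targets = c(is_a, rel_target[!is.na(rel_target)]),
      relations = c(rep("is_a", length(is_a)), rel_type[!is.na(rel_target)]),
      obsolete = obsolete
    )
  })
}

strip_obo_comment <- function(x) {
  trimws(sub("!.*$", "", x))
}

build_ontology_graph <- function(stanzas, drop_obsolete = FALSE) {
  ids <- vapply(stanzas, `[[`, character(1), "id")
  obsolete_ids <- ids[vapply(stanzas, `[[`, logical(1), "obsolete")]

  edges <- purrr::map_dfr(stanzas, function(st) {
    if (length(st$targets) == 0L) {
      return(tibble::tibble(from = character(), to = character(),
                            relation = character()))
    }
    tibble::tibble(from = st$id, to = st$targets, relation = st$relations)
  })
  if (ncol(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            relation = character())
  }

  if (drop_obsolete && length(obsolete_ids) > 0L) {
    ids <- setdiff(ids, obsolete_ids)
    edges <- dplyr::filter(edges,
                           !.data$from %in% obsolete_ids,
                           !.data$to %in% obsolete_ids)
  }

  # canonical unordered pair; drop self-loops; first relation label wins
  if (nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::filter(.data$from != .data$to) |>
      dplyr::mutate(
        a = pmin(.data$from, .data$to),
        b = pmax(.data$from, .data$to)
      ) |>
      dplyr::distinct(.data$a, .data$b, .keep_all = TRUE) |>
      dplyr::transmute(from = .data$a, to = .data$b,
                       relation = .data$relation)
  }

  nodes <- unique(c(ids, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )

  structure(
    list(
      graph = g,
      edges = edges,
      n_terms = length(nodes),
      n_edges = nrow(edges),
      obsolete = intersect(obsolete_ids, nodes)
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", x$n_terms, " terms, ", x$n_edges,
      " undirected edges", sep = "")
  if (length(x$obsolete) > 0L) {
    cat(" (", length(x$obsolete), " obsolete terms retained)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Shortest-path hop distance between ontology terms
#'
#' The unweighted shortest-path length, in hops, between two terms of the
#' undirected term graph. `Inf` is returned for pairs in different connected
#' components ("unreachable"); the distance from a term to itself is 0.
#' `t1` and `t2` may be vectors, recycled to a common length, in which case
#' the distances are computed pairwise.
#'
#' @param g An [ontology_graph][parse_obo].
#' @param t1,t2 Term identifiers (character).
#'
#' @return A numeric vector of hop counts (`Inf` where unreachable).
#' @examples
#' g <- parse_obo(c("[Term]", "id: A", "[Term]", "id: B", "is_a: A",
#'                  "[Term]", "id: C", "is_a: B"))
#' term_distance(g, "A", "C")
#' @export
term_distance <- function(g, t1, t2) {
  stopifnot(inherits(g, "ontology_graph"))
  assert_terms_known(g, c(t1, t2))
  n <- max(length(t1), length(t2))
  t1 <- rep_len(t1, n)
  t2 <- rep_len(t2, n)
  u1 <- unique(t1)
  d <- igraph::distances(g$graph, v = u1, to = unique(t2))
  as.numeric(d[cbind(match(t1, u1), match(t2, colnames(d)))])
}

assert_terms_known <- function(g, terms) {
  missing <- setdiff(unique(terms), igraph::V(g$graph)$name)
  if (length(missing) > 0L) {
    stop("unknown ontology term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Distance matrix between two term vectors (rows = a, cols = b), hop counts.
term_distance_matrix <- function(g, terms_a, terms_b) {
  assert_terms_known(g, c(terms_a, terms_b))
  d <- igraph::distances(g$graph, v = unique(terms_a), to = unique(terms_b))
  d[match(terms_a, rownames(d)), match(terms_b, colnames(d)), drop = FALSE]
}

#' Write an ontology graph's edge list
#'
#' Serializes the deduplicated undirected edge list as tab-separated text
#' (columns `from`, `to`, `relation`), the exchange format used by the
#' command-line `build-graph` entry point.
#'
#' @param g An [ontology_graph][parse_obo].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(g, path) {
  stopifnot(inherits(g, "ontology_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
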