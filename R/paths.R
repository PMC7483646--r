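# Shortest-path communication analysis on a PSN.
#
# Paths are minimum-hop (the smallest number of intermediate nodes joining
# source and target through persistent non-covalent contacts). Among equally
# short paths the one with the higher mean edge persistence wins; remaining
# ties break lexicographically on the node sequence, so results are
# deterministic.

# label for a resno in a graph's node roster; NA when absent
graph_label <- function(graph, resno) {
  hit <- graph$nodes$node[match(resno, graph$nodes$resno)]
  hit
}

best_geodesic <- function(g, weights, from, to) {
  # returns list(nodes=character vector) or NULL when unreachable
  if (!(from %in% igraph::V(g)$name) || !(to %in% igraph::V(g)$name)) return(NULL)
  sp <- suppressWarnings(igraph::all_shortest_paths(g, from = from, to = to,
                                                    weights = NA))
  paths <- sp$vpaths %||% sp$res
  if (length(paths) == 0L) return(NULL)
  seqs <- lapply(paths, function(p) igraph::V(g)$name[p])
  aw <- vapply(seqs, function(s) mean(edge_persistences(g, s)), numeric(1))
  best <- which(aw == max(aw))
  if (length(best) > 1L) {
    keys <- vapply(seqs[best], paste, character(1), collapse = "\r")
    best <- best[order(keys)][1]
  } else best <- best[1]
  list(nodes = seqs[[best]], average_weight = aw[best])
}

edge_persistences <- function(g, node_seq) {
  if (length(node_seq) < 2L) return(numeric(0))
  eids <- igraph::get_edge_ids(g, rbind(node_seq[-length(node_seq)], node_seq[-1]))
  igraph::E(g)$persistence[eids]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shortest communication paths from one residue to a set of targets
#'
#' @param graph A `psn_graph`.
#' @param source Source residue number.
#' @param targets Integer vector of target residue numbers.
#' @return Tibble with one row per target: `source`, `target`, `path`
#'   (dash-separated node labels, `NA` when unreachable), `length` (number of
#'   intermediate nodes), `edge_count`, and `average_weight` (mean edge
#'   persistence along the path). Unreachable targets (and sources absent
#'   from the network) are reported as no-path rows, not errors.
#' @export
psn_shortest_paths <- function(graph, source, targets) {
  g <- as_igraph(graph)
  src_lab <- graph_label(graph, source)
  rows <- purrr::map_dfr(targets, function(t) {
    tgt_lab <- graph_label(graph, t)
    bp <- if (!is.na(src_lab) && !is.na(tgt_lab) && src_lab != tgt_lab) {
      best_geodesic(g, NULL, src_lab, tgt_lab)
    } else NULL
    if (is.null(bp)) {
      tibble::tibble(source = source, target = t, path = NA_character_,
                     length = NA_integer_, edge_count = NA_integer_,
                     average_weight = NA_real_)
    } else {
      tibble::tibble(source = source, target = t,
                     path = paste(bp$nodes, collapse = "-"),
                     length = length(bp$nodes) - 2L,
                     edge_count = length(bp$nodes) - 1L,
                     average_weight = bp$average_weight)
    }
  })
  rows
}

#' Best communication path from each mutation site to each residue class
#'
#' For every source and every named class of target residues, reports the
#' single best path over all class members: lowest hop count, ties broken by
#' higher average persistence, then by target residue number. Absence of any
#' path is recorded explicitly (`path = NA`).
#'
#' @param graph A `psn_graph`.
#' @param sources Integer vector of mutation-site residue numbers.
#' @param annotation A [functional_annotation()].
#' @param classes Character vector of set names from `annotation` (default:
#'   the five kinase target classes `activity`, `DFG`, `HRD`, `APE`,
#'   `chelix`, `cspine`, `rspine` that exist in the annotation).
#' @return Tibble with columns `source`, `class`, `target`, `path`, `length`,
#'   `edge_count`, `average_weight`.
#' @export
class_paths <- function(graph, sources, annotation,
                        classes = intersect(c("activity", "DFG", "HRD", "APE",
                                              "chelix", "cspine", "rspine"),
                                            names(annotation$sets))) {
  missing_cls <- setdiff(classes, names(annotation$sets))
  if (length(missing_cls) > 0L) {
    stop("unknown residue class(es): ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(sources, function(src) {
    purrr::map_dfr(classes, function(cl) {
      members <- setdiff(annotation$sets[[cl]], src)
      cand <- psn_shortest_paths(graph, src, members)
      hit <- dplyr::filter(cand, !is.na(.data$length))
      if (nrow(hit) == 0L) {
        tibble::tibble(source = src, class = cl, target = NA_integer_,
                       path = NA_character_, length = NA_integer_,
                       edge_count = NA_integer_, average_weight = NA_real_)
      } else {
        best <- dplyr::arrange(hit, .data$length,
                               dplyr::desc(.data$average_weight), .data$target)[1, ]
        dplyr::mutate(best, class = cl, .after = "source")
      }
    })
  })
}

#' Paths conserved across two independent ensembles
#'
#' Keeps the (source, class) pairs for which both ensembles yield a path
#' (default, existence mode) or for which the node sequences coincide
#' (`strict = TRUE`).
#'
#' @param tableA,tableB Outputs of [class_paths()] over the same sources and
#'   classes.
#' @param strict Require identical node sequences (default `FALSE`).
#' @return Tibble of conserved pairs with both paths (`_A`/`_B` suffixes).
#' @export
conserved_paths <- function(tableA, tableB, strict = FALSE) {
  keyA <- paste(tableA$source, tableA$class)
  keyB <- paste(tableB$source, tableB$class)
  if (!setequal(keyA, keyB)) {
    stop("source/class rosters differ between the two path tables", call. = FALSE)
  }
  joined <- dplyr::inner_join(tableA, tableB, by = c("source", "class"),
                              suffix = c("_A", "_B"))
  out <- dplyr::filter(joined, !is.na(.data$path_A), !is.na(.data$path_B))
  if (strict) out <- dplyr::filter(out, .data$path_A == .data$path_B)
  dplyr::arrange(out, .data$source, .data$class)
}

#' Per-source summary of long-range communication
#'
#' Counts the distinct residue classes each mutation site communicates with
#' (through conserved paths) and flags sites reaching at least
#' `min_classes` classes as long-range communicators.
#'
#' @param conserved Output of [conserved_paths()].
#' @param min_classes Classes needed to flag a source (default 2).
#' @return Tibble with `source`, `n_classes`, `long_range` flag.
#' @export
communication_summary <- function(conserved, min_classes = 2L) {
  conserved |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_classes = dplyr::n_distinct(.data$class), .groups = "drop") |>
    dplyr::mutate(long_range = .data$n_classes >= min_classes) |>
    dplyr::arrange(dplyr::desc(.data$n_classes), .data$source)
}
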