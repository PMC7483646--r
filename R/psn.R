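# Persistence-weighted protein structure networks.
#
# A PSN has residues as nodes and an edge for every residue pair whose
# interaction (side-chain contact, salt bridge, hydrogen bond) occurs in at
# least `persistence_cutoff` percent of the ensemble frames; the edge weight
# is that persistence.

new_psn_graph <- function(edges, nodes, interaction_type, params) {
  structure(list(edges = edges, nodes = nodes,
                 interaction_type = interaction_type, params = params),
            class = "psn_graph")
}

#' @export
print.psn_graph <- function(x, ...) {
  cat("<psn_graph> ", x$interaction_type, ": ", nrow(x$nodes), " residues, ",
      nrow(x$edges), " edges (persistence >= ", x$params$persistence_cutoff,
      "%, distance < ", x$params$distance_cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Tidy a PSN graph into its edge table
#'
#' @param x A `psn_graph`.
#' @param ... Unused.
#' @return Tibble with one row per edge: node labels `i`/`j`, residue numbers,
#'   interaction `type` and `persistence` (% of frames).
#' @method tidy psn_graph
#' @export
tidy.psn_graph <- function(x, ...) x$edges

#' One-row summary of a PSN graph
#' @param x A `psn_graph`.
#' @param ... Unused.
#' @return Tibble with node, edge, hub and component counts and parameters.
#' @method glance psn_graph
#' @export
glance.psn_graph <- function(x, ...) {
  comp <- psn_components(x)
  tibble::tibble(
    interaction_type = x$interaction_type,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_hubs = nrow(hubs(x)),
    n_components = if (nrow(comp)) dplyr::n_distinct(comp$component[!comp$singleton]) else 0L,
    distance_cutoff = x$params$distance_cutoff,
    persistence_cutoff = x$params$persistence_cutoff
  )
}

# labels for a residue table; chain-qualified only when several chains exist
node_labels <- function(res) {
  if (dplyr::n_distinct(res$chain) > 1L) paste0(res$chain, ":", res$label) else res$label
}

psn_from_counts <- function(counts, n_frames_used, res, interaction_type,
                            persistence_cutoff, params) {
  labs <- node_labels(res)
  idx <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    i = labs[idx[, 1]], j = labs[idx[, 2]],
    resno_i = res$resno[idx[, 1]], resno_j = res$resno[idx[, 2]],
    type = interaction_type,
    persistence = 100 * counts[idx] / n_frames_used
  )
  records <- dplyr::arrange(edges, .data$resno_i, .data$resno_j)
  edges <- dplyr::filter(records, .data$persistence >= persistence_cutoff)
  nodes <- dplyr::mutate(res, node = labs)
  graph <- new_psn_graph(edges, nodes, interaction_type, params)
  list(graph = graph, records = records)
}

#' Build a contact-based protein structure network
#'
#' Two residues are in contact in a frame when the distance between their
#' side-chain centres of mass is below `distance_cutoff`. A pair becomes an
#' edge when it is in contact in at least `persistence_cutoff` percent of the
#' frames (inclusive) and the residues are further apart in sequence than
#' `sequence_exclusion` (default: covalently adjacent neighbours excluded).
#'
#' @param ensemble A [conf_ensemble()].
#' @param distance_cutoff Contact distance cutoff in Å (default 5.0).
#' @param persistence_cutoff Minimum persistence in % of frames (default 20).
#' @param sequence_exclusion Exclude pairs with `|i - j| <=` this value on the
#'   same chain (default 1).
#' @param frame_stride Use every `frame_stride`-th frame (default 1 = all).
#' @return A `psn_graph`.
#' @export
build_contact_psn <- function(ensemble, distance_cutoff = 5.0,
                              persistence_cutoff = 20,
                              sequence_exclusion = 1L, frame_stride = 1L) {
  if (distance_cutoff <= 0 || persistence_cutoff <= 0) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  frames <- seq(1L, n_frames(ensemble), by = frame_stride)
  centers <- sidechain_centers(ensemble)
  res <- attr(centers, "residues")
  nr <- nrow(res)
  counts <- matrix(0L, nr, nr)
  for (f in frames) {
    d <- as.matrix(stats::dist(centers[, , f, drop = FALSE][, , 1, drop = TRUE]))
    counts <- counts + (d < distance_cutoff)
  }
  # sequence-neighbour exclusion
  same_chain <- outer(res$chain, res$chain, "==")
  close_seq <- abs(outer(res$resno, res$resno, "-")) <= sequence_exclusion
  counts[same_chain & close_seq] <- 0L
  psn_from_counts(counts, length(frames), res, "contact", persistence_cutoff,
                  list(distance_cutoff = distance_cutoff,
                       persistence_cutoff = persistence_cutoff,
                       sequence_exclusion = sequence_exclusion))$graph
}

#' Hub residues of a PSN
#'
#' Hubs are network nodes with at least `min_degree` edges, a proxy for
#' residues critical to structural stability.
#'
#' @param graph A `psn_graph`.
#' @param min_degree Minimum degree to call a hub (default 3).
#' @return Tibble of hub residues with their degree, descending.
#' @export
hubs <- function(graph, min_degree = 3L) {
  deg <- node_degrees(graph)
  dplyr::arrange(dplyr::filter(deg, .data$degree >= min_degree),
                 dplyr::desc(.data$degree), .data$resno)
}

#' Degrees of every node of a PSN
#' @inheritParams hubs
#' @return Tibble with `node`, `resno`, `degree` for every residue.
#' @export
node_degrees <- function(graph) {
  tab <- table(c(graph$edges$i, graph$edges$j))
  graph$nodes |>
    dplyr::mutate(degree = as.integer(dplyr::coalesce(as.integer(tab[.data$node]), 0L))) |>
    dplyr::select("node", "resno", "chain", "degree")
}

#' Connected components of a PSN
#'
#' @param graph A `psn_graph`.
#' @return Tibble with `node`, `component` (integer id, components ordered by
#'   decreasing size), `size`, and `singleton` marking nodes with no edges
#'   (each its own trivial component, reported separately from the connected
#'   clusters).
#' @export
psn_components <- function(graph) {
  g <- as_igraph(graph)
  connected <- igraph::V(g)$name
  out <- tibble::tibble(node = character(), component = integer(),
                        size = integer(), singleton = logical())
  if (length(connected) > 0L) {
    cmp <- igraph::components(g)
    memb <- cmp$membership
    ord <- order(-cmp$csize, seq_along(cmp$csize))
    rank <- match(seq_along(cmp$csize), ord)
    out <- tibble::tibble(node = names(memb),
                          component = rank[memb],
                          size = cmp$csize[memb],
                          singleton = FALSE)
  }
  singles <- setdiff(graph$nodes$node, out$node)
  if (length(singles) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      node = singles,
      component = max(c(out$component, 0L)) + seq_along(singles),
      size = 1L, singleton = TRUE))
  }
  dplyr::arrange(out, .data$component)
}

#' Convert a PSN to an igraph object
#'
#' Nodes with no persistent edges are dropped (igraph view of the network);
#' edge attribute `persistence` carries the weights.
#'
#' @param graph A `psn_graph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("i", "j", "persistence")], directed = FALSE)
}

# charged-moiety atom lists
.acidic_groups <- list(ASP = c("OD1", "OD2", "CG"), GLU = c("OE1", "OE2", "CD"))
.basic_groups <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE", "CZ"))
.his_group <- c("ND1", "NE2", "CE1")

#' Build the salt-bridge network of an ensemble
#'
#' An Asp/Glu-Lys/Arg pair interacts in a frame when any atom of the acidic
#' carboxylate group lies closer than `distance_cutoff` to any atom of the
#' basic amino/guanidinium group. Doubly protonated histidine can optionally
#' join the basic side.
#'
#' @param ensemble A [conf_ensemble()].
#' @param distance_cutoff Charged-group atom distance cutoff in Å (default 4.5).
#' @param persistence_cutoff Minimum persistence in % for graph edges
#'   (default 20). All pairs with persistence > 0 are kept in the records.
#' @param include_his Treat histidine as a basic partner (default `FALSE`).
#' @return List with `graph` (a `psn_graph`) and `records` (tibble of every
#'   pair with nonzero persistence).
#' @export
build_salt_bridge_network <- function(ensemble, distance_cutoff = 4.5,
                                      persistence_cutoff = 20,
                                      include_his = FALSE) {
  if (distance_cutoff <= 0 || persistence_cutoff <= 0) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  basic <- .basic_groups
  if (include_his) basic$HIS <- .his_group
  at <- ensemble$atoms
  res <- residue_table(ensemble)
  nr <- nrow(res)
  grp_idx <- vector("list", nr)
  role <- rep(NA_character_, nr)
  for (r in seq_len(nr)) {
    rid <- res$resid[r]
    grp <- if (rid %in% names(.acidic_groups)) .acidic_groups[[rid]]
           else if (rid %in% names(basic)) basic[[rid]]
           else NULL
    if (!is.null(grp)) {
      idx <- which(at$resno == res$resno[r] & at$chain == res$chain[r] &
                     at$atom %in% grp)
      if (length(idx) > 0L) {
        grp_idx[[r]] <- idx
        role[r] <- if (rid %in% names(.acidic_groups)) "acid" else "base"
      }
    }
  }
  acid <- which(role == "acid")
  base <- which(role == "base")
  nf <- n_frames(ensemble)
  counts <- matrix(0L, nr, nr)
  for (a in acid) {
    for (b in base) {
      xa <- ensemble$coords[grp_idx[[a]], , , drop = FALSE]
      xb <- ensemble$coords[grp_idx[[b]], , , drop = FALSE]
      hit <- 0L
      for (f in seq_len(nf)) {
        pa <- xa[, , f, drop = FALSE][, , 1, drop = FALSE]
        pb <- xb[, , f, drop = FALSE][, , 1, drop = FALSE]
        dim(pa) <- dim(pa)[1:2]; dim(pb) <- dim(pb)[1:2]
        d2min <- min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
        if (d2min < distance_cutoff^2) hit <- hit + 1L
      }
      ii <- min(a, b); jj <- max(a, b)
      counts[ii, jj] <- counts[ii, jj] + hit
      counts[jj, ii] <- counts[ii, jj]
    }
  }
  psn_from_counts(counts, nf, res, "salt_bridge", persistence_cutoff,
                  list(distance_cutoff = distance_cutoff,
                       persistence_cutoff = persistence_cutoff,
                       include_his = include_his))
}

# donor and acceptor heavy atoms for the standard residues
.hb_donors <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1"
)
.hb_acceptors <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

#' Build the hydrogen-bond network of an ensemble
#'
#' Default geometric criterion: donor-acceptor heavy-atom distance at most
#' `distance_cutoff`, plus a donor-H-acceptor angle of at least `angle_cutoff`
#' when hydrogen coordinates are present. Without hydrogens the angle
#' criterion is dropped with a warning and the distance alone decides.
#'
#' @param ensemble A [conf_ensemble()].
#' @param distance_cutoff Donor-acceptor heavy-atom distance, Å (default 3.5).
#' @param angle_cutoff Donor-H-acceptor angle in degrees (default 120).
#' @param persistence_cutoff Minimum persistence in % (default 20).
#' @param sequence_exclusion Exclude pairs with `|i - j| <=` this value
#'   (default 1).
#' @return A `psn_graph`.
#' @export
build_hbond_network <- function(ensemble, distance_cutoff = 3.5,
                                angle_cutoff = 120, persistence_cutoff = 20,
                                sequence_exclusion = 1L) {
  at <- ensemble$atoms
  res <- residue_table(ensemble)
  nr <- nrow(res)
  nf <- n_frames(ensemble)
  has_h <- any(at$element == "H")
  if (!has_h) {
    warning("no hydrogen coordinates: hydrogen bonds assigned by the ",
            "distance criterion only", call. = FALSE)
  }
  don <- list(); acc <- list()
  for (r in seq_len(nr)) {
    sel <- at$resno == res$resno[r] & at$chain == res$chain[r]
    d_names <- c(.hb_donors$backbone[res$resid[r] != "PRO"],
                 .hb_donors[[res$resid[r]]])
    a_names <- c(.hb_acceptors$backbone, .hb_acceptors[[res$resid[r]]])
    don[[r]] <- which(sel & at$atom %in% d_names)
    acc[[r]] <- which(sel & at$atom %in% a_names)
  }
  h_idx <- which(at$element == "H")
  counts <- matrix(0L, nr, nr)
  cos_cut <- cos(angle_cutoff * pi / 180)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[, , f]
    # attach hydrogens to their nearest heavy donor (<= 1.25 A)
    h_of <- list()
    if (has_h) {
      all_don <- unique(unlist(don))
      for (h in h_idx) {
        d2 <- colSums((t(xyz[all_don, , drop = FALSE]) - xyz[h, ])^2)
        j <- all_don[which.min(d2)]
        if (min(d2) <= 1.25^2) h_of[[as.character(j)]] <- c(h_of[[as.character(j)]], h)
      }
    }
    direction_bonded <- function(ri, rj) {
      for (d in don[[ri]]) {
        for (a in acc[[rj]]) {
          dv <- xyz[a, ] - xyz[d, ]
          if (sum(dv^2) > distance_cutoff^2) next
          hs <- h_of[[as.character(d)]]
          if (has_h && length(hs) > 0L) {
            ok <- FALSE
            for (h in hs) {
              v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
              cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
              if (cosang <= cos_cut) { ok <- TRUE; break }  # angle >= cutoff
            }
            if (!ok) next
          }
          return(TRUE)
        }
      }
      FALSE
    }
    for (ri in seq_len(nr - 1L)) {
      for (rj in seq(ri + 1L, nr)) {
        if (res$chain[ri] == res$chain[rj] &&
            abs(res$resno[ri] - res$resno[rj]) <= sequence_exclusion) next
        if (direction_bonded(ri, rj) || direction_bonded(rj, ri)) {
          counts[ri, rj] <- counts[ri, rj] + 1L
        }
      }
    }
  }
  psn_from_counts(counts, nf, res, "hbond", persistence_cutoff,
                  list(distance_cutoff = distance_cutoff,
                       angle_cutoff = angle_cutoff,
                       persistence_cutoff = persistence_cutoff,
                       sequence_exclusion = sequence_exclusion))$graph
}

#' Jackknife stability scan over contact cutoffs
#'
#' Rebuilds the contact PSN at each candidate distance cutoff on repeated
#' frame subsamples and summarises how the hub set and component structure
#' respond — the procedure used to justify a cutoff choice.
#'
#' @param ensemble A [conf_ensemble()].
#' @param cutoffs Numeric vector of at least two distance cutoffs (Å).
#' @param resample_fraction Fraction of frames per jackknife resample, in
#'   (0, 1] (default 0.8; 1 disables resampling).
#' @param repetitions Number of resamples per cutoff (default 10).
#' @param persistence_cutoff,sequence_exclusion Passed to [build_contact_psn()].
#' @param seed Optional integer seed for reproducible resampling.
#' @return Tibble with one row per cutoff: mean and SD of hub count,
#'   component count and edge count over the resamples.
#' @export
cutoff_scan <- function(ensemble, cutoffs, resample_fraction = 0.8,
                        repetitions = 10L, persistence_cutoff = 20,
                        sequence_exclusion = 1L, seed = NULL) {
  if (length(cutoffs) < 2L) stop("provide at least two cutoffs", call. = FALSE)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  if (resample_fraction <= 0 || resample_fraction > 1) {
    stop("resample_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) { old <- .Random.seed_safe(); set.seed(seed) }
  nf <- n_frames(ensemble)
  n_take <- max(2L, floor(resample_fraction * nf))
  rows <- purrr::map_dfr(cutoffs, function(cu) {
    stats <- purrr::map_dfr(seq_len(repetitions), function(rep) {
      ens <- if (resample_fraction < 1) {
        subset_frames(ensemble, sort(sample.int(nf, n_take)))
      } else ensemble
      g <- build_contact_psn(ens, distance_cutoff = cu,
                             persistence_cutoff = persistence_cutoff,
                             sequence_exclusion = sequence_exclusion)
      comp <- psn_components(g)
      tibble::tibble(n_hubs = nrow(hubs(g)),
                     n_components = dplyr::n_distinct(comp$component[!comp$singleton]),
                     n_edges = nrow(g$edges))
    })
    tibble::tibble(
      cutoff = cu, repetitions = repetitions,
      hub_count_mean = mean(stats$n_hubs), hub_count_sd = stats::sd(stats$n_hubs),
      component_count_mean = mean(stats$n_components),
      component_count_sd = stats::sd(stats$n_components),
      edge_count_mean = mean(stats$n_edges), edge_count_sd = stats::sd(stats$n_edges)
    )
  })
  rows
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' Export a PSN edge list
#'
#' @param graph A `psn_graph`.
#' @param path Output path.
#' @param format `"tsv"` (columns res_i, res_j, type, persistence) or
#'   `"graphml"` for network viewers.
#' @return `path`, invisibly.
#' @export
export_psn <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(
      dplyr::select(graph$edges, res_i = "i", res_j = "j", "type", "persistence"),
      path)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}
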