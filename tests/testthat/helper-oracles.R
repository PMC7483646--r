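# Independent brute-force oracles used to check the implementation.

# masses and side-chain definitions restated independently of the package
.orc_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
.orc_backbone <- c("N", "CA", "C", "O", "OXT")

# side-chain COM of one residue by direct summation over the raw atom table
oracle_sidechain_com <- function(ensemble, resno, frame) {
  at <- ensemble$atoms
  sel <- at$resno == resno & !(at$atom %in% .orc_backbone) &
    substr(at$atom, 1, 1) != "H"
  if (!any(sel)) sel <- at$resno == resno & at$atom == "CA"
  idx <- which(sel)
  w <- .orc_masses[ensemble$atoms$element[idx]]
  xyz <- ensemble$coords[idx, , frame]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  colSums(xyz * w) / sum(w)
}

# exhaustive per-frame, per-pair contact persistence matrix (upper triangle)
oracle_contact_psn <- function(ensemble, cutoff = 5, pers_cutoff = 20,
                               seq_excl = 1) {
  res <- sort(unique(ensemble$atoms$resno))
  nf <- dim(ensemble$coords)[3]
  out <- NULL
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a) next
      if (abs(res[b] - res[a]) <= seq_excl) next
      hits <- 0
      for (f in seq_len(nf)) {
        ca <- oracle_sidechain_com(ensemble, res[a], f)
        cb <- oracle_sidechain_com(ensemble, res[b], f)
        if (sqrt(sum((ca - cb)^2)) < cutoff) hits <- hits + 1
      }
      pers <- 100 * hits / nf
      if (pers >= pers_cutoff) {
        out <- rbind(out, data.frame(resno_i = res[a], resno_j = res[b],
                                     persistence = pers))
      }
    }
  }
  out
}

# BFS hop distances from one node over an edge list (two-column matrix of
# node labels); returns named vector, Inf when unreachable
oracle_bfs <- function(edges, nodes, from) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  if (!from %in% nodes) return(dist)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# flood-fill connected components over an edge list
oracle_components <- function(edges, nodes) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0
  for (n in nodes) {
    if (!is.na(comp[n])) next
    cid <- cid + 1
    stack <- n
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
      stack <- c(stack, nb[is.na(comp[nb])])
    }
  }
  comp
}

# one-sided (greater) Fisher p by full hypergeometric enumeration
oracle_fisher_greater <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  K <- n11 + n10          # margin of gene A
  n <- n11 + n01          # margin of gene B
  ks <- max(0, K + n - N):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= n11])
}

# accessible area of sphere 1 of two overlapping spheres (analytic cap)
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d <= abs(r1 - r2)) return(if (r1 > r2) 4 * pi * r1^2 else 0)
  h <- r1 - (r1^2 - r2^2 + d^2) / (2 * d)   # cap height buried on sphere 1
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# build a psn_graph directly from an integer edge list (test scaffolding)
graph_from_edges <- function(edges_df, n_nodes,
                             persistence = rep(100, nrow(edges_df))) {
  res <- tibble::tibble(chain = "A", resno = seq_len(n_nodes), resid = "ALA",
                        aa = "A", label = paste0("A", seq_len(n_nodes)),
                        standard_aa = TRUE)
  nodes <- dplyr::mutate(res, node = label)
  edges <- tibble::tibble(
    i = paste0("A", edges_df[, 1]), j = paste0("A", edges_df[, 2]),
    resno_i = as.integer(edges_df[, 1]), resno_j = as.integer(edges_df[, 2]),
    type = "contact", persistence = persistence)
  psnmut:::new_psn_graph(edges, nodes, "contact",
                         list(distance_cutoff = 5, persistence_cutoff = 20,
                              sequence_exclusion = 0))
}

# random undirected simple graph as an edge data frame
random_edges <- function(n_nodes, p = 0.15, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}
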