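# Contact, salt-bridge and hydrogen-bond persistence networks.

test_that("contact persistence follows the planted schedule", {
  sched <- tibble::tibble(i = c(2L, 3L), j = c(9L, 11L),
                          persistence = c(100, 15))
  ens <- make_toy_ensemble(12, sched, n_frames = 20, seed = 1)
  g <- build_contact_psn(ens)
  edges <- tidy(g)
  # the always-in-contact pair is an edge at weight 100
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$resno_i, 2L)
  expect_equal(edges$resno_j, 9L)
  expect_equal(edges$persistence, 100)
  # 15% of frames is below the 20% persistence cutoff: no edge
  expect_false(any(edges$resno_i == 3L & edges$resno_j == 11L))
  expect_error(build_contact_psn(ens, distance_cutoff = -1), "positive")
})

test_that("contact PSN equals the exhaustive per-frame per-pair oracle", {
  for (seed in 1:3) {
    set.seed(seed * 100)
    n_res <- sample(8:14, 1)
    n_fr <- sample(c(10L, 25L, 50L), 1)
    pairs <- t(combn(n_res, 2))
    pairs <- pairs[pairs[, 2] - pairs[, 1] > 1, , drop = FALSE]
    pick <- pairs[sample(nrow(pairs), 3), , drop = FALSE]
    # avoid shared movers with overlapping frames: distinct j guarantees it
    pick <- pick[!duplicated(pick[, 2]), , drop = FALSE]
    sched <- tibble::tibble(i = as.integer(pick[, 1]), j = as.integer(pick[, 2]),
                            persistence = sample(c(10, 30, 60, 100),
                                                 nrow(pick), replace = TRUE))
    ens <- make_toy_ensemble(n_res, sched, n_frames = n_fr, seed = seed)
    got <- tidy(build_contact_psn(ens))
    want <- oracle_contact_psn(ens)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$resno_i, want$resno_i)
      expect_equal(got$resno_j, want$resno_j)
      expect_equal(got$persistence, want$persistence)
    }
  }
})

test_that("persistence is invariant under frame permutation and cutoffs nest", {
  sched <- tibble::tibble(i = c(2L, 4L), j = c(8L, 10L), persistence = c(45, 80))
  ens <- make_toy_ensemble(10, sched, n_frames = 20, seed = 7)
  g1 <- tidy(build_contact_psn(ens))
  set.seed(42)
  perm <- subset_frames(ens, sample(20))
  expect_equal(tidy(build_contact_psn(perm)), g1)
  # distance cutoff: edges at 4.5 A are a subset of edges at 5.5 A
  e_small <- tidy(build_contact_psn(ens, distance_cutoff = 4.5))
  e_large <- tidy(build_contact_psn(ens, distance_cutoff = 5.5))
  key <- function(e) paste(e$resno_i, e$resno_j)
  expect_true(all(key(e_small) %in% key(e_large)))
  # raising the persistence cutoff never adds edges
  e_p20 <- tidy(build_contact_psn(ens, persistence_cutoff = 20))
  e_p50 <- tidy(build_contact_psn(ens, persistence_cutoff = 50))
  expect_true(all(key(e_p50) %in% key(e_p20)))
})

test_that("hubs are the nodes of degree >= 3, by direct count", {
  # star with 3 leaves: centre is a hub at the threshold boundary
  star <- graph_from_edges(cbind(1, 2:4), 5)
  h <- hubs(star)
  expect_equal(h$resno, 1L)
  expect_equal(h$degree, 3L)
  # empty graph
  empty <- graph_from_edges(matrix(integer(), 0, 2), 4)
  expect_equal(nrow(hubs(empty)), 0L)
  # random graph vs adjacency-list degree count
  ed <- random_edges(30, p = 0.12, seed = 5)
  g <- graph_from_edges(ed, 30)
  want <- table(factor(c(ed[, 1], ed[, 2]), levels = 1:30))
  expect_setequal(hubs(g)$resno, as.integer(names(want))[want >= 3])
})

test_that("connected components match a flood-fill oracle", {
  # two disjoint triangles
  tri <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3),
                                c(4, 5), c(5, 6), c(4, 6)), 6)
  comp <- psn_components(tri)
  expect_equal(sort(unique(comp$component)), 1:2)
  expect_true(all(comp$size == 3))
  # complete graph on 5 nodes: one component
  k5 <- graph_from_edges(t(combn(5, 2)), 5)
  expect_equal(unique(psn_components(k5)$component), 1L)
  # random graph vs oracle (partition equality up to relabelling)
  ed <- random_edges(25, p = 0.08, seed = 8)
  g <- graph_from_edges(ed, 25)
  got <- psn_components(g)
  want <- oracle_components(matrix(paste0("A", ed), ncol = 2),
                            paste0("A", 1:25))
  split_got <- split(got$node, got$component)
  split_want <- split(names(want), want)
  expect_setequal(lapply(split_got, sort) |> lapply(paste, collapse = ",") |> unlist() |> unname(),
                  lapply(split_want, sort) |> lapply(paste, collapse = ",") |> unlist() |> unname())
})

test_that("salt bridges follow the charged-group distance criterion", {
  # scheduled 100%: Asp-Lys pair interacts in every frame
  full <- build_salt_bridge_network(make_charged_pair_ensemble(100, 20, seed = 2))
  expect_equal(nrow(full$records), 1L)
  expect_equal(full$records$persistence, 100)
  expect_equal(full$graph$edges$type, "salt_bridge")
  # closest charged-group atoms beyond the cutoff in every frame: no record
  none <- build_salt_bridge_network(make_charged_pair_ensemble(0, 20, seed = 2))
  expect_equal(nrow(none$records), 0L)
  # inclusive threshold: exactly 20% persistence is kept as an edge
  edge20 <- build_salt_bridge_network(make_charged_pair_ensemble(20, 20, seed = 2))
  expect_equal(edge20$graph$edges$persistence, 20)
  # only (Asp|Glu) x (Lys|Arg) pairs can be salt-bridge edges
  sched <- tibble::tibble(i = 1L, j = 4L, persistence = 100)
  mixed <- make_toy_ensemble(6, sched, n_frames = 10, seed = 3)
  sb <- build_salt_bridge_network(mixed)
  if (nrow(sb$records) > 0) {
    res <- residue_table(mixed)
    types <- cbind(res$resid[match(sb$records$resno_i, res$resno)],
                   res$resid[match(sb$records$resno_j, res$resno)])
    ok <- apply(types, 1, function(tp) {
      any(tp %in% c("ASP", "GLU")) && any(tp %in% c("LYS", "ARG"))
    })
    expect_true(all(ok))
  }
})

test_that("hydrogen bonds obey the geometric criterion", {
  # two serines: donor OG of residue 1 at 2.9 A from acceptor OG of residue 2
  at <- tibble::tibble(
    atom = rep(c("N", "CA", "C", "O", "CB", "OG"), 2),
    resno = rep(c(1L, 3L), each = 6),
    resid = "SER", chain = "A")
  base <- rbind(
    c(-1.2, 0.8, 0), c(0, 0, 0), c(1.3, 0.5, 0), c(1.5, 1.7, 0),
    c(0, -1.5, 0), c(0, -2.9, 0),
    c(19, 0.8, 0), c(20, 0, 0), c(21.3, 0.5, 0), c(21.5, 1.7, 0),
    c(20, -1.5, 0), c(2.9, -2.9, 0))   # OG2 2.9 A from OG1 along x
  coords <- array(rep(base, 5), dim = c(12, 3, 5))
  ens <- conf_ensemble(at, coords)
  expect_warning(g <- build_hbond_network(ens), "hydrogen")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$persistence, 100)
  # move the acceptor to 4.2 A: beyond the 3.5 A threshold, no edge
  base2 <- base; base2[12, 1] <- 4.2
  ens2 <- conf_ensemble(at, array(rep(base2, 5), dim = c(12, 3, 5)))
  expect_warning(g2 <- build_hbond_network(ens2), "hydrogen")
  expect_equal(nrow(g2$edges), 0L)
  # with an explicit hydrogen, the angle criterion gates the bond; use a
  # serine donor against an aspartate (acceptor-only side chain)
  atha <- tibble::tibble(
    atom = c("N", "CA", "C", "O", "CB", "OG", "HG",
             "N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    resno = rep(c(1L, 3L), c(7L, 8L)),
    resid = rep(c("SER", "ASP"), c(7L, 8L)), chain = "A")
  mk <- function(h_xyz) {
    b <- rbind(
      c(-1.2, 0.8, 0), c(0, 0, 0), c(1.3, 0.5, 0), c(1.5, 1.7, 0),
      c(0, -1.5, 0), c(0, -2.9, 0), h_xyz,
      c(19, 0.8, 0), c(20, 0, 0), c(21.3, 0.5, 0), c(21.5, 1.7, 0),
      c(20, -1.5, 0), c(2.9, -3.9, 0), c(2.9, -2.9, 0), c(2.9, -5.5, 0))
    conf_ensemble(atha, array(rep(b, 2), dim = c(15, 3, 2)))
  }
  # donor H pointing away from the acceptor (angle ~0 deg at H) kills it
  gh <- build_hbond_network(mk(c(-0.9, -2.9, 0)))
  expect_equal(nrow(gh$edges), 0L)
  # H between donor and acceptor (angle ~180 deg) keeps it
  gh2 <- build_hbond_network(mk(c(0.95, -2.9, 0)))
  expect_equal(nrow(gh2$edges), 1L)
})

test_that("cutoff_scan reduces to single builds and is seed-reproducible", {
  sched <- tibble::tibble(i = c(2L, 3L), j = c(8L, 9L), persistence = c(100, 60))
  ens <- make_toy_ensemble(10, sched, n_frames = 15, seed = 4)
  # no resampling, one repetition: identical to build_contact_psn per cutoff
  scan <- cutoff_scan(ens, c(4.5, 5.5), resample_fraction = 1, repetitions = 1)
  for (k in 1:2) {
    g <- build_contact_psn(ens, distance_cutoff = scan$cutoff[k])
    expect_equal(scan$edge_count_mean[k], nrow(g$edges))
    expect_equal(scan$hub_count_mean[k], nrow(hubs(g)))
  }
  # monotone: more edges at the larger cutoff
  expect_gte(scan$edge_count_mean[2], scan$edge_count_mean[1])
  # same seed, same dispersion
  s1 <- cutoff_scan(ens, c(4.5, 5.5), repetitions = 5, seed = 99)
  s2 <- cutoff_scan(ens, c(4.5, 5.5), repetitions = 5, seed = 99)
  expect_identical(s1, s2)
  expect_error(cutoff_scan(ens, c(4, 5), resample_fraction = 1.2), "resample")
})

test_that("PSN edge lists export as TSV and GraphML", {
  sched <- tibble::tibble(i = 2L, j = 8L, persistence = 100)
  g <- build_contact_psn(make_toy_ensemble(9, sched, n_frames = 5, seed = 6))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_psn(g, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(names(back), c("res_i", "res_j", "type", "persistence"))
  expect_equal(nrow(back), 1L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_psn(g, gml, format = "graphml")
  expect_true(file.size(gml) > 0)
})
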