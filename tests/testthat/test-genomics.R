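# Mutation curation, annotations, SASA and co-occurrence statistics.

test_that("mutation tables parse from MAF and TSV dialects", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tHGVSp_Short",
    "ULK1\tS1\tMissense_Mutation\tp.S184F",
    "ULK1\tS2\tSilent\tp.G12G",
    "ATG13\tS1\tMissense_Mutation\tp.A10V"), maf)
  expect_message(recs <- parse_mutation_table(maf, "maf"), "non-missense")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$wt[1], "S")
  expect_equal(recs$site[1], 184L)
  expect_equal(recs$mut[1], "F")
  # malformed protein change is a row-level error with context
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein_change", "ULK1\tS18"), bad)
  expect_error(parse_mutation_table(bad, "tsv"), "malformed")
})

test_that("the curated table yields 36 unique kinase-domain mutations", {
  mu <- ulk1_mutations()
  in_domain <- filter_domain(mu)
  expect_equal(length(unique(in_domain$protein_change)), 36L)
  # domain filter boundary and idempotence
  toy <- tibble::tibble(site = c(7L, 8L, 280L, 281L))
  kept <- filter_domain(toy)
  expect_equal(kept$site, c(8L, 280L))
  expect_equal(filter_domain(kept), kept)
  # random positions vs interval-membership oracle
  set.seed(2)
  rnd <- tibble::tibble(site = sample(1:400, 100))
  expect_equal(filter_domain(rnd)$site,
               rnd$site[rnd$site >= 8 & rnd$site <= 280])
})

test_that("REVEL classification matches the curated calls and is monotone", {
  mu <- ulk1_mutations()
  expect_equal(revel_classify(mu$revel[mu$protein_change == "R137C"]),
               "damaging")   # score 0.843
  expect_equal(revel_classify(mu$revel[mu$protein_change == "V211I"]),
               "neutral")    # score 0.04
  expect_equal(revel_classify(NA_real_), "unscored")
  expect_equal(revel_classify(0.4), "damaging")  # inclusive boundary
  # monotone in the score
  s <- sort(runif(50))
  cls <- revel_classify(s)
  expect_true(all(diff(match(cls, c("neutral", "damaging"))) >= 0))
})

test_that("PTM and SLiM annotation flags follow the tables", {
  recs <- tibble::tibble(site = c(279L, 250L, 195L, 100L),
                         mut = c("N", "S", "P", "V"))
  slim <- tibble::tibble(name = "IAP-binding motif", start = 279L, end = 283L)
  ptm <- tibble::tibble(site = 195L, modification = "phosphorylation")
  gain <- tibble::tibble(site = 250L, mut = "S",
                         modification = "phosphorylation by PKC")
  sasa_tbl <- tibble::tibble(site = 250L, rel_sasa = 0.55)
  ann <- ptm_slim_annotate(recs, ptm_table = ptm, slim_table = slim,
                           gain_table = gain, sasa_table = sasa_tbl)
  # D279N sits at the start of the 279-283 motif: flagged without any halo
  expect_true(ann$slim_overlap[1])
  expect_match(ann$slim_motif[1], "IAP")
  # P250S introduces a phosphosite and the site is exposed
  expect_true(ann$ptm_gained[2])
  # S195P abolishes a predicted phosphosite
  expect_true(ann$ptm_abolished[3])
  # a site with no table hits gets no flags
  expect_false(any(ann$ptm_abolished[4], ann$ptm_gained[4],
                   ann$slim_overlap[4]))
  # a buried site blocks the phospho-gain flag
  ann2 <- ptm_slim_annotate(recs, gain_table = gain,
                            sasa_table = tibble::tibble(site = 250L,
                                                        rel_sasa = 0.05))
  expect_false(ann2$ptm_gained[2])
})

test_that("SASA matches closed-form sphere geometry", {
  # one isolated carbon: SASA = 4 pi (r + probe)^2 within quadrature error
  one <- conf_ensemble(
    tibble::tibble(atom = "CA", resno = 1L, resid = "GLY", chain = "A"),
    array(c(0, 0, 0), dim = c(1, 3, 1)))
  got <- sasa(one)$total_sasa
  expect_equal(got, 4 * pi * (1.87 + 1.4)^2, tolerance = 0.01)
  # two overlapping carbon spheres vs the analytic spherical-cap area
  two <- conf_ensemble(
    tibble::tibble(atom = c("CA", "CA"), resno = c(1L, 3L), resid = "GLY",
                   chain = "A"),
    array(c(0, 2.5, 0, 0, 0, 0), dim = c(2, 3, 1)))
  want <- oracle_two_sphere_area(1.87 + 1.4, 1.87 + 1.4, 2.5)
  got2 <- sasa(two)$total_sasa
  expect_equal(got2[1], want, tolerance = want * 0.02)
  # an atom buried inside a dense shell is fully occluded
  dirs <- psnmut:::sphere_points(60)
  shell_at <- tibble::tibble(
    atom = "CA", resno = c(1L, seq(3, 2 + nrow(dirs))), resid = "GLY",
    chain = "A")
  shell_xyz <- rbind(c(0, 0, 0), dirs * 2.2)
  shell <- conf_ensemble(shell_at, array(shell_xyz, dim = c(nrow(shell_xyz), 3, 1)))
  expect_lt(sasa(shell)$total_sasa[1], 1)
  # rotation invariance within quadrature tolerance
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  two_rot <- conf_ensemble(two$atoms,
                           array(t(rot %*% t(two$coords[, , 1])),
                                 dim = c(2, 3, 1)))
  expect_equal(sasa(two_rot)$total_sasa, got2, tolerance = 0.01)
})

test_that("Fisher co-occurrence equals exact hypergeometric enumeration", {
  # 10 samples, A in 4, B in 4, overlap 4: one-sided p = 1/C(10,4)
  m <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("A", "B")))
  m[1:4, "A"] <- TRUE; m[1:4, "B"] <- TRUE
  res <- cooccurrence_fisher(m, "A", "B")
  expect_equal(res$p_value, 1 / choose(10, 4), tolerance = 1e-12)
  # degenerate margin: a never-mutated gene gives p = 1
  m0 <- matrix(FALSE, 8, 2, dimnames = list(NULL, c("A", "B")))
  m0[1:3, "B"] <- TRUE
  expect_equal(cooccurrence_fisher(m0, "A", "B")$p_value, 1)
  # random incidence matrices vs the enumeration oracle
  for (seed in 1:5) {
    set.seed(seed)
    mm <- matrix(runif(30 * 5) < 0.3, 30, 5,
                 dimnames = list(NULL, paste0("G", 1:5)))
    r <- cooccurrence_fisher(mm, "G1", "G2")
    expect_equal(r$p_value,
                 oracle_fisher_greater(r$n11, r$n10, r$n01, r$n00),
                 tolerance = 1e-12)
    # label symmetry of the two-sided test
    p_ab <- cooccurrence_fisher(mm, "G1", "G2", "two.sided")$p_value
    p_ba <- cooccurrence_fisher(mm, "G2", "G1", "two.sided")$p_value
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
  }
  expect_error(cooccurrence_fisher(m[0, , drop = FALSE], "A", "B"),
               "no samples")
})

test_that("a gene panel screen orders pairs and can adjust p-values", {
  md <- make_mutation_data(150, c("ULK1", "P1", "P2", "P3"), rates = 0.2,
                           pair = c("ULK1", "P2"), odds_ratio = 15, seed = 4)
  sc <- cooccurrence_screen(md$matrix, "ULK1", adjust = TRUE)
  expect_equal(sc$geneB[1], "P2")
  expect_true(all(sc$fdr >= sc$p_value))
})

test_that("expression calls follow the logFC and FDR cutoffs", {
  dea <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                        logFC = c(0.8, -0.7, 0, 0.6, 2.0),
                        FDR = c(0.01, 0.04, 0.001, 0.2, NA))
  expect_warning(out <- classify_expression(dea), "no_DE")
  expect_equal(out$call, c("up", "down", "no_DE", "no_DE", "no_DE"))
  # boundary: logFC exactly at the cutoff counts
  at <- classify_expression(tibble::tibble(gene = "x", logFC = 0.5, FDR = 0.05))
  expect_equal(at$call, "up")
})
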