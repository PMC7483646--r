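# ddG parsing, aggregation, hotspots, and the network stability criteria.

test_that("ddG tables round-trip through both dialects", {
  gen <- make_ddg_scan(4, hotspot_sites = 2L, runs = 5L, frames = 2L, seed = 8,
                       dir = withr::local_tempdir())
  # tsv: one record per (site, substitution, run, frame)
  tsv <- grep("scan.tsv$", gen$files, value = TRUE)
  recs <- parse_ddg_tables(tsv, dialect = "tsv")
  expect_equal(nrow(recs), nrow(gen$records))
  expect_equal(recs$ddg, gen$records$ddg)
  # single mutation over 5 runs -> 5 records
  one <- recs[recs$site == 1 & recs$sub == recs$sub[1] & recs$frame == 1, ]
  expect_equal(nrow(one), 5L)
  # foldx-style matrices carry the same values
  fx <- grep("foldx$", gen$files, value = TRUE)
  recs_fx <- parse_ddg_tables(fx, dialect = "foldx")
  key <- function(d) paste(d$site, d$sub, d$run, d$frame)
  recs_fx <- recs_fx[order(match(key(recs_fx), key(recs))), ]
  expect_equal(recs_fx$ddg, recs$ddg, tolerance = 1e-9)
  # empty file: empty record list with a warning
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("site\twt\tsub\trun\tframe\tddg", empty)
  expect_warning(out <- parse_ddg_tables(empty, "tsv"), "no ddG")
  expect_equal(nrow(out), 0L)
  # unknown residue codes are a parse error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\twt\tsub\trun\tframe\tddg", "1\tX\tB\t1\t1\t0.5"), bad)
  expect_error(parse_ddg_tables(bad, "tsv"), "residue code")
})

test_that("aggregation averages runs within frames, then frames", {
  recs <- tibble::tibble(
    site = 1L, wt = "A", sub = "V",
    run = c(1L, 2L, 1L), frame = c(1L, 1L, 2L),
    ddg = c(0.5, 1.5, 3.0))
  scan <- aggregate_scan(recs)
  # frame means 1.0 and 3.0 -> mean 2.0, sd over frame means
  expect_equal(scan$mean_ddg, 2.0)
  expect_equal(scan$sd_ddg, sd(c(1, 3)))
  # the flat mean differs when run counts vary by frame
  expect_equal(aggregate_scan(recs, flat = TRUE)$mean_ddg, mean(recs$ddg))
  # constant records: mean x, dispersion 0
  const <- tibble::tibble(site = 1L, wt = "A", sub = "G",
                          run = rep(1:5, 4), frame = rep(1:4, each = 5),
                          ddg = 2.2)
  sc <- aggregate_scan(const)
  expect_equal(sc$mean_ddg, 2.2)
  expect_equal(sc$sd_ddg, 0)
  # permutation invariance in record order
  set.seed(4)
  gen <- make_ddg_scan(5, hotspot_sites = 3L, runs = 3L, frames = 4L, seed = 2)
  shuffled <- gen$records[sample(nrow(gen$records)), ]
  expect_equal(aggregate_scan(gen$records), aggregate_scan(shuffled))
  # two-level average equals a brute-force oracle
  want <- tapply(gen$records$ddg,
                 paste(gen$records$site, gen$records$sub),
                 function(x) mean(x))  # balanced design: flat = two-level
  got <- aggregate_scan(gen$records)
  expect_equal(got$mean_ddg, as.numeric(want[paste(got$site, got$sub)]),
               tolerance = 1e-12)
})

test_that("stability classification respects the documented thresholds", {
  scan <- tibble::tibble(site = c(1L, 1L, 2L, 2L), wt = "A",
                         sub = c("V", "G", "W", "D"),
                         mean_ddg = c(1.6, 0.0, 5.2, -1.0))
  # minor free-energy changes (0.2-1.6 kcal/mol) are neutral
  expect_equal(classify_stability(scan, "A1V"), "neutral")
  expect_equal(classify_stability(scan, "A1G"), "neutral")
  expect_equal(classify_stability(scan, "A2W"), "destabilizing")
  expect_equal(classify_stability(scan, "A2D"), "stabilizing")
  expect_error(classify_stability(scan, "A3V"), "no ddG value")
  # categories partition the line; boundaries are inclusive
  expect_equal(psnmut:::classify_ddg(3.0), "destabilizing")
  expect_equal(psnmut:::classify_ddg(2.999), "neutral")
  expect_equal(psnmut:::classify_ddg(-0.999), "neutral")
})

test_that("planted hotspots are found exactly and monotonically", {
  gen <- make_ddg_scan(12, hotspot_sites = c(3L, 7L, 10L), effect = 8,
                       noise_sd = 0.3, runs = 5L, frames = 5L, seed = 6)
  scan <- aggregate_scan(gen$records)
  hs <- find_hotspots(scan, damaging_threshold = 3.0)
  expect_setequal(hs$site[hs$hotspot], c(3L, 7L, 10L))   # recall & precision 1
  # an all-zero scan has no hotspots
  flat <- tibble::tibble(site = rep(1:3, each = 2), wt = "A",
                         sub = rep(c("V", "G"), 3), mean_ddg = 0)
  expect_false(any(find_hotspots(flat)$hotspot))
  # lowering the damaging threshold never removes a hotspot
  hs_low <- find_hotspots(scan, damaging_threshold = 1.0)
  expect_true(all(hs$site[hs$hotspot] %in% hs_low$site[hs_low$hotspot]))
})

test_that("hub loss requires a wild-type hub that the mutant loses", {
  wt <- graph_from_edges(cbind(1, 2:5), 6)       # node 1 has degree 4
  mut_lost <- graph_from_edges(cbind(1, 2:3), 6) # degree 2: hub abolished
  mut_kept <- graph_from_edges(cbind(1, 2:4), 6) # degree 3: hub conserved
  expect_true(hub_loss(wt, mut_lost, 1L)$hub_loss)
  r <- hub_loss(wt, mut_kept, 1L)
  expect_false(r$hub_loss)
  expect_match(r$reason, "conserved")
  # a non-hub site cannot lose hub behaviour
  r2 <- hub_loss(wt, mut_lost, 2L)
  expect_false(r2$hub_loss)
  expect_match(r2$reason, "not a wild-type hub")
  # no mutant ensemble: not evaluated, never silently false
  expect_true(is.na(hub_loss(wt, NULL, 1L)$hub_loss))
  expect_error(hub_loss(wt, mut_lost, 99L), "absent")
})

test_that("salt-bridge loss applies the charge-compatibility rules", {
  recs <- tibble::tibble(
    i = c("R152", "D138", "D268"), j = c("D102", "K140", "K201"),
    resno_i = c(152L, 138L, 268L), resno_j = c(102L, 140L, 201L),
    type = "salt_bridge", persistence = c(67.5, 99.8, 98.8))
  # arginine to leucine destroys the bridge
  expect_true(saltbridge_loss(recs, "R152L")$saltbridge_loss)
  # aspartate to histidine destroys it
  expect_true(saltbridge_loss(recs, "D268H")$saltbridge_loss)
  # asparagine retains electrostatic capability against the basic partner
  expect_false(saltbridge_loss(recs, "D138N")$saltbridge_loss)
  # acid-to-acid swap conserves
  expect_false(saltbridge_loss(recs, "D268E")$saltbridge_loss)
  # a site with no persistent bridge is never a loss
  r <- saltbridge_loss(recs, "D113E")
  expect_false(r$saltbridge_loss)
  expect_match(r$reason, "no persistent")
  # Arg-only asparagine rule flags D138N
  expect_true(saltbridge_loss(recs, "D138N",
                              asn_rule_partners = "R")$saltbridge_loss)
})

test_that("stability calls combine criteria as an OR with tri-state handling", {
  gen <- make_ddg_scan(12, hotspot_sites = 5L, runs = 2L, frames = 2L, seed = 3)
  scan <- aggregate_scan(gen$records)
  wt <- graph_from_edges(cbind(1, 2:5), 12)
  recs <- tibble::tibble(i = "D7", j = "K9", resno_i = 7L, resno_j = 9L,
                         type = "salt_bridge", persistence = 80)
  wt_aa <- scan$wt[match(c(5L, 7L), scan$site)]
  calls <- stability_calls(
    c(paste0(wt_aa[1], 5, "W"), paste0(wt_aa[2], 7, "L")),
    scan = scan, wt_graph = wt, sb_records = recs)
  # site 5: hotspot cell destabilising; no mutant graph -> hub NA; flag TRUE
  expect_true(calls$ddg_damaging[1])
  expect_true(calls$stability_flag[1])
  # site 7: wt 'D' bridges K -> D7L is a salt-bridge loss
  expect_true(calls$saltbridge_loss[2])
  expect_true(calls$network_loss[2])
  # all criteria unavailable -> everything not evaluated
  bare <- stability_calls("A3V", scan = NULL, wt_graph = NULL)
  expect_true(is.na(bare$stability_flag))
})
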