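# Saturation-mutagenesis free-energy aggregation and stability criteria.
#
# DDG records are one value per (site, substitution, run, frame), in
# kcal/mol, positive = destabilising. Aggregation averages runs within each
# frame, then frames (matching a protocol of several independent runs per
# ensemble conformation); the dispersion is the SD over frame means.

.aa1 <- unname(.aa3_to_1)

#' Parse a protein change string
#'
#' @param x Character vector like `"S184F"` or `"p.S184F"`.
#' @return Tibble with `wt`, `site`, `mut`.
#' @export
parse_protein_change <- function(x) {
  m <- stringr::str_match(sub("^p\\.", "", x), "^([A-Z])(\\d+)([A-Z])$")
  bad <- which(is.na(m[, 1]) | !(m[, 2] %in% .aa1) | !(m[, 4] %in% .aa1))
  if (length(bad) > 0L) {
    stop("malformed protein change string(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(wt = m[, 2], site = as.integer(m[, 3]), mut = m[, 4])
}

#' Read saturation-scan ΔΔG tables
#'
#' Two dialects are supported. `"tsv"`: a tidy table with columns `site`,
#' `wt`, `sub`, `run`, `frame`, `ddg`. `"foldx"`: a PSSM-style matrix per
#' file — first column the wild-type residue and position (e.g. `S184`),
#' remaining columns one ΔΔG per substituting residue (one-letter headers);
#' `run`/`frame` provenance read from `# run:`/`# frame:` header comments
#' (default 1).
#'
#' @param paths Character vector of file paths.
#' @param dialect `"tsv"` or `"foldx"`.
#' @return Tibble of ΔΔG records: `site`, `wt`, `sub`, `run`, `frame`, `ddg`.
#' @export
parse_ddg_tables <- function(paths, dialect = c("tsv", "foldx")) {
  dialect <- match.arg(dialect)
  recs <- purrr::map_dfr(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    if (dialect == "tsv") parse_ddg_tsv(p) else parse_ddg_foldx(p)
  })
  if (nrow(recs) == 0L) {
    warning("no ddG records parsed", call. = FALSE)
    return(tibble::tibble(site = integer(), wt = character(), sub = character(),
                          run = integer(), frame = integer(), ddg = double()))
  }
  bad <- which(!(recs$wt %in% .aa1) | !(recs$sub %in% .aa1))
  if (length(bad) > 0L) {
    stop("unknown residue code at record(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  self <- recs$wt == recs$sub
  recs[!self, , drop = FALSE]
}

parse_ddg_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("site", "wt", "sub", "run", "frame", "ddg")
  if (!all(need %in% names(df))) {
    stop(path, ": tsv dialect needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(site = as.integer(df$site), wt = df$wt, sub = df$sub,
                 run = as.integer(df$run), frame = as.integer(df$frame),
                 ddg = as.numeric(df$ddg))
}

parse_ddg_foldx <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  run <- as.integer(stringr::str_match(paste(hdr, collapse = " "), "run:\\s*(\\d+)")[, 2])
  frame <- as.integer(stringr::str_match(paste(hdr, collapse = " "), "frame:\\s*(\\d+)")[, 2])
  if (is.na(run)) run <- 1L
  if (is.na(frame)) frame <- 1L
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body), "\\s+")
  head_row <- fields[[1]]
  subs <- head_row[-1]
  purrr::map_dfr(fields[-1], function(fl) {
    pos <- stringr::str_match(fl[1], "^([A-Z])(\\d+)$")
    if (is.na(pos[1, 1])) {
      stop(path, ": cannot parse site label '", fl[1], "'", call. = FALSE)
    }
    vals <- fl[-1]
    vals[vals %in% c("NA", "-")] <- NA_character_
    tibble::tibble(site = as.integer(pos[1, 3]), wt = pos[1, 2], sub = subs,
                   run = run, frame = frame, ddg = as.numeric(vals))
  })
}

#' Write ΔΔG records to file
#'
#' @param records ΔΔG record tibble (see [parse_ddg_tables()]).
#' @param path Output file. For the foldx dialect one file is written per
#'   (run, frame); `path` is then treated as a template containing `{run}`
#'   and `{frame}`.
#' @param dialect `"tsv"` or `"foldx"`.
#' @return The written path(s), invisibly.
#' @export
write_ddg_tables <- function(records, path, dialect = c("tsv", "foldx")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    readr::write_tsv(records, path)
    return(invisible(path))
  }
  groups <- dplyr::group_split(dplyr::group_by(records, .data$run, .data$frame))
  out <- character(0)
  for (g in groups) {
    p <- sub("\\{run\\}", g$run[1], sub("\\{frame\\}", g$frame[1], path))
    wide <- tidyr::pivot_wider(
      dplyr::mutate(g, rowlab = paste0(.data$wt, .data$site)),
      id_cols = "rowlab", names_from = "sub", values_from = "ddg")
    con <- file(p, "wt")
    writeLines(c(paste0("# run: ", g$run[1]), paste0("# frame: ", g$frame[1]),
                 paste(c("site", names(wide)[-1]), collapse = "\t")), con)
    utils::write.table(wide, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    out <- c(out, p)
  }
  invisible(out)
}

#' Aggregate ΔΔG records into a saturation scan
#'
#' Per (site, substitution): the mean over runs within each frame, then the
#' mean over frames; dispersion is the SD over the frame means.
#'
#' @param records ΔΔG record tibble.
#' @param flat Use a flat mean over all records instead of the two-level
#'   average (identical when every frame has the same run count).
#' @return Tibble of class `saturation_scan`: `site`, `wt`, `sub`,
#'   `mean_ddg`, `sd_ddg`, `n_frames`, `n_records`.
#' @export
aggregate_scan <- function(records, flat = FALSE) {
  if (nrow(records) == 0L) stop("no ddG records to aggregate", call. = FALSE)
  scan <- records |>
    dplyr::group_by(.data$site, .data$wt, .data$sub, .data$frame) |>
    dplyr::summarise(frame_mean = mean(.data$ddg), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(.data$site, .data$wt, .data$sub) |>
    dplyr::summarise(mean_ddg = mean(.data$frame_mean),
                     sd_ddg = ifelse(dplyr::n() > 1, stats::sd(.data$frame_mean), 0),
                     n_frames = dplyr::n(), n_records = sum(.data$n),
                     .groups = "drop")
  if (flat) {
    flatm <- records |>
      dplyr::group_by(.data$site, .data$wt, .data$sub) |>
      dplyr::summarise(mean_ddg = mean(.data$ddg), .groups = "drop")
    scan$mean_ddg <- flatm$mean_ddg[match(paste(scan$site, scan$sub),
                                          paste(flatm$site, flatm$sub))]
  }
  class(scan) <- c("saturation_scan", class(scan))
  scan
}

#' Classify the stability impact of one substitution
#'
#' @param scan A [aggregate_scan()] result.
#' @param mutation Protein change string, e.g. `"S184F"`.
#' @param damaging_threshold Destabilising when mean ΔΔG `>=` this
#'   (kcal/mol, default 3.0).
#' @param stabilizing_threshold Stabilising when mean ΔΔG `<=` this
#'   (default -1.0).
#' @return One of `"destabilizing"`, `"neutral"`, `"stabilizing"`.
#' @export
classify_stability <- function(scan, mutation, damaging_threshold = 3.0,
                               stabilizing_threshold = -1.0) {
  pc <- parse_protein_change(mutation)
  cell <- scan[scan$site == pc$site & scan$sub == pc$mut, ]
  if (nrow(cell) == 0L) {
    stop("no ddG value for ", mutation, " in the scan", call. = FALSE)
  }
  classify_ddg(cell$mean_ddg[1], damaging_threshold, stabilizing_threshold)
}

classify_ddg <- function(ddg, damaging_threshold = 3.0,
                         stabilizing_threshold = -1.0) {
  dplyr::case_when(
    ddg >= damaging_threshold ~ "destabilizing",
    ddg <= stabilizing_threshold ~ "stabilizing",
    TRUE ~ "neutral"
  )
}

#' Stability hotspot sites of a saturation scan
#'
#' A site is a hotspot when more than `site_fraction` of its available
#' substitutions are destabilising — i.e. the position is sensitive to
#' replacement by most other residues.
#'
#' @param scan A [aggregate_scan()] result.
#' @param site_fraction Fraction of destabilising substitutions beyond which
#'   a site is a hotspot (default 0.5, strict `>`).
#' @param damaging_threshold Destabilising ΔΔG threshold (default 3.0).
#' @return Tibble per site: `site`, `wt`, `n_sub`, `n_damaging`, `fraction`,
#'   `hotspot`.
#' @export
find_hotspots <- function(scan, site_fraction = 0.5, damaging_threshold = 3.0) {
  scan |>
    dplyr::group_by(.data$site, .data$wt) |>
    dplyr::summarise(n_sub = dplyr::n(),
                     n_damaging = sum(.data$mean_ddg >= damaging_threshold),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_damaging / .data$n_sub,
                  hotspot = .data$fraction > site_fraction) |>
    dplyr::arrange(.data$site)
}

#' Hub-loss stability criterion
#'
#' A mutation damages stability by this criterion only when the wild-type
#' site is a network hub and the substitution abolishes the hub behaviour in
#' the mutant ensemble's network. Sites that are not wild-type hubs are
#' reported as not damaging with the reason recorded; without a mutant graph
#' the criterion is "not evaluated" (`NA`), never silently false.
#'
#' @param wt_graph Wild-type `psn_graph`.
#' @param mut_graph Mutant-ensemble `psn_graph`, or `NULL` if unavailable.
#' @param site Residue number of the mutation site.
#' @param min_degree Hub degree threshold (default 3).
#' @return One-row tibble: `site`, `wt_degree`, `mut_degree`, `hub_loss`
#'   (logical, `NA` = not evaluated), `reason`.
#' @export
hub_loss <- function(wt_graph, mut_graph, site, min_degree = 3L) {
  degs <- node_degrees(wt_graph)
  if (!site %in% degs$resno) {
    stop("site ", site, " absent from the wild-type graph roster", call. = FALSE)
  }
  wt_deg <- degs$degree[match(site, degs$resno)]
  if (wt_deg < min_degree) {
    return(tibble::tibble(site = site, wt_degree = wt_deg, mut_degree = NA_integer_,
                          hub_loss = FALSE, reason = "not a wild-type hub"))
  }
  if (is.null(mut_graph)) {
    return(tibble::tibble(site = site, wt_degree = wt_deg, mut_degree = NA_integer_,
                          hub_loss = NA, reason = "no mutant ensemble supplied"))
  }
  mdegs <- node_degrees(mut_graph)
  mut_deg <- if (site %in% mdegs$resno) mdegs$degree[match(site, mdegs$resno)] else 0L
  lost <- mut_deg < min_degree
  tibble::tibble(site = site, wt_degree = wt_deg, mut_degree = mut_deg,
                 hub_loss = lost,
                 reason = if (lost) "hub behaviour abolished" else "hub conserved")
}

#' Salt-bridge-loss stability criterion
#'
#' Damaging when the mutated site participates in a persistent salt bridge
#' and the substitution destroys the charge compatibility. Conservative
#' substitutions keep the bridge: acid-to-acid (D/E) and base-to-base (K/R)
#' swaps, and acid-to-asparagine facing an arginine partner (the amide can
#' still coordinate the guanidinium group).
#'
#' @param records Salt-bridge records from [build_salt_bridge_network()].
#' @param mutation Protein change string, e.g. `"R152L"`.
#' @param persistence_cutoff Bridges at or above this persistence count as
#'   persistent (default 20).
#' @param asn_rule_partners Basic partners against which the asparagine rule
#'   applies (default both `"R"` and `"K"`: the amide is treated as keeping
#'   electrostatic capability against either basic group).
#' @return One-row tibble: `mutation`, `site`, `saltbridge_loss`, `bridges`
#'   (semicolon-joined labels with persistences), `reason`.
#' @export
saltbridge_loss <- function(records, mutation, persistence_cutoff = 20,
                            asn_rule_partners = c("R", "K")) {
  pc <- parse_protein_change(mutation)
  acid1 <- c("D", "E"); base1 <- c("K", "R")
  pers <- records[records$persistence >= persistence_cutoff &
                    (records$resno_i == pc$site | records$resno_j == pc$site), ,
                  drop = FALSE]
  if (nrow(pers) == 0L) {
    return(tibble::tibble(mutation = mutation, site = pc$site,
                          saltbridge_loss = FALSE, bridges = NA_character_,
                          reason = "no persistent salt bridge at the site"))
  }
  partners <- ifelse(pers$resno_i == pc$site, pers$j, pers$i)
  partner_aa <- substr(partners, 1L, 1L)
  bridges <- paste0(ifelse(pers$resno_i == pc$site, pers$i, pers$j), "-",
                    partners, " (", round(pers$persistence, 1), "%)",
                    collapse = "; ")
  conserved <-
    (pc$wt %in% acid1 && pc$mut %in% acid1) ||
    (pc$wt %in% base1 && pc$mut %in% base1) ||
    (pc$wt %in% acid1 && pc$mut == "N" && all(partner_aa %in% asn_rule_partners))
  tibble::tibble(
    mutation = mutation, site = pc$site,
    saltbridge_loss = !conserved, bridges = bridges,
    reason = if (conserved) "charge compatibility conserved"
             else "substitution removes charge compatibility")
}

#' Per-mutation stability call combining all criteria
#'
#' @param mutations Character vector of protein changes (`"R152L"`, ...).
#' @param scan Optional [aggregate_scan()] result (ΔΔG criterion).
#' @param wt_graph Optional wild-type contact `psn_graph`.
#' @param mut_graphs Optional named list of mutant `psn_graph`s (names =
#'   protein change strings).
#' @param sb_records Optional salt-bridge records tibble.
#' @param damaging_threshold,stabilizing_threshold ΔΔG thresholds.
#' @param min_degree Hub degree threshold.
#' @param include_saltbridge Fold salt-bridge loss into the network criterion
#'   (default `TRUE`).
#' @return Tibble per mutation: `mutation`, `site`, `ddg`, `ddg_category`,
#'   `ddg_damaging`, `hub_loss`, `saltbridge_loss`, `network_loss`,
#'   `stability_flag` (logicals; `NA` = not evaluated).
#' @export
stability_calls <- function(mutations, scan = NULL, wt_graph = NULL,
                            mut_graphs = NULL, sb_records = NULL,
                            damaging_threshold = 3.0,
                            stabilizing_threshold = -1.0, min_degree = 3L,
                            include_saltbridge = TRUE) {
  purrr::map_dfr(mutations, function(m) {
    pc <- parse_protein_change(m)
    ddg <- NA_real_; ddg_cat <- NA_character_; ddg_dmg <- NA
    if (!is.null(scan)) {
      cell <- scan[scan$site == pc$site & scan$sub == pc$mut, ]
      if (nrow(cell) > 0L) {
        ddg <- cell$mean_ddg[1]
        ddg_cat <- classify_ddg(ddg, damaging_threshold, stabilizing_threshold)
        ddg_dmg <- ddg_cat == "destabilizing"
      }
    }
    hl <- NA
    if (!is.null(wt_graph)) {
      mg <- if (!is.null(mut_graphs)) mut_graphs[[m]] else NULL
      hl <- hub_loss(wt_graph, mg, pc$site, min_degree)$hub_loss
    }
    sb <- NA
    if (!is.null(sb_records)) sb <- saltbridge_loss(sb_records, m)$saltbridge_loss
    network <- if (include_saltbridge) tri_or(hl, sb) else hl
    tibble::tibble(mutation = m, site = pc$site, ddg = ddg,
                   ddg_category = ddg_cat, ddg_damaging = ddg_dmg,
                   hub_loss = hl, saltbridge_loss = sb, network_loss = network,
                   stability_flag = tri_or(ddg_dmg, network))
  })
}

# three-valued OR: TRUE beats everything; all-NA stays NA (not evaluated)
tri_or <- function(...) {
  vals <- c(...)
  if (any(vals %in% TRUE)) return(TRUE)
  if (all(is.na(vals))) return(NA)
  FALSE
}
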