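# Final per-mutation assessment: two stability descriptors (ddG, network
# loss) and five function descriptors (PTM abolished, PTM gained, SLiM
# overlap, functional-dynamics overlap, long-range communication), each
# tri-state: TRUE / FALSE / NA (not evaluated). Scores count TRUE
# descriptors, so "no evidence" never masquerades as "no effect".

.stability_descriptors <- c("ddg_damaging", "network_loss")
.function_descriptors <- c("ptm_abolished", "ptm_gained", "slim_overlap",
                           "dynamics_overlap", "long_range_paths")

#' Assemble the descriptor vector of one mutation
#'
#' Maps the upstream analysis outputs onto the seven tri-state descriptor
#' slots. Any analysis not supplied leaves its descriptors `NA`
#' (not evaluated).
#'
#' @param mutation Protein change string.
#' @param stability_call Optional one-row slice of [stability_calls()].
#' @param path_summary Optional [communication_summary()] tibble.
#' @param dynamics_flags Optional [mutation_dynamics_overlap()] tibble.
#' @param annotation_flags Optional [ptm_slim_annotate()] tibble slice.
#' @return One-row tibble: `mutation`, `site`, the seven descriptors.
#' @export
assemble_descriptors <- function(mutation, stability_call = NULL,
                                 path_summary = NULL, dynamics_flags = NULL,
                                 annotation_flags = NULL) {
  pc <- parse_protein_change(mutation)
  ddg <- NA; network <- NA
  if (!is.null(stability_call)) {
    row <- stability_call[stability_call$mutation == mutation, , drop = FALSE]
    if (nrow(row) > 1L) {
      stop("conflicting stability calls for ", mutation, call. = FALSE)
    }
    if (nrow(row) == 1L) {
      ddg <- row$ddg_damaging
      network <- row$network_loss
    }
  }
  ptm_ab <- NA; ptm_g <- NA; slim <- NA
  if (!is.null(annotation_flags)) {
    row <- annotation_flags[annotation_flags$site == pc$site &
                              annotation_flags$mut == pc$mut, , drop = FALSE]
    if (nrow(row) > 1L) {
      stop("conflicting annotation rows for ", mutation, call. = FALSE)
    }
    if (nrow(row) == 1L) {
      ptm_ab <- row$ptm_abolished
      ptm_g <- row$ptm_gained
      slim <- row$slim_overlap
    }
  }
  dyn <- NA
  if (!is.null(dynamics_flags)) {
    row <- dynamics_flags[dynamics_flags$site == pc$site, , drop = FALSE]
    if (nrow(row) >= 1L) dyn <- row$dynamics_overlap[1]
  }
  paths <- NA
  if (!is.null(path_summary)) {
    paths <- pc$site %in% path_summary$source[path_summary$long_range]
  }
  tibble::tibble(mutation = mutation, site = pc$site,
                 ddg_damaging = ddg, network_loss = network,
                 ptm_abolished = ptm_ab, ptm_gained = ptm_g,
                 slim_overlap = slim, dynamics_overlap = dyn,
                 long_range_paths = paths)
}

#' Score and categorise a descriptor vector
#'
#' Scores count the `TRUE` descriptors: stability in 0-2, function in 0-5.
#' Categories: both scores 0 is `neutral`; a positive stability score alone
#' is `stability_only`; a positive function score alone is `function_only`;
#' both positive is `both`.
#'
#' @param descriptors Tibble of descriptor rows (see
#'   [assemble_descriptors()]).
#' @return The input with `stability_score`, `function_score`, `category`
#'   and `n_not_evaluated` columns appended.
#' @export
score_and_categorize <- function(descriptors) {
  st <- as.matrix(descriptors[, .stability_descriptors])
  fn <- as.matrix(descriptors[, .function_descriptors])
  s_score <- rowSums(st, na.rm = TRUE)
  f_score <- rowSums(fn, na.rm = TRUE)
  dplyr::mutate(
    descriptors,
    stability_score = as.integer(s_score),
    function_score = as.integer(f_score),
    category = dplyr::case_when(
      s_score > 0 & f_score > 0 ~ "both",
      s_score > 0 ~ "stability_only",
      f_score > 0 ~ "function_only",
      TRUE ~ "neutral"
    ),
    n_not_evaluated = rowSums(is.na(st)) + rowSums(is.na(fn))
  )
}

#' Rank an assessment report
#'
#' Stable sort by the chosen score (descending), ties broken by the other
#' score, then by mutation label, so results are deterministic.
#'
#' @param report Output of [score_and_categorize()].
#' @param order `"function"`, `"stability"` or `"combined"`.
#' @return The ranked tibble with a `rank` column.
#' @export
rank_report <- function(report, order = c("function", "stability", "combined")) {
  order <- match.arg(order)
  key <- switch(order,
    "function" = report$function_score * 10 + report$stability_score,
    stability = report$stability_score * 10 + report$function_score,
    combined = report$function_score + report$stability_score)
  out <- report[base::order(-key, report$mutation), , drop = FALSE]
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Descriptor matrix of a report (heatmap-ready)
#'
#' @param report Output of [score_and_categorize()].
#' @return Long tibble: `mutation`, `descriptor`, `layer`
#'   (stability/function), `value` (`"damaging"`, `"neutral"`,
#'   `"not_evaluated"`).
#' @export
descriptor_matrix <- function(report) {
  report |>
    dplyr::select("mutation", dplyr::all_of(c(.stability_descriptors,
                                              .function_descriptors))) |>
    tidyr::pivot_longer(-"mutation", names_to = "descriptor",
                        values_to = "flag") |>
    dplyr::mutate(
      layer = ifelse(.data$descriptor %in% .stability_descriptors,
                     "stability", "function"),
      value = dplyr::case_when(
        is.na(.data$flag) ~ "not_evaluated",
        .data$flag ~ "damaging",
        TRUE ~ "neutral")) |>
    dplyr::select(-"flag")
}

#' Run the full mutation-assessment pipeline
#'
#' Executes ensemble reading, contact and salt-bridge networks,
#' communication paths, dynamics overlap, ΔΔG aggregation, annotation, and
#' the final scoring, in order, from a single configuration. Every analysis
#' is optional: descriptors whose inputs are absent stay "not evaluated".
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `mutations` (character vector or mutation-table path + `mutation_dialect`),
#'   `ensemble` / `ensemble2` (multi-model PDB paths),
#'   `ddg_tables` + `ddg_dialect`, `annotation` (YAML path or
#'   `functional_annotation`), `ptm_table`, `slim_table`, `gain_table`
#'   (tibbles or TSV paths), `mobile_regions` (tibble with start/end; default
#'   detected from the ensemble PCA when available), and thresholds
#'   `distance_cutoff`, `persistence_cutoff`, `damaging_threshold`, `halo`,
#'   `min_degree`, `seed`.
#' @return List of class `psnmut_run`: `report` (ranked assessment),
#'   `descriptors`, `stability`, `paths`, `dynamics`, `networks`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  cfg <- config
  get_num <- function(nm, dflt) if (!is.null(cfg[[nm]])) cfg[[nm]] else dflt
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  muts <- cfg$mutations
  if (is.null(muts)) stop("config must name mutations", call. = FALSE)
  if (length(muts) == 1L && file.exists(muts)) {
    muts <- parse_mutation_table(muts, dialect = get_num("mutation_dialect", "tsv"))$protein_change
  }
  muts <- unique(muts)

  annotation <- cfg$annotation
  if (is.null(annotation)) annotation <- ulk1_annotation()
  else if (is.character(annotation)) annotation <- load_annotation_config(annotation)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ens <- NULL; ens2 <- NULL
  if (!is.null(cfg$ensemble)) {
    ens <- stage("ensemble_io", {
      if (inherits(cfg$ensemble, "conf_ensemble")) cfg$ensemble
      else read_pdb_ensemble(cfg$ensemble)
    })
  }
  if (!is.null(cfg$ensemble2)) {
    ens2 <- stage("ensemble_io", {
      if (inherits(cfg$ensemble2, "conf_ensemble")) cfg$ensemble2
      else read_pdb_ensemble(cfg$ensemble2)
    })
  }

  sites <- parse_protein_change(muts)$site
  graph <- NULL; sb <- NULL; path_summary <- NULL; paths_tbl <- NULL
  if (!is.null(ens)) {
    graph <- stage("psn", build_contact_psn(
      ens, distance_cutoff = get_num("distance_cutoff", 5.0),
      persistence_cutoff = get_num("persistence_cutoff", 20)))
    sb <- stage("psn", build_salt_bridge_network(
      ens, persistence_cutoff = get_num("persistence_cutoff", 20)))
    paths_tbl <- stage("paths", class_paths(graph, sites, annotation))
    if (!is.null(ens2)) {
      graph2 <- stage("psn", build_contact_psn(
        ens2, distance_cutoff = get_num("distance_cutoff", 5.0),
        persistence_cutoff = get_num("persistence_cutoff", 20)))
      paths2 <- stage("paths", class_paths(graph2, sites, annotation))
      cons <- stage("paths", conserved_paths(paths_tbl, paths2))
    } else {
      cons <- dplyr::filter(paths_tbl, !is.na(.data$path)) |>
        dplyr::mutate(path_A = .data$path)
    }
    path_summary <- stage("paths", communication_summary(cons))
  }

  dyn <- NULL
  regions <- cfg$mobile_regions
  if (is.null(regions) && !is.null(ens) && n_frames(ens) >= 2L) {
    pca <- stage("dynamics", fit_pca(ens))
    regions <- stage("dynamics", mobile_regions(pca))
  }
  if (!is.null(regions) && nrow(regions) > 0L) {
    dyn <- stage("dynamics", mutation_dynamics_overlap(
      sites, regions, halo = get_num("halo", 2L)))
  }

  scan <- NULL
  if (!is.null(cfg$ddg_tables)) {
    scan <- stage("stability", aggregate_scan(parse_ddg_tables(
      cfg$ddg_tables, dialect = get_num("ddg_dialect", "tsv"))))
  }
  st_calls <- NULL
  if (!is.null(scan) || !is.null(graph)) {
    st_calls <- stage("stability", stability_calls(
      muts, scan = scan, wt_graph = graph,
      mut_graphs = cfg$mut_graphs, sb_records = if (!is.null(sb)) sb$records,
      damaging_threshold = get_num("damaging_threshold", 3.0),
      min_degree = get_num("min_degree", 3L)))
  }

  ann_flags <- NULL
  load_tbl <- function(x) {
    if (is.null(x)) NULL
    else if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE)
    else x
  }
  if (!is.null(cfg$ptm_table) || !is.null(cfg$slim_table) ||
      !is.null(cfg$gain_table)) {
    ann_flags <- stage("genomics", ptm_slim_annotate(
      parse_protein_change(muts),
      ptm_table = load_tbl(cfg$ptm_table),
      slim_table = load_tbl(cfg$slim_table),
      gain_table = load_tbl(cfg$gain_table),
      sasa_table = load_tbl(cfg$sasa_table)))
  }

  descriptors <- stage("classify", purrr::map_dfr(muts, assemble_descriptors,
    stability_call = st_calls, path_summary = path_summary,
    dynamics_flags = dyn, annotation_flags = ann_flags))
  report <- rank_report(score_and_categorize(descriptors), "combined")

  manifest <- list(
    n_mutations = length(muts),
    parameters = list(
      distance_cutoff = get_num("distance_cutoff", 5.0),
      persistence_cutoff = get_num("persistence_cutoff", 20),
      damaging_threshold = get_num("damaging_threshold", 3.0),
      min_degree = get_num("min_degree", 3L),
      halo = get_num("halo", 2L),
      seed = cfg$seed),
    inputs = list(
      ensemble = if (is.character(cfg$ensemble)) cfg$ensemble else !is.null(ens),
      ensemble2 = if (is.character(cfg$ensemble2)) cfg$ensemble2 else !is.null(ens2),
      ddg_tables = cfg$ddg_tables)
  )
  structure(list(report = report, descriptors = descriptors,
                 stability = st_calls, paths = paths_tbl,
                 path_summary = path_summary, dynamics = dyn,
                 networks = list(contact = graph, salt_bridge = sb),
                 scan = scan, manifest = manifest),
            class = "psnmut_run")
}

#' @export
print.psnmut_run <- function(x, ...) {
  cat("<psnmut_run> ", nrow(x$report), " mutations; categories: ",
      paste(names(table(x$report$category)), table(x$report$category),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an assessment run into its ranked report
#' @param x A `psnmut_run`.
#' @param ... Unused.
#' @method tidy psnmut_run
#' @export
tidy.psnmut_run <- function(x, ...) x$report

#' @method glance psnmut_run
#' @export
glance.psnmut_run <- function(x, ...) {
  tibble::tibble(
    n_mutations = nrow(x$report),
    n_stability_only = sum(x$report$category == "stability_only"),
    n_function_only = sum(x$report$category == "function_only"),
    n_both = sum(x$report$category == "both"),
    n_neutral = sum(x$report$category == "neutral"),
    pct_stability_damaging = 100 * mean(x$report$stability_score > 0)
  )
}

#' Write the report, descriptor matrix and manifest of a run
#'
#' @param run A `psnmut_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(run$report, file.path(dir, "report.tsv"))
  readr::write_tsv(descriptor_matrix(run$report),
                   file.path(dir, "descriptor_matrix.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
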