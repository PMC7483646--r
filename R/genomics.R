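# Curation of cancer missense mutations and their annotations.

#' Read a missense mutation table
#'
#' `"maf"` dialect expects the MAF column subset `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification` and `HGVSp_Short`
#' (`p.S184F` style); rows that are not missense are dropped with a message.
#' `"tsv"` expects tidy columns `gene`, `sample` (optional), `study`
#' (optional), `protein_change`, and optional `revel`.
#'
#' @param path Input file path.
#' @param dialect `"maf"` or `"tsv"`.
#' @return Tibble with one row per mutation record: `gene`, `sample`,
#'   `study`, `protein_change`, `wt`, `site`, `mut`, `revel`.
#' @export
parse_mutation_table <- function(path, dialect = c("maf", "tsv")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (dialect == "maf") {
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
              "HGVSp_Short")
    if (!all(need %in% names(df))) {
      stop(path, ": maf dialect needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    n0 <- nrow(df)
    df <- df[df$Variant_Classification == "Missense_Mutation", , drop = FALSE]
    if (nrow(df) < n0) {
      message(n0 - nrow(df), " non-missense row(s) dropped")
    }
    out <- tibble::tibble(
      gene = df$Hugo_Symbol,
      sample = df$Tumor_Sample_Barcode,
      study = if ("study" %in% names(df)) df$study else NA_character_,
      protein_change = sub("^p\\.", "", df$HGVSp_Short),
      revel = if ("revel" %in% names(df)) as.numeric(df$revel) else NA_real_
    )
  } else {
    if (!all(c("gene", "protein_change") %in% names(df))) {
      stop(path, ": tsv dialect needs columns gene, protein_change", call. = FALSE)
    }
    out <- tibble::tibble(
      gene = df$gene,
      sample = if ("sample" %in% names(df)) df$sample else NA_character_,
      study = if ("study" %in% names(df)) df$study else NA_character_,
      protein_change = sub("^p\\.", "", df$protein_change),
      revel = if ("revel" %in% names(df)) as.numeric(df$revel) else NA_real_
    )
  }
  bad <- !grepl("^[A-Z]\\d+[A-Z]$", out$protein_change)
  if (any(bad)) {
    stop(path, ": malformed protein change at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(utils::head(out$protein_change[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(out, parse_protein_change(out$protein_change))
}

#' The ULK1 kinase-domain missense mutations curated from TCGA
#'
#' The in-package copy of the curated pan-cancer ULK1 missense mutation
#' table (36 unique kinase-domain mutations across TCGA studies), with the
#' REVEL score, co-occurring ULK2 mutations, the differential-expression
#' call of the source study, and PTM/SLiM notes for each mutation.
#'
#' @return Tibble with columns `protein_change`, `study`, `revel`,
#'   `cooccurring_ulk2`, `dea`, `ptm_slim`, plus parsed `wt`, `site`, `mut`.
#' @export
ulk1_mutations <- function() {
  path <- system.file("extdata", "ulk1_tcga_missense.tsv", package = "psnmut",
                      mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  dplyr::bind_cols(df, parse_protein_change(df$protein_change))
}

#' Keep mutations inside a domain range
#'
#' @param records Tibble with a `site` column.
#' @param domain_range Closed position interval (default the ULK1 kinase
#'   domain, 8-280).
#' @return The records with `site` inside the interval.
#' @export
filter_domain <- function(records, domain_range = c(8L, 280L)) {
  dplyr::filter(records, .data$site >= domain_range[1],
                .data$site <= domain_range[2])
}

#' REVEL-based pathogenicity classification
#'
#' @param revel Numeric REVEL scores in \[0, 1\] (`NA` allowed).
#' @param cutoff Damaging at `score >= cutoff` (default 0.4).
#' @return Character vector: `"damaging"`, `"neutral"` or `"unscored"`.
#' @export
revel_classify <- function(revel, cutoff = 0.4) {
  dplyr::case_when(
    is.na(revel) ~ "unscored",
    revel >= cutoff ~ "damaging",
    TRUE ~ "neutral"
  )
}

#' Annotate mutations with PTM and SLiM interplay
#'
#' Flags, per mutation: abolition of a listed PTM site (mutation position is
#' an annotated modification site), overlap with a short linear motif range,
#' and gain of a new PTM (a predictor row marks the mutant residue at that
#' position, gated for phosphorylation gains by side-chain solvent exposure).
#'
#' @param records Mutation tibble with `site` and `mut` columns.
#' @param ptm_table Tibble of known sites: `site`, `modification`.
#' @param slim_table Tibble of motif ranges: `name`, `start`, `end`.
#' @param gain_table Tibble of predictor outputs: `site`, `mut`,
#'   `modification` (e.g. `"phosphorylation"`, `"S-nitrosylation"`), and
#'   optional free-text `detail`.
#' @param sasa_table Optional per-site relative side-chain SASA: `site`,
#'   `rel_sasa` (used only for phosphorylation gains).
#' @param exposure_threshold Relative SASA at or above which a site counts
#'   as solvent exposed (default 0.2).
#' @param slim_halo Extra residues around each motif range (default 0).
#' @return `records` with columns `ptm_abolished`, `ptm_gained`,
#'   `slim_overlap` (logical) and `ptm_note`, `slim_motif` (character).
#' @export
ptm_slim_annotate <- function(records, ptm_table = NULL, slim_table = NULL,
                              gain_table = NULL, sasa_table = NULL,
                              exposure_threshold = 0.2, slim_halo = 0L) {
  ann <- purrr::pmap_dfr(list(records$site, records$mut), function(site, mut) {
    abolished <- FALSE; note <- NA_character_
    if (!is.null(ptm_table) && nrow(ptm_table) > 0L) {
      hit <- ptm_table[ptm_table$site == site, , drop = FALSE]
      if (nrow(hit) > 0L) {
        abolished <- TRUE
        note <- paste(unique(hit$modification), collapse = "; ")
      }
    }
    motif <- NA_character_; slim <- FALSE
    if (!is.null(slim_table) && nrow(slim_table) > 0L) {
      hit <- slim_table[site >= slim_table$start - slim_halo &
                          site <= slim_table$end + slim_halo, , drop = FALSE]
      if (nrow(hit) > 0L) {
        slim <- TRUE
        motif <- paste(hit$name, collapse = "; ")
      }
    }
    gained <- FALSE; gnote <- NA_character_
    if (!is.null(gain_table) && nrow(gain_table) > 0L) {
      hit <- gain_table[gain_table$site == site & gain_table$mut == mut, ,
                        drop = FALSE]
      if (nrow(hit) > 0L) {
        keep <- rep(TRUE, nrow(hit))
        is_phos <- grepl("phos", hit$modification, ignore.case = TRUE)
        if (any(is_phos) && !is.null(sasa_table)) {
          rel <- sasa_table$rel_sasa[match(site, sasa_table$site)]
          if (!is.na(rel) && rel < exposure_threshold) keep[is_phos] <- FALSE
        }
        hit <- hit[keep, , drop = FALSE]
        if (nrow(hit) > 0L) {
          gained <- TRUE
          gnote <- paste(unique(hit$modification), collapse = "; ")
        }
      }
    }
    tibble::tibble(ptm_abolished = abolished, ptm_gained = gained,
                   slim_overlap = slim,
                   ptm_note = dplyr::coalesce(note, gnote),
                   slim_motif = motif)
  })
  dplyr::bind_cols(records, ann)
}

# NACCESS-style van der Waals radii by element (Å)
.vdw_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00,
                P = 1.90, SE = 1.90)

# Reference side-chain accessibilities (Å^2) in an extended Gly-X-Gly
# tripeptide, for relative-exposure normalisation.
.ref_sidechain_sasa <- c(
  ALA = 67.0, ARG = 196.0, ASN = 113.0, ASP = 106.0, CYS = 104.0,
  GLN = 144.0, GLU = 138.0, GLY = 25.0, HIS = 151.0, ILE = 140.0,
  LEU = 137.0, LYS = 167.0, MET = 160.0, PHE = 175.0, PRO = 105.0,
  SER = 80.0, THR = 102.0, TRP = 217.0, TYR = 187.0, VAL = 117.0)

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a rolling probe: each atom's extended sphere
#' (vdW + probe radius) is sampled with `n_points` quasi-uniform points and
#' the accessible fraction is the share of points outside every neighbour's
#' extended sphere. Returns per-residue totals and the side-chain relative
#' accessibility against extended Gly-X-Gly reference values.
#'
#' @param ensemble A [conf_ensemble()].
#' @param frame Frame to analyse (default 1).
#' @param probe_radius Probe radius in Å (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Tibble per residue: `resno`, `resid`, `total_sasa`,
#'   `sidechain_sasa` (Å²) and `rel_sasa` (side chain, fraction of the
#'   reference; `NA` for non-standard residues).
#' @export
sasa <- function(ensemble, frame = 1L, probe_radius = 1.4, n_points = 960L) {
  at <- ensemble$atoms
  heavy <- which(at$element != "H")
  unknown <- setdiff(unique(at$element[heavy]), names(.vdw_radii))
  if (length(unknown) > 0L) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  xyz <- ensemble$coords[heavy, , frame, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  r_ext <- unname(.vdw_radii[at$element[heavy]]) + probe_radius
  pts <- sphere_points(n_points)
  n <- length(heavy)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r_ext + r_ext[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * r_ext[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- colSums((t(surf) - xyz[j, ])^2)
      acc <- acc & dj2 > r_ext[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / n_points
  }
  res <- residue_table(ensemble)
  sc <- !(at$atom[heavy] %in% .backbone_atoms)
  purrr::pmap_dfr(list(res$resno, res$chain, res$resid), function(rn, ch, rid) {
    sel <- at$resno[heavy] == rn & at$chain[heavy] == ch
    sc_sel <- sel & sc
    if (!any(sc_sel)) sc_sel <- sel & at$atom[heavy] == "CA"  # glycine
    ref <- .ref_sidechain_sasa[rid]
    tibble::tibble(resno = rn, resid = rid,
                   total_sasa = sum(area[sel]),
                   sidechain_sasa = sum(area[sc_sel]),
                   rel_sasa = unname(sum(area[sc_sel]) / ref))
  })
}

#' Build a sample-by-gene mutation incidence matrix
#'
#' @param records Mutation tibble with `sample` and `gene` columns.
#' @return Logical matrix, samples in rows, genes in columns.
#' @export
mutation_matrix <- function(records) {
  samples <- sort(unique(records$sample))
  genes <- sort(unique(records$gene))
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(records$sample, samples), match(records$gene, genes))] <- TRUE
  m
}

#' Fisher's exact test for mutation co-occurrence
#'
#' Exact hypergeometric test on the 2x2 sample-incidence table of two genes;
#' one-sided "greater" by default (enrichment of joint mutation).
#'
#' @param matrix Logical sample-by-gene incidence matrix
#'   (see [mutation_matrix()]).
#' @param geneA,geneB Column names to test.
#' @param alternative `"greater"` (default), `"two.sided"`, or `"less"`.
#' @return One-row tibble: `geneA`, `geneB`, counts `n11`, `n10`, `n01`,
#'   `n00`, `odds_ratio` (conditional MLE), `p_value`.
#' @export
cooccurrence_fisher <- function(matrix, geneA, geneB,
                                alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (nrow(matrix) == 0L) stop("mutation matrix has no samples", call. = FALSE)
  for (g in c(geneA, geneB)) {
    if (!g %in% colnames(matrix)) stop("gene not in matrix: ", g, call. = FALSE)
  }
  a <- matrix[, geneA]; b <- matrix[, geneB]
  tab <- base::matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                      nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  tibble::tibble(geneA = geneA, geneB = geneB,
                 n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1],
                 n00 = tab[2, 2],
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Co-occurrence of one gene against a panel
#'
#' @param matrix Logical incidence matrix.
#' @param gene Focal gene.
#' @param against Character vector of partner genes (default: all others).
#' @param alternative Passed to [cooccurrence_fisher()].
#' @param adjust Apply Benjamini-Hochberg FDR across the tested pairs
#'   (default `FALSE`, matching a per-pair exact-test report).
#' @return Tibble with one row per pair, ordered by p-value.
#' @export
cooccurrence_screen <- function(matrix, gene, against = NULL,
                                alternative = "greater", adjust = FALSE) {
  if (is.null(against)) against <- setdiff(colnames(matrix), gene)
  out <- purrr::map_dfr(against, function(g) {
    cooccurrence_fisher(matrix, gene, g, alternative = alternative)
  })
  if (adjust) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Classify differential-expression results
#'
#' @param dea Tibble with `gene`, `logFC`, `FDR` columns (output of a
#'   differential expression analysis).
#' @param logfc_cutoff Absolute logFC cutoff (default 0.5).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @return `dea` with a `call` column: `"up"`, `"down"` or `"no_DE"`. Rows
#'   with missing FDR get `"no_DE"` with a warning.
#' @export
classify_expression <- function(dea, logfc_cutoff = 0.5, fdr_cutoff = 0.05) {
  if (anyNA(dea$FDR)) {
    warning(sum(is.na(dea$FDR)), " row(s) without FDR classified as no_DE",
            call. = FALSE)
  }
  dplyr::mutate(dea, call = dplyr::case_when(
    is.na(.data$FDR) ~ "no_DE",
    .data$logFC >= logfc_cutoff & .data$FDR <= fdr_cutoff ~ "up",
    .data$logFC <= -logfc_cutoff & .data$FDR <= fdr_cutoff ~ "down",
    TRUE ~ "no_DE"
  ))
}
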