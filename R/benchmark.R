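#' Validate the network and PCA stages against the deposited ULK1 ensembles
#'
#' Runs the cross-force-field checks on the two published microsecond MD
#' ensembles of the ULK1 kinase domain (CHARMM22star and CHARMM27,
#' deposited at OSF, record 8xuaj; converted to multi-model PDB): the RMSIP
#' of the first 20 principal components between the two ensembles, the joint
#' variance of the first two components of the concatenated trajectory, and
#' the persistence of the D138-K140 and D268-K201 salt bridges.
#'
#' The trajectories are not shipped with the package (hundreds of MB);
#' download them once and convert each to a multi-model PDB named
#' `charmm22star.pdb` / `charmm27.pdb` inside `dir`.
#'
#' @param dir Directory containing `charmm22star.pdb` and `charmm27.pdb`.
#' @param n_modes Modes for the RMSIP (default 20).
#' @return A tibble with `metric`, `ensemble`, `value`: rows `rmsip_20`,
#'   `top2_variance_pct`, `persistence_D138_K140` (both ensembles) and
#'   `persistence_D268_K201` (CHARMM22star).
#' @export
ulk1_ensemble_benchmark <- function(dir, n_modes = 20L) {
  f22 <- file.path(dir, "charmm22star.pdb")
  f27 <- file.path(dir, "charmm27.pdb")
  for (f in c(f22, f27)) {
    if (!file.exists(f)) {
      stop("deposited ensemble not found: ", f,
           " (download the published trajectories and convert to ",
           "multi-model PDB)", call. = FALSE)
    }
  }
  e22 <- read_pdb_ensemble(f22)
  e27 <- read_pdb_ensemble(f27)
  p22 <- fit_pca(e22)
  p27 <- fit_pca(e27)
  pcat <- fit_pca(e22, e27)
  sb22 <- build_salt_bridge_network(e22)$records
  sb27 <- build_salt_bridge_network(e27)$records
  bridge <- function(rec, a, b) {
    hit <- rec[(rec$resno_i == a & rec$resno_j == b) |
                 (rec$resno_i == b & rec$resno_j == a), ]
    if (nrow(hit) == 0L) NA_real_ else hit$persistence[1]
  }
  tibble::tibble(
    metric = c("rmsip_20", "top2_variance_pct",
               "persistence_D138_K140", "persistence_D138_K140",
               "persistence_D268_K201"),
    ensemble = c("charmm22star/charmm27", "concatenated",
                 "charmm22star", "charmm27", "charmm22star"),
    value = c(rmsip(p22, p27, n_modes), variance_fraction(pcat, 2L),
              bridge(sb22, 138L, 140L), bridge(sb27, 138L, 140L),
              bridge(sb22, 268L, 201L))
  )
}
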