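# Principal component analysis of Calpha fluctuations and essential-subspace
# comparison between ensembles.

# Kabsch optimal rotation of x (n x 3) onto y (n x 3), both centred.
kabsch_rotation <- function(x, y) {
  s <- svd(t(x) %*% y)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Least-squares superpose every row of a frames x 3N matrix onto ref (3N).
superpose_to <- function(xyz, ref) {
  refm <- matrix(ref, ncol = 3L, byrow = TRUE)
  refc <- sweep(refm, 2L, colMeans(refm))
  t(apply(xyz, 1L, function(fr) {
    m <- matrix(fr, ncol = 3L, byrow = TRUE)
    mc <- sweep(m, 2L, colMeans(m))
    as.vector(t(mc %*% kabsch_rotation(mc, refc)))
  }))
}

#' Principal component analysis of Cα fluctuations
#'
#' Frames (Cα only) are least-squares superposed onto their mean structure
#' (two fitting iterations), then the 3N x 3N covariance matrix of the
#' fluctuations is eigendecomposed. Pass several ensembles to analyse their
#' concatenated trajectory in one common essential subspace.
#'
#' @param ... One or more [conf_ensemble()] objects sharing a Cα roster.
#' @param fit Superpose frames onto the mean before the covariance
#'   (default `TRUE`; disable for pre-fitted input).
#' @return An object of class `pca_model`: `mean` (3N vector), `vectors`
#'   (3N x 3N orthonormal eigenvector matrix, columns descending),
#'   `values` (Å² variances), `residues` (tibble), `n_frames`.
#' @export
fit_pca <- function(..., fit = TRUE) {
  ensembles <- list(...)
  stopifnot(length(ensembles) >= 1L)
  mats <- lapply(ensembles, calpha_coords)
  res <- attr(mats[[1]], "residues")
  ncols <- unique(vapply(mats, ncol, integer(1)))
  if (length(ncols) != 1L) {
    stop("ensembles have different Calpha rosters", call. = FALSE)
  }
  xyz <- do.call(rbind, mats)
  if (nrow(xyz) < 2L) stop("need at least two frames for PCA", call. = FALSE)
  if (fit) {
    for (iter in 1:2) {
      ref <- colMeans(xyz)
      xyz <- superpose_to(xyz, ref)
    }
  }
  mu <- colMeans(xyz)
  dev <- sweep(xyz, 2L, mu)
  covm <- crossprod(dev) / (nrow(dev) - 1L)
  eig <- eigen(covm, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  structure(list(mean = mu, vectors = eig$vectors, values = values,
                 residues = res, n_frames = nrow(xyz)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", length(x$values), " modes over ", nrow(x$residues),
      " residues (", x$n_frames, " frames); top-2 variance ",
      round(variance_fraction(x, 2), 1), "%\n", sep = "")
  invisible(x)
}

#' Tidy a PCA model into a per-mode table
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return Tibble with `pc`, `eigenvalue` (Å²), `variance_pct`,
#'   `cumulative_pct`.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  tot <- sum(x$values)
  tibble::tibble(
    pc = seq_along(x$values),
    eigenvalue = x$values,
    variance_pct = if (tot > 0) 100 * x$values / tot else 0,
    cumulative_pct = if (tot > 0) 100 * cumsum(x$values) / tot else 0
  )
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_residues = nrow(x$residues), n_frames = x$n_frames,
                 total_variance = sum(x$values),
                 top2_variance_pct = variance_fraction(x, min(2L, length(x$values))))
}

#' Percentage of variance captured by the top k components
#'
#' @param model A `pca_model`.
#' @param k Number of leading components.
#' @return Percentage in \[0, 100\].
#' @export
variance_fraction <- function(model, k) {
  if (k < 1L || k > length(model$values)) {
    stop("k must be in 1..", length(model$values), call. = FALSE)
  }
  tot <- sum(model$values)
  if (tot == 0) return(0)
  100 * sum(model$values[seq_len(k)]) / tot
}

#' Root mean square inner product between two essential subspaces
#'
#' `sqrt( (1/n) * sum_ij (v_i . w_j)^2 )` over the first `n_modes`
#' eigenvectors of each model; 1 means identical subspaces, 0 mutually
#' orthogonal ones.
#'
#' @param modelA,modelB `pca_model` objects over identical Cα rosters.
#' @param n_modes Number of leading modes to compare (default 20).
#' @return Value in \[0, 1\].
#' @export
rmsip <- function(modelA, modelB, n_modes = 20L) {
  if (nrow(modelA$residues) != nrow(modelB$residues) ||
      !all(modelA$residues$resno == modelB$residues$resno)) {
    stop("models are defined over different residue rosters", call. = FALSE)
  }
  n <- min(n_modes, length(modelA$values), length(modelB$values))
  va <- modelA$vectors[, seq_len(n), drop = FALSE]
  vb <- modelB$vectors[, seq_len(n), drop = FALSE]
  sqrt(sum((t(va) %*% vb)^2) / n)
}

#' Per-residue displacement profile of a principal component
#'
#' @param model A `pca_model`.
#' @param pc Component index (default 1).
#' @return Tibble with `resno`, `label`, `displacement` (Euclidean norm of
#'   the residue's three eigenvector components; unit-eigenvector scale).
#' @export
residue_mobility <- function(model, pc = 1L) {
  if (pc < 1L || pc > ncol(model$vectors)) stop("invalid pc index", call. = FALSE)
  v <- matrix(model$vectors[, pc], ncol = 3L, byrow = TRUE)
  tibble::tibble(resno = model$residues$resno,
                 label = model$residues$label,
                 displacement = sqrt(rowSums(v^2)))
}

#' Detect mobile regions from a PC mobility profile
#'
#' Residues whose displacement exceeds `mean + n_sd * SD` of the profile are
#' merged into contiguous intervals of at least `min_length` residues.
#'
#' @param model A `pca_model`.
#' @param pc Component to analyse (default 1).
#' @param n_sd Threshold in SD units above the mean (default 1).
#' @param min_length Minimum interval length in residues (default 3).
#' @return Tibble with `start`, `end`, `peak` displacement and `pc`.
#' @export
mobile_regions <- function(model, pc = 1L, n_sd = 1, min_length = 3L) {
  prof <- residue_mobility(model, pc)
  thr <- mean(prof$displacement) + n_sd * stats::sd(prof$displacement)
  hot <- prof$resno[prof$displacement > thr]
  if (length(hot) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          peak = numeric(), pc = integer()))
  }
  runs <- split(hot, cumsum(c(1L, diff(hot) != 1L)))
  purrr::map_dfr(runs, function(r) {
    if (length(r) < min_length) return(NULL)
    tibble::tibble(start = min(r), end = max(r),
                   peak = max(prof$displacement[prof$resno %in% r]),
                   pc = as.integer(pc))
  })
}

#' ULK1 mobile regions from the microsecond dynamics
#'
#' The three concerted mobile loops of the ULK1 kinase domain: 148-158 and
#' the activation-loop stretch 172-183 (closure motions coupled through the
#' R152/R153-D102 electrostatics) and the loop 35-41 adjacent to the
#' catalytic lysine.
#'
#' @return Tibble with `start`, `end` columns.
#' @export
ulk1_mobile_regions <- function() {
  tibble::tibble(start = c(148L, 172L, 35L), end = c(158L, 183L, 41L))
}

#' Which mutation sites sit in or near mobile regions
#'
#' A site is flagged when its position falls inside a mobile region extended
#' by `halo` residues on each side — proximity to a functional motion that
#' the substitution may perturb.
#'
#' @param sites Integer vector of residue positions.
#' @param regions Tibble with `start`/`end` columns (default the ULK1
#'   regions of [ulk1_mobile_regions()]).
#' @param halo Extension in residues on each side (default 2).
#' @return Tibble with `site`, `dynamics_overlap` flag and the matched
#'   region (`NA` when none).
#' @export
mutation_dynamics_overlap <- function(sites, regions = ulk1_mobile_regions(),
                                      halo = 2L) {
  purrr::map_dfr(sites, function(s) {
    hit <- which(s >= regions$start - halo & s <= regions$end + halo)
    tibble::tibble(
      site = s,
      dynamics_overlap = length(hit) > 0L,
      region = if (length(hit) > 0L) {
        paste0(regions$start[hit[1]], "-", regions$end[hit[1]])
      } else NA_character_
    )
  })
}
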