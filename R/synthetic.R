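# Synthetic-data generators. Every input class of the pipeline can be
# produced with planted, exactly recoverable structure: contact schedules
# are realised by deterministic frame assignment (the first
# round(p * F / 100) frames of a pair are in contact), so persistences are
# exact up to one-frame rounding rather than sampled.

.toy_sidechains <- list(
  ALA = list(CB = c(0, -1.5, 0)),
  SER = list(CB = c(0, -1.5, 0), OG = c(0.8, -2.5, 0)),
  ASP = list(CB = c(0, -1.5, 0), CG = c(0, -2.9, 0),
             OD1 = c(1.0, -3.6, 0), OD2 = c(-1.0, -3.6, 0)),
  LYS = list(CB = c(0, -1.5, 0), CG = c(0, -2.9, 0), NZ = c(0, -4.4, 0)),
  ARG = list(CB = c(0, -1.5, 0), CZ = c(0, -3.3, 0), NE = c(-1.0, -2.6, 0),
             NH1 = c(1.0, -4.0, 0), NH2 = c(-1.0, -4.0, 0)),
  GLY = list()
)
.toy_cycle <- c("ALA", "ASP", "LYS", "ARG", "SER", "GLY")

toy_backbone <- function(ca) {
  list(N = ca + c(-1.2, 0.8, 0), CA = ca, C = ca + c(1.3, 0.5, 0),
       O = ca + c(1.5, 1.7, 0))
}

#' Build a toy ensemble with a planted contact schedule
#'
#' Pseudo-residues (backbone plus a small all-heavy-atom side chain, cycling
#' through Ala/Asp/Lys/Arg/Ser/Gly) are laid out far apart (~18 Å), so no
#' unscheduled side-chain contact can occur. For each scheduled pair the
#' higher-numbered residue's side chain is posed 3.5 Å from its partner's
#' side-chain centre of mass in exactly `round(persistence * n_frames / 100)`
#' frames (the first ones; `sampled = TRUE` draws them at random instead) and
#' stays home (>= 6 Å away) otherwise. The realised contact matrix is
#' verified against the schedule; an unrealisable geometry is an error naming
#' the conflicting pairs.
#'
#' @param n_residues Number of residues (>= 2).
#' @param schedule Tibble with columns `i`, `j` (residue numbers) and
#'   `persistence` (target % of frames); may be empty.
#' @param n_frames Number of frames (default 20).
#' @param seed Integer seed (coordinates get a small seeded jitter).
#' @param sampled Draw contact frames at random instead of deterministically.
#' @return A [conf_ensemble()] with attribute `"schedule"`.
#' @export
make_toy_ensemble <- function(n_residues, schedule = NULL, n_frames = 20L,
                              seed = 1L, sampled = FALSE) {
  stopifnot(n_residues >= 2L)
  if (is.null(schedule)) {
    schedule <- tibble::tibble(i = integer(), j = integer(),
                               persistence = double())
  }
  stopifnot(all(schedule$persistence >= 0), all(schedule$persistence <= 100))
  if (any(schedule$i >= schedule$j)) {
    stop("schedule pairs must have i < j", call. = FALSE)
  }
  set.seed(seed)
  spacing <- 18
  resid <- .toy_cycle[(seq_len(n_residues) - 1L) %% length(.toy_cycle) + 1L]
  # contact frame sets per pair
  contact_frames <- lapply(seq_len(nrow(schedule)), function(k) {
    nf_in <- round(schedule$persistence[k] * n_frames / 100)
    if (sampled) sort(sample.int(n_frames, nf_in)) else seq_len(nf_in)
  })
  # a mover handling two overlapping pairs is unrealisable
  if (nrow(schedule) > 1L) {
    for (a in seq_len(nrow(schedule) - 1L)) {
      for (b in seq(a + 1L, nrow(schedule))) {
        shared <- intersect(contact_frames[[a]], contact_frames[[b]])
        if (length(shared) > 0L && schedule$j[a] == schedule$j[b] &&
            schedule$i[a] != schedule$i[b]) {
          stop("unrealisable schedule: residue ", schedule$j[a],
               " must contact both ", schedule$i[a], " and ", schedule$i[b],
               " in overlapping frames", call. = FALSE)
        }
      }
    }
  }
  atoms <- list(); home <- list()
  for (r in seq_len(n_residues)) {
    ca <- c(spacing * ((r - 1L) %% 8L), 24 * ((r - 1L) %/% 8L), 0)
    bb <- toy_backbone(ca)
    sc <- lapply(.toy_sidechains[[resid[r]]], function(off) ca + off)
    coords <- c(bb, sc)
    atoms[[r]] <- tibble::tibble(atom = names(coords), resno = r,
                                 resid = resid[r], chain = "A")
    home[[r]] <- do.call(rbind, coords)
  }
  at <- dplyr::bind_rows(atoms)
  base <- do.call(rbind, home)
  n_at <- nrow(at)
  coords <- array(rep(base, n_frames), dim = c(n_at, 3L, n_frames))
  # indices of side-chain atoms (COM roster) per residue
  ens0 <- conf_ensemble(at, coords[, , 1, drop = FALSE])
  sc_idx <- lapply(seq_len(n_residues),
                   function(r) sidechain_atom_idx(ens0$atoms, r, "A"))
  masses <- ens0$atoms$mass
  com_of <- function(xyz, idx) {
    w <- masses[idx]
    m <- xyz[idx, , drop = FALSE]
    colSums(m * w) / sum(w)
  }
  frame_mat <- function(f, idx) {
    m <- coords[idx, , f]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    m
  }
  # pose movers (ordered so an anchor that itself moves is placed first)
  ord <- order(schedule$j)
  for (f in seq_len(n_frames)) {
    for (k in ord) {
      if (!(f %in% contact_frames[[k]])) next
      i <- schedule$i[k]; j <- schedule$j[k]
      anchor_com <- com_of(coords[, , f], sc_idx[[i]])
      u <- c(cos(2 * pi * j / n_residues), sin(2 * pi * j / n_residues), 0)
      target <- anchor_com + 3.5 * u
      shift <- target - com_of(coords[, , f], sc_idx[[j]])
      coords[sc_idx[[j]], , f] <- sweep(frame_mat(f, sc_idx[[j]]), 2L, shift, "+")
    }
  }
  coords <- coords + array(stats::rnorm(length(coords), sd = 0.02),
                           dim = dim(coords))
  ens <- conf_ensemble(ens0$atoms, coords)
  verify_schedule(ens, schedule, contact_frames, sc_idx, masses)
  attr(ens, "schedule") <- schedule
  ens
}

verify_schedule <- function(ens, schedule, contact_frames, sc_idx, masses) {
  centers <- sidechain_centers(ens)
  nf <- n_frames(ens)
  n_res <- dim(centers)[1]
  bad <- character(0)
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(centers[, , f, drop = FALSE][, , 1, drop = TRUE]))
    want <- matrix(FALSE, n_res, n_res)
    for (k in seq_len(nrow(schedule))) {
      if (f %in% contact_frames[[k]]) {
        want[schedule$i[k], schedule$j[k]] <- TRUE
      }
    }
    got <- d < 5
    diag(got) <- FALSE
    got[lower.tri(got)] <- FALSE
    mism <- which(want != got, arr.ind = TRUE)
    if (nrow(mism) > 0L) {
      bad <- unique(c(bad, paste0("(", mism[, 1], ",", mism[, 2], ")")))
    }
  }
  if (length(bad) > 0L) {
    stop("unrealisable schedule: conflicting geometry for pair(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Toy ensemble with one Asp-Lys salt bridge of scheduled persistence
#'
#' The lysine ammonium nitrogen sits 3.5 Å from the aspartate carboxylate in
#' the first `round(persistence * n_frames / 100)` frames and 7 Å away
#' otherwise, so the charged-group minimum distance crosses the 4.5 Å
#' criterion exactly as scheduled.
#'
#' @param persistence Target persistence in %.
#' @param n_frames Number of frames (default 20).
#' @param seed Integer seed for coordinate jitter.
#' @return A [conf_ensemble()] with residues ASP 1 and LYS 2.
#' @export
make_charged_pair_ensemble <- function(persistence, n_frames = 20L, seed = 1L) {
  stopifnot(persistence >= 0, persistence <= 100)
  set.seed(seed)
  bbA <- toy_backbone(c(0, 0, 0))
  scA <- lapply(.toy_sidechains$ASP, function(off) off)
  bbK <- toy_backbone(c(14, 0, 0))
  scK_home <- lapply(.toy_sidechains$LYS, function(off) c(14, 0, 0) + off)
  at <- tibble::tibble(
    atom = c(names(bbA), names(scA), names(bbK), names(scK_home)),
    resno = rep(c(1L, 2L), c(length(bbA) + length(scA),
                             length(bbK) + length(scK_home))),
    resid = rep(c("ASP", "LYS"), c(length(bbA) + length(scA),
                                   length(bbK) + length(scK_home))),
    chain = "A")
  base <- do.call(rbind, c(bbA, scA, bbK, scK_home))
  n_at <- nrow(at)
  coords <- array(rep(base, n_frames), dim = c(n_at, 3L, n_frames))
  od1 <- which(at$atom == "OD1")
  nz <- which(at$atom == "NZ")
  n_in <- round(persistence * n_frames / 100)
  for (f in seq_len(n_frames)) {
    d_target <- if (f <= n_in) 3.5 else 7.0
    # move the whole lysine side chain so NZ sits at d_target from OD1 along x
    shift <- (base[od1, ] + c(d_target, 0, 0)) - base[nz, ]
    ksc <- which(at$resno == 2L & !(at$atom %in% .backbone_atoms))
    coords[ksc, , f] <- sweep(base[ksc, , drop = FALSE], 2L, shift, "+")
  }
  coords <- coords + array(stats::rnorm(length(coords), sd = 0.01),
                           dim = dim(coords))
  conf_ensemble(at, coords)
}

# orthonormal modes for a Calpha roster, orthogonal to the rigid-body
# (translation + rotation) subspace of the mean structure
planted_modes <- function(mean_xyz, k, seed = 1L) {
  set.seed(seed)
  n3 <- length(mean_xyz)
  m <- matrix(mean_xyz, ncol = 3L, byrow = TRUE)
  mc <- sweep(m, 2L, colMeans(m))
  n <- nrow(m)
  rigid <- matrix(0, n3, 6L)
  for (d in 1:3) rigid[seq(d, n3, by = 3L), d] <- 1
  rot <- cbind(c(0, -1, 0, 1, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0, -1, 0, 0),
               c(0, 0, 0, 0, 0, -1, 0, 1, 0))
  for (d in 1:3) {
    g <- matrix(rot[, d], 3L, 3L)
    rigid[, 3L + d] <- as.vector(t(mc %*% t(g)))
  }
  rigid <- qr.Q(qr(rigid))
  raw <- matrix(stats::rnorm(n3 * k), n3, k)
  raw <- raw - rigid %*% (t(rigid) %*% raw)
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

# straight Calpha chain as a glycine-only ensemble scaffold
ca_scaffold <- function(n_residues) {
  tibble::tibble(atom = "CA", resno = seq_len(n_residues), resid = "GLY",
                 chain = "A")
}

#' Ensemble sampled from planted orthonormal displacement modes
#'
#' Frames are `mean + sum_i a_i(t) mode_i + noise`, with mode amplitudes
#' `a_i(t) ~ N(0, amplitude_i^2)` and isotropic Gaussian coordinate noise.
#' The planted modes are orthogonal to the rigid-body subspace, so they are
#' recoverable by Cα PCA.
#'
#' @param n_residues Number of Cα pseudo-residues.
#' @param amplitudes Descending per-mode displacement SDs (Å); their number
#'   sets the number of planted modes.
#' @param n_frames Number of frames (default 500).
#' @param noise Isotropic coordinate noise SD in Å (default 0.1).
#' @param seed Integer seed.
#' @param modes Optional pre-built 3N x k orthonormal mode matrix.
#' @return List: `ensemble` (a [conf_ensemble()]), `modes`, `amplitudes`.
#' @export
make_mode_ensemble <- function(n_residues, amplitudes = c(3, 2),
                               n_frames = 500L, noise = 0.1, seed = 1L,
                               modes = NULL) {
  stopifnot(all(diff(amplitudes) <= 0))
  at <- ca_scaffold(n_residues)
  mean_xyz <- as.vector(t(cbind(3.8 * seq_len(n_residues),
                                2 * sin(seq_len(n_residues)),
                                2 * cos(seq_len(n_residues)))))
  k <- length(amplitudes)
  if (is.null(modes)) modes <- planted_modes(mean_xyz, k, seed = seed)
  set.seed(seed + 1L)
  amps <- matrix(stats::rnorm(n_frames * k), n_frames, k) %*% diag(amplitudes, k)
  frames <- tcrossprod(amps, modes)          # n_frames x 3N displacements
  frames <- sweep(frames, 2L, mean_xyz, "+")
  frames <- frames + matrix(stats::rnorm(length(frames), sd = noise),
                            nrow = n_frames)
  coords <- array(NA_real_, dim = c(n_residues, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(frames[f, ], ncol = 3L, byrow = TRUE)
  }
  list(ensemble = conf_ensemble(at, coords), modes = modes,
       amplitudes = amplitudes)
}

#' Two ensembles with a tunable shared essential subspace
#'
#' Ensemble A is driven by modes `s_i`; ensemble B by
#' `overlap * s_i + sqrt(1 - overlap^2) * p_i` with `p_i` orthonormal private
#' modes, so the expected RMSIP of the top-k subspaces approximates
#' `overlap`.
#'
#' @param n_residues Number of Cα pseudo-residues.
#' @param overlap Target subspace overlap in \[0, 1\].
#' @param amplitudes Per-mode displacement SDs (Å).
#' @param n_frames Frames per ensemble (default 500).
#' @param noise Coordinate noise SD (default 0.1).
#' @param seed Integer seed.
#' @return List: `A`, `B` ([conf_ensemble()]s), `modes_A`, `modes_B`,
#'   `overlap`.
#' @export
make_ensemble_pair <- function(n_residues, overlap, amplitudes = c(3, 2),
                               n_frames = 500L, noise = 0.1, seed = 1L) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]", call. = FALSE)
  k <- length(amplitudes)
  at <- ca_scaffold(n_residues)
  mean_xyz <- as.vector(t(cbind(3.8 * seq_len(n_residues),
                                2 * sin(seq_len(n_residues)),
                                2 * cos(seq_len(n_residues)))))
  all_modes <- planted_modes(mean_xyz, 2L * k, seed = seed)
  shared <- all_modes[, seq_len(k), drop = FALSE]
  private <- all_modes[, k + seq_len(k), drop = FALSE]
  modes_B <- shared * overlap + private * sqrt(1 - overlap^2)
  a <- make_mode_ensemble(n_residues, amplitudes, n_frames, noise,
                          seed = seed + 10L, modes = shared)
  b <- make_mode_ensemble(n_residues, amplitudes, n_frames, noise,
                          seed = seed + 20L, modes = modes_B)
  list(A = a$ensemble, B = b$ensemble, modes_A = shared, modes_B = modes_B,
       overlap = overlap)
}

#' Saturation ΔΔG scan with planted hotspot sites
#'
#' Hotspot cells draw from `N(effect, noise_sd)`, all other cells from
#' `N(0.5, noise_sd)` (a mildly positive but sub-threshold background), for
#' every one of the 19 substitutions at each site, each run and frame.
#'
#' @param n_sites Number of sites.
#' @param hotspot_sites Integer site numbers planted as hotspots.
#' @param effect Hotspot mean ΔΔG in kcal/mol (default 8).
#' @param noise_sd Cell noise SD (default 0.3).
#' @param runs Independent runs per frame (default 5).
#' @param frames Ensemble conformations (default 20).
#' @param seed Integer seed.
#' @param dir Optional directory: records are also written in both dialects.
#' @return List: `records` tibble, `hotspot_sites`, and written `files`.
#' @export
make_ddg_scan <- function(n_sites, hotspot_sites = integer(), effect = 8,
                          noise_sd = 0.3, runs = 5L, frames = 20L, seed = 1L,
                          dir = NULL) {
  stopifnot(all(hotspot_sites >= 1L), all(hotspot_sites <= n_sites))
  set.seed(seed)
  wt <- .aa1[(seq_len(n_sites) - 1L) %% 20L + 1L]
  grid <- tidyr::expand_grid(site = seq_len(n_sites),
                             sub = .aa1,
                             run = seq_len(runs), frame = seq_len(frames))
  grid$wt <- wt[grid$site]
  grid <- grid[grid$sub != grid$wt, , drop = FALSE]
  mu <- ifelse(grid$site %in% hotspot_sites, effect, 0.5)
  grid$ddg <- stats::rnorm(nrow(grid), mean = mu, sd = noise_sd)
  records <- dplyr::select(grid, "site", "wt", "sub", "run", "frame", "ddg")
  files <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tsv <- file.path(dir, "scan.tsv")
    write_ddg_tables(records, tsv, dialect = "tsv")
    fx <- write_ddg_tables(records, file.path(dir, "scan_run{run}_frame{frame}.foldx"),
                           dialect = "foldx")
    files <- c(tsv, fx)
  }
  list(records = records, hotspot_sites = sort(unique(hotspot_sites)),
       files = files)
}

#' Binary mutation data with one planted co-occurring gene pair
#'
#' Genes mutate independently per sample at their background rates except
#' the planted pair, whose joint distribution matches the requested odds
#' ratio with the marginal rates preserved.
#'
#' @param n_samples Number of tumour samples.
#' @param genes Character vector of gene names.
#' @param rates Per-gene background mutation probabilities (recycled).
#' @param pair Length-2 character vector naming the co-occurring pair.
#' @param odds_ratio Target odds ratio for the pair (default 1 = none).
#' @param seed Integer seed.
#' @param maf_path Optional path: a MAF-dialect table is also written.
#' @return List: `matrix` (logical samples x genes), `records` tibble,
#'   `maf` path or `NULL`.
#' @export
make_mutation_data <- function(n_samples, genes, rates = 0.2, pair = NULL,
                               odds_ratio = 1, seed = 1L, maf_path = NULL) {
  stopifnot(all(rates > 0), all(rates < 1))
  set.seed(seed)
  rates <- rep_len(rates, length(genes))
  names(rates) <- genes
  m <- matrix(FALSE, n_samples, length(genes),
              dimnames = list(sprintf("S%04d", seq_len(n_samples)), genes))
  indep <- genes
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L, all(pair %in% genes))
    pA <- rates[pair[1]]; pB <- rates[pair[2]]
    p11 <- joint_prob_for_or(pA, pB, odds_ratio)
    u <- stats::runif(n_samples)
    both <- u < p11
    onlyA <- !both & u < p11 + (pA - p11)
    onlyB <- !both & !onlyA & u < pA + (pB - p11)
    m[, pair[1]] <- both | onlyA
    m[, pair[2]] <- both | onlyB
    indep <- setdiff(genes, pair)
  }
  for (g in indep) m[, g] <- stats::runif(n_samples) < rates[g]
  idx <- which(m, arr.ind = TRUE)
  records <- tibble::tibble(
    gene = colnames(m)[idx[, 2]],
    sample = rownames(m)[idx[, 1]],
    protein_change = "A10V")
  maf <- NULL
  if (!is.null(maf_path)) {
    maf_df <- tibble::tibble(
      Hugo_Symbol = records$gene,
      Tumor_Sample_Barcode = records$sample,
      Variant_Classification = "Missense_Mutation",
      HGVSp_Short = paste0("p.", records$protein_change))
    readr::write_tsv(maf_df, maf_path)
    maf <- maf_path
  }
  list(matrix = m, records = records, maf = maf)
}

# p11 solving OR = p11*p00 / (p10*p01) with fixed marginals
joint_prob_for_or <- function(pA, pB, or) {
  if (or == 1) return(pA * pB)
  a <- or - 1
  b <- -(a * (pA + pB) + 1)
  cc <- or * pA * pB
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  ok <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
  if (length(ok) == 0L) stop("odds ratio unattainable for these rates", call. = FALSE)
  min(max(ok[1], lo), hi)
}
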