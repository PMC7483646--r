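#' @importFrom rlang .data
NULL

# Atomic masses (u) for the heavy elements found in standard amino acids,
# plus hydrogen for ensembles that carry it.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971)

.standard_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

.aa3_to_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Construct a conformational ensemble
#'
#' A `conf_ensemble` holds an ordered set of frames (coordinate sets) over a
#' fixed atom roster. It is the substrate of every network and principal
#' component stage of the pipeline.
#'
#' @param atoms Tibble describing the atom roster, with columns `atom`
#'   (PDB atom name), `resno` (residue number), `resid` (three-letter residue
#'   code), `chain`, `element`, and `mass` (atomic mass units). `element` and
#'   `mass` are inferred from the atom name when missing.
#' @param coords Numeric array of dimension `n_atoms x 3 x n_frames` (Å).
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(atoms, coords) {
  atoms <- tibble::as_tibble(atoms)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (nrow(atoms) != dim(coords)[1]) {
    stop("atom roster (", nrow(atoms), " atoms) does not match coordinates (",
         dim(coords)[1], " rows)", call. = FALSE)
  }
  if (dim(coords)[3] < 1L) stop("ensemble must contain at least one frame", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (!"element" %in% names(atoms)) atoms$element <- NA_character_
  if (anyNA(atoms$element)) {
    inferred <- infer_element(atoms$atom)
    atoms$element[is.na(atoms$element)] <- inferred[is.na(atoms$element)]
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"mass" %in% names(atoms)) atoms$mass <- unname(.element_masses[atoms$element])
  if (anyNA(atoms$mass)) {
    bad <- unique(atoms$element[is.na(atoms$mass)])
    stop("no mass known for element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(atoms$mass <= 0)) stop("atomic masses must be positive", call. = FALSE)
  atoms$standard_aa <- atoms$resid %in% .standard_aa3
  structure(list(atoms = atoms, coords = coords), class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat("<conf_ensemble> ", n_frames(x), " frame(s), ", n_atoms(x), " atoms, ",
      nrow(residue_table(x)), " residues\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble A `conf_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[1]

#' Residue roster of an ensemble
#'
#' @param ensemble A `conf_ensemble`.
#' @return Tibble with one row per residue: `chain`, `resno`, `resid`,
#'   one-letter `aa`, a display `label` (e.g. `"D138"`), and `standard_aa`
#'   flagging the 20 standard residue types. Non-standard residues are kept
#'   and flagged, never silently dropped.
#' @export
residue_table <- function(ensemble) {
  ensemble$atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$resid) |>
    dplyr::arrange(.data$chain, .data$resno) |>
    dplyr::mutate(
      aa = dplyr::coalesce(.aa3_to_1[.data$resid], "X"),
      label = paste0(.data$aa, .data$resno),
      standard_aa = .data$resid %in% .standard_aa3
    )
}

infer_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  el <- substr(nm, 1L, 1L)
  el[grepl("^SE", nm)] <- "SE"
  # digit-led hydrogens such as 1HB
  el[grepl("^[0-9]", nm)] <- substr(sub("^[0-9]+", "", nm[grepl("^[0-9]", nm)]), 1L, 1L)
  el
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' One frame is created per `MODEL` record (a file without `MODEL` records
#' yields a single-frame ensemble). All models must share an identical atom
#' roster. Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties: first encountered).
#'
#' @param path Path to a PDB file.
#' @param model_policy `"all"` (default) keeps every model; `"first"` keeps
#'   only the first.
#' @return A [conf_ensemble()].
#' @export
read_pdb_ensemble <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  model_starts <- grepl("^MODEL", raw)
  if (any(model_starts)) {
    blocks <- cumsum(model_starts)
    is_atom <- grepl("^(ATOM|HETATM)", raw)
    per_model <- table(blocks[is_atom & blocks > 0])
    if (length(unique(as.integer(per_model))) > 1L) {
      stop("atom rosters differ between MODEL records in ", path, call. = FALSE)
    }
    if (length(per_model) == 0L) stop("no atom records in ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = (model_policy == "all"),
                         rm.alt = FALSE, verbose = FALSE)
  at_all <- pdb$atom
  keep <- at_all$type %in% c("ATOM", "HETATM")
  if (!any(keep)) stop("no atom records in ", path, call. = FALSE)
  # alternate locations: keep highest occupancy, tie -> first encountered
  alt <- keep & !is.na(at_all$alt) & at_all$alt != ""
  if (any(alt)) {
    key <- paste(at_all$chain, at_all$resno, at_all$insert, at_all$elety, sep = "|")
    occ <- ifelse(is.na(at_all$o), 1, at_all$o)
    for (k in unique(key[alt])) {
      idx <- which(keep & key == k)
      if (length(idx) > 1L) {
        best <- idx[which.max(occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  at <- at_all[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  if (model_policy == "first") {
    xyz <- xyz[1L, , drop = FALSE]
    nf <- 1L
  }
  na_rows <- apply(xyz, 1L, function(r) anyNA(r))
  if (any(na_rows)) {
    stop("atom rosters differ between MODEL records in ", path,
         " (models with missing atoms: ", paste(which(na_rows), collapse = ", "),
         ")", call. = FALSE)
  }
  n_at <- nrow(at)
  if (ncol(xyz) != 3L * n_at) {
    stop("atom rosters differ between MODEL records in ", path, call. = FALSE)
  }
  coords <- array(NA_real_, dim = c(n_at, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  el <- toupper(trimws(at$elesy))
  el[is.na(el) | el == ""] <- NA_character_
  atoms <- tibble::tibble(
    atom = trimws(at$elety),
    resno = at$resno,
    resid = toupper(trimws(at$resid)),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    element = el
  )
  conf_ensemble(atoms, coords)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Frames are written as `MODEL`/`ENDMDL` blocks with standard fixed-width
#' ATOM records (coordinate precision 0.001 Å).
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  nf <- n_frames(ensemble)
  con <- file(path, open = "wt")
  on.exit(close(con))
  name4 <- ifelse(nchar(at$atom) >= 4L, substr(at$atom, 1L, 4L),
                  sprintf(" %-3s", at$atom))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$coords[, , f]
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(at)) %% 100000L, name4, substr(at$resid, 1, 3),
                     at$chain, at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Subset or evenly subsample the frames of an ensemble
#'
#' `subset_frames` keeps the given frame indices; `representative_frames`
#' picks `n` frames equally spaced in time, the default policy for choosing
#' representative conformations (e.g. for free-energy scans).
#'
#' @param ensemble A [conf_ensemble()].
#' @param frames Integer frame indices (in order).
#' @param n Number of equally spaced frames to keep.
#' @return A [conf_ensemble()] with the selected frames.
#' @export
subset_frames <- function(ensemble, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(ensemble)))
  conf_ensemble(ensemble$atoms, ensemble$coords[, , frames, drop = FALSE])
}

#' @rdname subset_frames
#' @export
representative_frames <- function(ensemble, n) {
  nf <- n_frames(ensemble)
  stopifnot(n >= 1L, n <= nf)
  subset_frames(ensemble, unique(round(seq(1L, nf, length.out = n))))
}

#' Side-chain centre of mass of a residue
#'
#' Mass-weighted mean of the side-chain heavy atoms (hydrogens and backbone
#' N/CA/C/O excluded). Glycine has no side chain and falls back to its Cα;
#' alanine's centre is its lone Cβ.
#'
#' @param ensemble A [conf_ensemble()].
#' @param resno Residue number (coordinate-file numbering).
#' @param frame Frame index (default 1).
#' @param chain Chain identifier; default the first chain of the roster.
#' @return Numeric length-3 coordinate vector (Å).
#' @export
sidechain_center_of_mass <- function(ensemble, resno, frame = 1L, chain = NULL) {
  at <- ensemble$atoms
  if (is.null(chain)) chain <- at$chain[1]
  idx <- sidechain_atom_idx(at, resno, chain)
  if (length(idx) == 0L) {
    stop("residue ", resno, " has no side-chain heavy atoms and no CA", call. = FALSE)
  }
  xyz <- ensemble$coords[idx, , frame, drop = FALSE][, , 1, drop = TRUE]
  if (length(idx) == 1L) return(as.numeric(xyz))
  w <- at$mass[idx]
  as.numeric(colSums(xyz * w) / sum(w))
}

# Indices of the atoms defining a residue's interaction centre.
sidechain_atom_idx <- function(atoms, resno, chain) {
  in_res <- atoms$resno == resno & atoms$chain == chain
  if (!any(in_res)) stop("residue ", resno, " not present in ensemble", call. = FALSE)
  sc <- in_res & !(atoms$atom %in% .backbone_atoms) & atoms$element != "H"
  if (!any(sc)) sc <- in_res & atoms$atom == "CA"  # glycine fallback
  which(sc)
}

# Side-chain COMs for every residue and frame: n_res x 3 x n_frames array.
# Attribute "residues" carries the residue table.
sidechain_centers <- function(ensemble) {
  res <- residue_table(ensemble)
  nf <- n_frames(ensemble)
  idx_list <- purrr::map2(res$resno, res$chain,
                          ~sidechain_atom_idx(ensemble$atoms, .x, .y))
  out <- array(NA_real_, dim = c(nrow(res), 3L, nf))
  for (r in seq_len(nrow(res))) {
    idx <- idx_list[[r]]
    w <- ensemble$atoms$mass[idx]
    block <- ensemble$coords[idx, , , drop = FALSE]
    for (f in seq_len(nf)) {
      out[r, , f] <- colSums(block[, , f, drop = FALSE][, , 1, drop = FALSE] * w) / sum(w)
    }
  }
  attr(out, "residues") <- res
  out
}

#' Cα coordinates of an ensemble
#'
#' @param ensemble A [conf_ensemble()].
#' @return Matrix of dimension `n_frames x 3N` (frame-major, xyz interleaved),
#'   with the residue table as attribute `"residues"`.
#' @export
calpha_coords <- function(ensemble) {
  at <- ensemble$atoms
  idx <- which(at$atom == "CA")
  if (length(idx) == 0L) stop("ensemble has no CA atoms", call. = FALSE)
  nf <- n_frames(ensemble)
  m <- matrix(NA_real_, nrow = nf, ncol = 3L * length(idx))
  for (f in seq_len(nf)) m[f, ] <- as.vector(t(ensemble$coords[idx, , f]))
  res <- tibble::tibble(chain = at$chain[idx], resno = at$resno[idx],
                        resid = at$resid[idx])
  res$aa <- dplyr::coalesce(.aa3_to_1[res$resid], "X")
  res$label <- paste0(res$aa, res$resno)
  attr(m, "residues") <- res
  m
}
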