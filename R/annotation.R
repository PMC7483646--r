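#' Functional annotation of a kinase domain
#'
#' Named residue sets (catalytic motifs, spines, mobile loops, ...) plus the
#' domain range, used to define the target classes of the communication-path
#' analysis and the region filters of the mutation curation. The defaults
#' describe the ULK1 kinase domain in UniProt O75385 numbering: the key
#' activity residues (catalytic K46, its salt-bridge partner E63, M62, the
#' activation-loop phosphosite T180 and the acetylation site K162), the DFG
#' (165-167), HRD (136-138) and APE (189-191) motifs, the C-helix (55-65),
#' the catalytic and regulatory spines, and the bipartite activation loop.
#'
#' @param sets Named list of integer position vectors.
#' @param domain_range Length-2 integer vector, closed interval of the domain.
#' @return An object of class `functional_annotation` (a list with elements
#'   `sets` and `domain_range`).
#' @export
functional_annotation <- function(sets, domain_range) {
  stopifnot(is.list(sets), length(domain_range) == 2L,
            domain_range[1] <= domain_range[2])
  if (anyDuplicated(names(sets))) stop("set names must be unique", call. = FALSE)
  sets <- lapply(sets, function(x) sort(unique(as.integer(x))))
  for (nm in names(sets)) {
    out <- sets[[nm]][sets[[nm]] < domain_range[1] | sets[[nm]] > domain_range[2]]
    if (length(out) > 0L) {
      stop("set '", nm, "' has positions outside the domain range [",
           domain_range[1], ", ", domain_range[2], "]: ",
           paste(out, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sets = sets, domain_range = as.integer(domain_range)),
            class = "functional_annotation")
}

#' @export
print.functional_annotation <- function(x, ...) {
  cat("<functional_annotation> domain [", x$domain_range[1], ", ",
      x$domain_range[2], "], ", length(x$sets), " residue sets: ",
      paste(names(x$sets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default ULK1 kinase-domain annotation
#'
#' @return A [functional_annotation()] with the ULK1 residue sets (UniProt
#'   O75385 numbering) and domain range 8-280.
#' @export
ulk1_annotation <- function() {
  functional_annotation(
    sets = list(
      activity = c(46L, 63L, 62L, 180L, 162L),
      DFG = 165:167,
      HRD = 136:138,
      APE = 189:191,
      chelix = 55:65,
      cspine = c(21L, 30L, 44L, 145L, 144L, 146L, 210L, 214L),
      rspine = c(203L, 136L, 166L, 67L, 78L),
      activation_loop = c(165:174, 178:191)
    ),
    domain_range = c(8L, 280L)
  )
}

#' Load a functional annotation from a YAML config
#'
#' The config may declare `domain_range: [lo, hi]` and a `sets:` mapping of
#' set names to position lists; ranges can be written as strings `"165-167"`.
#' Omitted fields fall back to the ULK1 defaults of [ulk1_annotation()].
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A [functional_annotation()].
#' @export
load_annotation_config <- function(path = NULL) {
  dflt <- ulk1_annotation()
  if (is.null(path)) return(dflt)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  rng <- if (!is.null(cfg$domain_range)) as.integer(unlist(cfg$domain_range)) else dflt$domain_range
  sets <- if (!is.null(cfg$sets)) lapply(cfg$sets, parse_position_spec) else dflt$sets
  functional_annotation(sets, rng)
}

# "165-167", c(1, "5-7"), or plain integers -> integer vector
parse_position_spec <- function(x) {
  unlist(lapply(x, function(el) {
    if (is.numeric(el)) return(as.integer(el))
    el <- as.character(el)
    if (grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", el)) {
      parts <- as.integer(strsplit(el, "-")[[1]])
      return(seq(parts[1], parts[2]))
    }
    as.integer(el)
  }))
}
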