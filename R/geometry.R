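#' Packaged default spin geometry (synthetic)
#'
#' A fixed 15N-centric distance fixture qualitatively matching the
#' intermolecular geometry of a parallel-in-register cross-beta stack:
#' 5 carbons of the succeeding chain and 8 of the preceding chain, all in
#' the 4.1-5.8 Angstrom range, of which 9 lie within 5.5 Angstrom (the
#' truncation used for the two-sided C-N-C mode). These values are a
#' synthetic fixture chosen for the packaged generator - they are NOT
#' extracted from a deposited fibril structure; use
#' [geometry_from_structure()] on a real structure for measured lists.
#'
#' @param cnc_radius Truncation radius for the C-N-C mode (Angstrom);
#'   stored as an attribute for downstream use.
#' @return A [spin_geometry()] with attribute `cnc_radius`.
#' @export
default_spin_geometry <- function(cnc_radius = 5.5) {
  g <- spin_geometry(
    distances_succeeding = c(4.1, 4.6, 5.2, 5.6, 5.8),
    distances_preceding = c(4.3, 4.5, 4.8, 5.0, 5.2, 5.4, 5.7, 5.8),
    cutoff_radius = 5.8)
  attr(g, "cnc_radius") <- cnc_radius
  g
}

#' Idealized parallel-in-register protofilament coordinates (synthetic)
#'
#' Builds a toy cross-beta stack: `n_chains` identical extended strands of
#' `n_residues` alanine-like residues (atoms N, CA, C, O, CB), translated
#' along +z by `spacing` Angstrom per chain with no twist, i.e. perfectly
#' in register. Every atom of chain k+1 sits directly above its
#' counterpart in chain k, so 15N-13C distances are analytically
#' `sqrt(dxy^2 + spacing^2)` with dxy the in-plane N-carbon distance. The
#' default spacing of 4.8 Angstrom is the canonical hydrogen-bonded
#' beta-strand separation.
#'
#' @param n_chains Number of stacked chains (>= 3 so a central chain has
#'   both neighbours).
#' @param spacing Inter-strand rise along z in Angstrom.
#' @param n_residues Residues per strand.
#' @return An atom tibble with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`.
#' @export
generate_toy_protofilament <- function(n_chains = 5, spacing = 4.8,
                                       n_residues = 5) {
  if (n_chains < 3) abort("`n_chains` must be >= 3 (central chain needs both neighbours).")
  # extended-strand template, ~3.5 A per residue along x, alternating pleat
  template <- purrr::map_dfr(seq_len(n_residues), function(i) {
    x0 <- 3.5 * (i - 1)
    pleat <- 0.6 * (-1)^i
    tibble(
      resno = i,
      resid = "ALA",
      elety = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = x0 + c(0.0, 1.2, 2.4, 2.4, 1.2),
      y = pleat + c(0.0, 0.6, 0.0, -1.2, 1.9),
      z = 0
    )
  })
  purrr::map_dfr(seq_len(n_chains), function(k) {
    dplyr::mutate(template, chain = LETTERS[k], z = spacing * (k - 1),
                  .before = 1)
  })
}

#' Coerce a structure to the internal atom tibble
#'
#' Accepts a `bio3d` `pdb` object (from [bio3d::read.pdb()] or
#' [bio3d::read.cif()]), a file path to a PDB/mmCIF file, or an atom
#' tibble already in the internal layout.
#'
#' @param structure A `pdb` object, file path, or atom tibble.
#' @return An atom tibble with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`.
#' @export
as_atom_tibble <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    structure <- read_structure(structure)
  }
  if (inherits(structure, "pdb")) {
    a <- structure$atom
    elem <- a$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- substr(trimws(a$elety), 1, 1)
    }
    return(tibble(chain = a$chain, resno = a$resno, resid = a$resid,
                  elety = trimws(a$elety), element = trimws(elem),
                  x = a$x, y = a$y, z = a$z))
  }
  if (is.data.frame(structure)) {
    need <- c("chain", "resno", "elety", "element", "x", "y", "z")
    if (!all(need %in% names(structure))) {
      abort(paste("Atom tibble must have columns:", paste(need, collapse = ", ")))
    }
    return(as_tibble(structure))
  }
  abort("`structure` must be a bio3d pdb object, a file path, or an atom tibble.")
}

#' Read a PDB or mmCIF structure file
#'
#' Thin dispatch over [bio3d::read.pdb()] and [bio3d::read.cif()] by file
#' extension.
#'
#' @param path Structure file (.pdb or .cif/.mmcif).
#' @return A `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("Structure file '%s' not found.", path))
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
}

#' Extract 15N-centric distance lists from a stacked structure
#'
#' Takes the backbone amide N of `ref_residue` in a central chain of a
#' parallel-in-register stack and lists its distances to all carbon atoms
#' of the chain stacked above it along +z ("succeeding") and the chain
#' below ("preceding"), truncated at `radius`. Chains are ordered by their
#' mean z coordinate (the fibril axis is taken as +z of the input frame);
#' both one-sided lists are always returned so the succeeding/preceding
#' assignment can be swapped downstream if the axis orientation of the
#' deposited structure is reversed.
#'
#' @param structure Anything accepted by [as_atom_tibble()].
#' @param ref_residue Residue number carrying the reference 15N.
#' @param radius Truncation radius in Angstrom (e.g. 5.8 or 5.5 for 9-spin
#'   variants, 8.8 for the long-range variant).
#' @param ref_chain Chain identifier of the reference chain; defaults to
#'   the central chain of the stack.
#' @param nat_abund_rate Passed through to [spin_geometry()].
#' @return A [spin_geometry()] with attribute `counts` (carbons found per
#'   side).
#' @export
geometry_from_structure <- function(structure, ref_residue, radius = 5.8,
                                    ref_chain = NULL,
                                    nat_abund_rate = nat_abund_rate_from_anchor()) {
  atoms <- as_atom_tibble(structure)
  order_tbl <- atoms |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(zbar = mean(.data$z), .groups = "drop") |>
    dplyr::arrange(.data$zbar)
  if (nrow(order_tbl) < 3) {
    abort("Need at least 3 stacked chains to define both neighbours.")
  }
  if (is.null(ref_chain)) {
    ref_chain <- order_tbl$chain[ceiling(nrow(order_tbl) / 2)]
  }
  idx <- match(ref_chain, order_tbl$chain)
  if (is.na(idx)) abort(sprintf("Chain '%s' not present in the structure.", ref_chain))
  if (idx == 1 || idx == nrow(order_tbl)) {
    abort(sprintf("Chain '%s' is terminal: it lacks a neighbour on one side.", ref_chain))
  }
  ref_n <- atoms |>
    dplyr::filter(.data$chain == ref_chain, .data$resno == ref_residue,
                  .data$elety == "N")
  if (nrow(ref_n) == 0) {
    abort(sprintf("Residue %s of chain '%s' has no backbone amide N in the structure.",
                  ref_residue, ref_chain))
  }
  ref_n <- ref_n[1, ]
  side_distances <- function(side_chain) {
    carbons <- dplyr::filter(atoms, .data$chain == side_chain,
                             .data$element == "C")
    d <- sqrt((carbons$x - ref_n$x)^2 + (carbons$y - ref_n$y)^2 +
                (carbons$z - ref_n$z)^2)
    sort(d[d <= radius])
  }
  succ <- side_distances(order_tbl$chain[idx + 1])
  prec <- side_distances(order_tbl$chain[idx - 1])
  g <- spin_geometry(succ, prec, cutoff_radius = radius,
                     nat_abund_rate = nat_abund_rate)
  attr(g, "counts") <- c(succeeding = length(succ), preceding = length(prec))
  attr(g, "ref") <- list(chain = ref_chain, resno = ref_residue)
  g
}
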