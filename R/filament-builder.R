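#' Replicate a protofilament seed into a long helical filament
#'
#' Rigid-body helical replication: monomer k (k = 0, 1, ...) of each
#' protofilament is the seed monomer rotated by `k * twist` degrees about
#' the fibril axis (the +z axis of the input frame) and translated by
#' `k * rise` Angstrom along it. The defaults (4.7 Angstrom rise, 1 degree
#' twist per monomer) describe a paired-helical-filament-like geometry in
#' which a full turn spans 360 monomers (~170 nm). The twist is
#' left-handed by default, consistent with known PHF helicity, and is
#' applied about the shared axis for all protofilaments.
#'
#' @param seed Atom tibble (see [as_atom_tibble()]); a column `proto`
#'   labels protofilaments (added as `"P1"` if absent). Each protofilament
#'   seed is treated as one monomer.
#' @param n_monomers Monomers per protofilament in the output.
#' @param rise Axial rise per monomer in Angstrom.
#' @param twist Twist per monomer in degrees (magnitude).
#' @param handedness `"left"` (default) or `"right"`.
#' @return An object of class `filament_model`: list with `atoms` (tibble
#'   with `proto`, `monomer`, atom columns), `n_monomers`, `rise`,
#'   `twist`, `handedness`, `isoforms` (NULL until
#'   [assign_isoforms()]).
#' @examples
#' seed <- generate_toy_protofilament(1, n_residues = 2)
#' seed$proto <- "P1"
#' fil <- replicate_helix(seed, n_monomers = 10)
#' axial_length(fil)
#' @export
replicate_helix <- function(seed, n_monomers, rise = 4.7, twist = 1.0,
                            handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  seed <- as_atom_tibble_filament(seed)
  if (!is.numeric(n_monomers) || n_monomers < 1) {
    abort("`n_monomers` must be >= 1.")
  }
  if (!is.numeric(rise) || !is.finite(rise) || rise == 0) {
    abort("Degenerate axis: `rise` must be a nonzero finite number.")
  }
  n_monomers <- as.integer(n_monomers)
  sign_twist <- if (handedness == "left") -1 else 1
  atoms <- purrr::map_dfr(seq_len(n_monomers) - 1L, function(k) {
    th <- sign_twist * k * twist * pi / 180
    co <- cos(th)
    si <- sin(th)
    dplyr::mutate(seed,
                  monomer = k + 1L,
                  x_new = co * .data$x - si * .data$y,
                  y_new = si * .data$x + co * .data$y,
                  z = .data$z + k * rise) |>
      dplyr::mutate(x = .data$x_new, y = .data$y_new) |>
      dplyr::select(-"x_new", -"y_new")
  })
  atoms <- dplyr::relocate(atoms, "proto", "monomer")
  structure(
    list(atoms = atoms, n_monomers = n_monomers, rise = rise, twist = twist,
         handedness = handedness, isoforms = NULL),
    class = "filament_model")
}

# internal: seed coercion that tolerates a missing proto column
as_atom_tibble_filament <- function(seed) {
  atoms <- as_atom_tibble(seed)
  if (!"proto" %in% names(atoms)) atoms$proto <- "P1"
  atoms
}

#' @export
print.filament_model <- function(x, ...) {
  protos <- unique(x$atoms$proto)
  cat(sprintf(
    "Helical filament model: %d protofilament(s) x %d monomers (%d atoms)\n",
    length(protos), x$n_monomers, nrow(x$atoms)))
  cat(sprintf("  rise %.2f A, twist %.2f deg/monomer (%s-handed), length %.1f nm\n",
              x$rise, x$twist, x$handedness, axial_length(x)))
  if (!is.null(x$isoforms)) cat("  isoforms assigned per monomer\n")
  invisible(x)
}

#' Axial length of a filament model
#'
#' Axial extent spanned by the monomer stack, `n_monomers * rise`,
#' reported in nm. 360 monomers at 4.7 Angstrom rise give 169.2 nm
#' (~170 nm).
#'
#' @param model A `filament_model`.
#' @return Length in nm.
#' @export
axial_length <- function(model) {
  stopifnot(inherits(model, "filament_model"))
  model$n_monomers * model$rise / 10
}

#' Annotate a filament model with isoform sequences
#'
#' Attaches one isoform label per monomer per protofilament (simulated
#' independently for each protofilament, e.g. by
#' [simulate_until_match()]). The label is carried in an `isoform` column
#' of the atom table and rendered in output files through a two-level
#' B-factor convention (4R -> 0, 3R -> 50) plus a sidecar JSON.
#'
#' @param model A `filament_model`.
#' @param chains A single `isoform_chain` (recycled check: only when one
#'   protofilament) or a named list, one chain per protofilament; lengths
#'   must equal `n_monomers`.
#' @return The annotated `filament_model`.
#' @export
assign_isoforms <- function(model, chains) {
  stopifnot(inherits(model, "filament_model"))
  protos <- unique(model$atoms$proto)
  if (inherits(chains, "isoform_chain")) {
    if (length(protos) != 1L) {
      abort("Supply one chain per protofilament (a named list).")
    }
    chains <- setNames(list(chains), protos)
  }
  if (!setequal(names(chains), protos)) {
    abort(sprintf("Chain names (%s) must match protofilaments (%s).",
                  paste(names(chains), collapse = ", "),
                  paste(protos, collapse = ", ")))
  }
  for (pn in protos) {
    if (length(chains[[pn]]) != model$n_monomers) {
      abort(sprintf(
        "Chain for protofilament '%s' has %d labels but the model has %d monomers.",
        pn, length(chains[[pn]]), model$n_monomers))
    }
  }
  lookup <- purrr::imap_dfr(chains, function(ch, pn) {
    tibble(proto = pn, monomer = seq_along(ch), isoform = as.character(ch))
  })
  model$atoms <- model$atoms |>
    dplyr::select(-dplyr::any_of("isoform")) |>
    dplyr::left_join(lookup, by = c("proto", "monomer"))
  model$isoforms <- purrr::map(chains, as.character)
  model
}

#' Write a filament model as mmCIF (with a label sidecar)
#'
#' Writes a minimal mmCIF `atom_site` loop (the format required for
#' models beyond the 99,999-atom fixed-width PDB serial limit), carrying
#' the monomer index in `label_entity_id`, the protofilament in
#' `auth_asym_id`, and the isoform (when assigned) as a two-level B factor
#' (4R -> 0.00, 3R -> 50.00). Model-level metadata (rise, twist,
#' handedness, per-monomer isoform strings) is stored in a `_fibril_model`
#' category so [read_filament_cif()] can rebuild the object. A sidecar
#' JSON of per-monomer isoform labels is written next to the file when
#' labels are assigned.
#'
#' @param model A `filament_model`.
#' @param path Output path (`.cif`).
#' @param sidecar Write the isoform sidecar JSON (`<path>.labels.json`)?
#' @return Invisibly, `path`.
#' @export
write_filament_cif <- function(model, path, sidecar = TRUE) {
  stopifnot(inherits(model, "filament_model"))
  a <- model$atoms
  n <- nrow(a)
  b <- if (!is.null(a[["isoform"]])) ifelse(a$isoform == "3R", 50, 0) else rep(0, n)
  asym <- paste0(a$proto, a$monomer)
  lines <- c(
    "data_fibrilmix_model",
    "#",
    sprintf("_fibril_model.n_monomers %d", model$n_monomers),
    sprintf("_fibril_model.rise %.6f", model$rise),
    sprintf("_fibril_model.twist %.6f", model$twist),
    sprintf("_fibril_model.handedness %s", model$handedness),
    if (!is.null(model$isoforms)) {
      vapply(names(model$isoforms), function(pn) {
        sprintf("_fibril_model.isoforms_%s %s", pn,
                chain_to_string(model$isoforms[[pn]]))
      }, "")
    },
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_asym_id",
    sprintf("ATOM %d %s %s %s %s %d %d %.4f %.4f %.4f 1.00 %.2f %s",
            seq_len(n), a$element, a$elety,
            a[["resid"]] %||% rep("ALA", n), asym, a$monomer, a$resno,
            a$x, a$y, a$z, b, a$proto),
    "#")
  writeLines(lines, path)
  if (sidecar && !is.null(model$isoforms)) {
    jsonlite::write_json(
      purrr::map(model$isoforms, ~ unname(as.character(.x))),
      paste0(path, ".labels.json"))
  }
  invisible(path)
}

#' Read back a filament model written by [write_filament_cif()]
#'
#' Parses the `_fibril_model` metadata and the `atom_site` loop of files
#' produced by this package (it is not a general mmCIF reader; use
#' [read_structure()] for arbitrary deposited files).
#'
#' @param path A `.cif` file written by [write_filament_cif()].
#' @return A `filament_model`.
#' @export
read_filament_cif <- function(path) {
  lines <- readLines(path)
  meta <- function(key) {
    ln <- grep(paste0("^_fibril_model\\.", key, " "), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^_fibril_model\\.", key, " "), "", ln[1])
  }
  atom_lines <- grep("^ATOM ", lines, value = TRUE)
  f <- strsplit(atom_lines, " +")
  m <- do.call(rbind, f)
  atoms <- tibble(
    proto = m[, 14],
    monomer = as.integer(m[, 7]),
    resno = as.integer(m[, 8]),
    resid = m[, 5],
    elety = m[, 4],
    element = m[, 3],
    x = as.numeric(m[, 9]),
    y = as.numeric(m[, 10]),
    z = as.numeric(m[, 11])
  )
  b <- as.numeric(m[, 13])
  iso_keys <- grep("^_fibril_model\\.isoforms_", lines, value = TRUE)
  isoforms <- NULL
  if (length(iso_keys) > 0) {
    isoforms <- purrr::map(iso_keys, function(ln) {
      as.character(chain_from_string(sub("^\\S+ ", "", ln)))
    })
    names(isoforms) <- sub("^_fibril_model\\.isoforms_(\\S+) .*$", "\\1", iso_keys)
    lookup <- purrr::imap_dfr(isoforms, function(ch, pn) {
      tibble(proto = pn, monomer = seq_along(ch), isoform = ch)
    })
    atoms <- dplyr::left_join(atoms, lookup, by = c("proto", "monomer"))
  } else if (any(b > 0)) {
    atoms$isoform <- ifelse(b >= 25, "3R", "4R")
  }
  structure(
    list(atoms = atoms,
         n_monomers = as.integer(meta("n_monomers")),
         rise = as.numeric(meta("rise")),
         twist = as.numeric(meta("twist")),
         handedness = meta("handedness") %||% "left",
         isoforms = isoforms),
    class = "filament_model")
}

#' Write a small filament model in PDB format
#'
#' Fixed-width PDB output for models of at most 99,999 atoms (the serial
#' field width); larger models must use [write_filament_cif()]. The chain
#' identifier is the protofilament and residue numbers are offset per
#' monomer so every residue is unique; the isoform two-level B-factor
#' convention matches the mmCIF writer.
#'
#' @param model A `filament_model`.
#' @param path Output path (`.pdb`).
#' @return Invisibly, `path`.
#' @export
write_filament_pdb <- function(model, path) {
  stopifnot(inherits(model, "filament_model"))
  a <- model$atoms
  if (nrow(a) > 99999) {
    abort("PDB output is limited to 99,999 atoms; write mmCIF instead.")
  }
  chain1 <- substr(a$proto, nchar(a$proto), nchar(a$proto))
  resno_offset <- (a$monomer - 1L) * max(a$resno)
  b <- if (!is.null(a[["isoform"]])) ifelse(a$isoform == "3R", 50, 0) else rep(0, nrow(a))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), a$elety, " ", (a[["resid"]] %||% "ALA"), chain1,
    a$resno + resno_offset, " ", a$x, a$y, a$z, 1, b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
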