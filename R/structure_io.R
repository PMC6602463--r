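#' Van der Waals radii (Bondi) used for clearance computation
#'
#' Element-to-radius map in angstroms. Unknown elements fall back to the
#' `default` entry (1.70, the carbon value). Pass a modified copy to
#' [assign_radii()] to override.
#'
#' @return Named numeric vector of radii in angstroms.
#' @export
#' @examples
#' bondi_radii()[["C"]]
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, default = 1.70)
}

#' Atomic masses used for centre-of-mass starting points
#' @return Named numeric vector of atomic masses (u); `default` covers
#'   unrecognized elements.
#' @export
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, default = 12.011)
}

# element from PDB columns 77-78 with fallback to the atom-name field
infer_element <- function(elesy, name, hetero) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Za-z]", "", name[miss]))
    two <- substr(nm, 1, 2)
    known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "CU", "SE")
    # two-letter symbols are trusted for hetero groups only: in polymers "CA"
    # is an alpha carbon, not calcium
    el2 <- ifelse(hetero[miss] & two %in% known2, two, substr(nm, 1, 1))
    el2[grepl("^[0-9]*H", toupper(name[miss]))] <- "H"
    el[miss] <- el2
  }
  el
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records of one model into an atom
#' table. Only blank and 'A' alternate-location indicators are kept. Elements
#' come from PDB columns 77-78, falling back to the atom-name field.
#'
#' @param path Path to a PDB file.
#' @param model_index Model to read (1-based) for multi-model files.
#' @param keep_hetero Keep HETATM records?
#' @return A tibble with one row per atom: `serial`, `element`, `name`,
#'   `resname`, `chain`, `resno`, `ins`, `x`, `y`, `z`, `is_hetero`,
#'   `considered` (initially `TRUE` for all atoms). Radii are added by
#'   [assign_radii()].
#' @export
read_structure <- function(path, model_index = 1L, keep_hetero = TRUE) {
  if (!file.exists(path)) stop_input("structure file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_input("failed to parse PDB %s: %s", path,
                                   conditionMessage(e)))
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod) {
    stop_input("model %d requested but file has %d model(s)", model_index, nmod)
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  if (!any(keep)) stop_input("no atoms parsed from %s", path)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  hetero <- at$type == "HETATM"
  tibble::tibble(
    serial = as.integer(at$eleno),
    element = infer_element(at$elesy, at$elety, hetero),
    name = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hetero = hetero,
    considered = TRUE
  )
}

#' Write an atom table back to a PDB file
#'
#' @param structure Atom table as returned by [read_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  n <- nrow(structure)
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path,
    type = ifelse(structure$is_hetero, "HETATM", "ATOM"),
    xyz = xyz,
    resno = structure$resno,
    resid = structure$resname,
    eleno = structure$serial %||% seq_len(n),
    elety = structure$name,
    chain = structure$chain,
    insert = structure$ins,
    elesy = structure$element,
    o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}

#' Assign van der Waals radii to every atom
#'
#' @param structure Atom table.
#' @param table Named element-to-angstrom map containing a `default` entry;
#'   see [bondi_radii()].
#' @return The atom table with a `vdw_radius` column.
#' @export
assign_radii <- function(structure, table = bondi_radii()) {
  req <- c("H", "C", "N", "O", "S", "P", "default")
  if (!all(req %in% names(table))) {
    stop_input("radius table must cover %s", paste(req, collapse = ", "))
  }
  el <- toupper(structure$element)
  r <- unname(table[el])
  r[is.na(r)] <- table[["default"]]
  dplyr::mutate(structure, vdw_radius = r)
}

#' Select the atoms considered for tunnel calculation
#'
#' Flags all polymer (ATOM) atoms as considered; HETATM groups are considered
#' only when their residue name is listed, and water never is (when
#' `exclude_water`).
#'
#' @param structure Atom table.
#' @param exclude_water Drop HOH/WAT even if listed?
#' @param include_het_names Character vector of HETATM residue names to keep.
#' @return The atom table with an updated `considered` mask.
#' @export
select_considered <- function(structure, exclude_water = TRUE,
                              include_het_names = character()) {
  mask <- !structure$is_hetero |
    structure$resname %in% include_het_names
  if (exclude_water) mask <- mask & !(structure$resname %in% c("HOH", "WAT"))
  out <- dplyr::mutate(structure, considered = mask)
  if (sum(mask) < 5) {
    stop_input("selection leaves %d considered atoms; at least 5 are needed",
               sum(mask))
  }
  out
}

considered_atoms <- function(structure) {
  s <- dplyr::filter(structure, .data$considered)
  if (!"vdw_radius" %in% names(s)) {
    stop_input("structure has no vdw_radius column; run assign_radii() first")
  }
  s
}

coords_matrix <- function(structure) {
  unname(as.matrix(structure[, c("x", "y", "z")]))
}

#' Write tunnel spheres as a HETATM-only PDB file
#'
#' One HETATM record per sphere (residue name TUN), with the sphere radius
#' stored in the B-factor column to two decimals.
#'
#' @param spheres Data frame or tibble with columns `x`, `y`, `z`, `radius`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spheres_pdb <- function(spheres, path) {
  if (nrow(spheres) == 0) stop_input("no spheres to write")
  lines <- sprintf(
    "HETATM%5d  S   TUN T%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(spheres)),
    seq_len(nrow(spheres)) %% 10000,
    spheres$x, spheres$y, spheres$z, 1, spheres$radius, "S")
  ok <- tryCatch({
    writeLines(c(lines, "END"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_input("cannot write %s", path)
  invisible(path)
}
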