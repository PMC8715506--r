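#' Structure models and coordinate ensembles
#'
#' `allokit` keeps topology and coordinates separate, the way trajectory
#' analysis tools usually do. A *structure model* holds per-atom records
#' (residue id, atom name, element, heavy-atom flag) plus the C-alpha index
#' and an optional generic-label map (e.g. Ballesteros-Weinstein numbers for
#' a GPCR). An *ensemble* is a frames x atoms x 3 coordinate array, in
#' Angstrom, carrying a class label such as `"nb80"` or `"apo"`.
#'
#' @name structure_model
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with one row per atom, in file order, and columns
#'   `residue_id` (integer), `resname`, `chain`, `atom_name`, `element`,
#'   `x`, `y`, `z` (reference coordinates, Angstrom).
#' @param label_map Optional named integer vector mapping generic residue
#'   labels (e.g. `"3.50"`) to residue ids.
#' @return A `structure_model` object.
#' @export
new_structure_model <- function(atoms, label_map = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("residue_id", "resname", "chain", "atom_name", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure has zero atoms")
  atoms$atom <- seq_len(nrow(atoms))
  atoms$is_heavy <- toupper(atoms$element) != "H"
  atoms$is_ca <- atoms$atom_name == "CA"

  # residue identity is (chain, residue number); ids must be unambiguous
  res_tab <- unique(atoms[, c("chain", "residue_id")])
  if (anyDuplicated(res_tab$residue_id)) {
    abort("residue numbers are reused across chains; renumber to make residue ids unique")
  }
  for (ch in unique(res_tab$chain)) {
    ids <- res_tab$residue_id[res_tab$chain == ch]
    if (any(diff(ids) <= 0)) {
      abort(sprintf("residue ids not strictly increasing within chain '%s'", ch))
    }
  }
  residue_ids <- res_tab$residue_id

  heavy_per_res <- tapply(atoms$is_heavy, atoms$residue_id, any)
  if (!all(heavy_per_res)) {
    bad <- names(heavy_per_res)[!heavy_per_res]
    abort(paste0("residue(s) without any heavy atom: ", paste(bad, collapse = ", ")))
  }

  ca_rows <- atoms[atoms$is_ca, ]
  ca_index <- stats::setNames(ca_rows$atom, ca_rows$residue_id)
  is_aa <- tapply(atoms$resname %in% STANDARD_AA, atoms$residue_id, any)
  aa_ids <- as.integer(names(is_aa)[is_aa])
  missing_ca <- setdiff(aa_ids, as.integer(names(ca_index)))
  if (length(missing_ca) > 0) {
    abort(paste0("amino-acid residue(s) missing a CA atom: ", paste(missing_ca, collapse = ", ")))
  }

  model <- structure(
    list(
      atoms = atoms,
      residue_ids = residue_ids,
      ca_index = ca_index,
      label_map = NULL
    ),
    class = "structure_model"
  )
  if (!is.null(label_map)) model <- set_label_map(model, label_map)
  model
}

#' Read a topology file into a structure model
#'
#' Supports PDB and GRO (GROMACS) topologies. GRO coordinates are converted
#' from nm to Angstrom on load so that all distance thresholds in the
#' package are in Angstrom. Hydrogens are retained but flagged, so
#' closest-heavy-atom computations can exclude them.
#'
#' @param path Path to a `.pdb` or `.gro` file.
#' @param label_map Optional named integer vector or path to a two-column
#'   TSV (label, residue id), see [read_label_map()].
#' @return A `structure_model`.
#' @export
read_structure <- function(path, label_map = NULL) {
  if (!file.exists(path)) abort(sprintf("topology file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  atoms <- switch(ext,
    pdb = {
      lines <- readLines(path, warn = FALSE)
      starts <- which(trimws(substr(lines, 1, 6)) == "MODEL")
      if (length(starts) > 1) lines <- lines[starts[1]:(starts[2] - 1)]
      parse_pdb_atoms(lines)
    },
    gro = parse_gro_atoms(readLines(path, warn = FALSE)),
    abort(sprintf("unsupported topology format '.%s' (expected .pdb or .gro)", ext))
  )
  if (is.character(label_map) && length(label_map) == 1) {
    label_map <- read_label_map(label_map)
  }
  new_structure_model(atoms, label_map = label_map)
}

element_from_name <- function(atom_name) {
  stripped <- sub("^[0-9']+", "", trimws(atom_name))
  toupper(substr(stripped, 1, 1))
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_lines <- lines[trimws(rec) %in% c("ATOM", "HETATM")]
  if (length(atom_lines) == 0) abort("no ATOM/HETATM records found")
  icode <- trimws(substr(atom_lines, 27, 27))
  if (any(icode != "")) {
    abort("insertion codes are not supported; renumber residues first")
  }
  name <- trimws(substr(atom_lines, 13, 16))
  element <- trimws(substr(atom_lines, 77, 78))
  blank <- element == ""
  if (any(blank)) {
    warn(sprintf(
      "%d atom(s) without an element symbol; classifying by atom-name prefix",
      sum(blank)
    ))
    element[blank] <- element_from_name(name[blank])
  }
  known <- c(
    "H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "SE", "FE", "ZN",
    "MG", "CA", "NA", "K", "MN", "CU"
  )
  odd <- !(toupper(element) %in% known)
  if (any(odd)) {
    warn(sprintf(
      "unknown element symbol(s) %s; classifying by atom-name prefix",
      paste(unique(element[odd]), collapse = ", ")
    ))
    element[odd] <- element_from_name(name[odd])
  }
  chain <- substr(atom_lines, 22, 22)
  chain[chain == " "] <- "A"
  tibble(
    residue_id = as.integer(substr(atom_lines, 23, 26)),
    resname = trimws(substr(atom_lines, 18, 20)),
    chain = chain,
    atom_name = name,
    element = element,
    x = as.numeric(substr(atom_lines, 31, 38)),
    y = as.numeric(substr(atom_lines, 39, 46)),
    z = as.numeric(substr(atom_lines, 47, 54))
  )
}

parse_gro_atoms <- function(lines) {
  if (length(lines) < 3) abort("GRO file too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1) abort("invalid atom count in GRO file")
  if (length(lines) < 2 + n) abort("GRO file truncated")
  al <- lines[3:(2 + n)]
  name <- trimws(substr(al, 11, 15))
  tibble(
    residue_id = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    chain = "A",
    atom_name = name,
    element = element_from_name(name),
    # GRO stores nm; convert to Angstrom
    x = as.numeric(substr(al, 21, 28)) * 10,
    y = as.numeric(substr(al, 29, 36)) * 10,
    z = as.numeric(substr(al, 37, 44)) * 10
  )
}

#' Construct an ensemble from a coordinate array
#'
#' @param coords Numeric array, frames x atoms x 3, Angstrom.
#' @param class_label Class label string for the ensemble.
#' @param model Optional `structure_model` to validate the atom count against.
#' @return An `ensemble` object.
#' @export
new_ensemble <- function(coords, class_label, model = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) abort("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) abort("ensemble coordinates must be finite")
  if (!is.null(model) && dim(coords)[2] != nrow(model$atoms)) {
    abort(sprintf(
      "atom-count mismatch: trajectory has %d atoms, model has %d",
      dim(coords)[2], nrow(model$atoms)
    ))
  }
  structure(
    list(
      coords = coords,
      class_label = as.character(class_label),
      frame_count = dim(coords)[1]
    ),
    class = "ensemble"
  )
}

#' Read a trajectory into an ensemble
#'
#' Reads a multi-model PDB trajectory against an existing structure model.
#' Binary trajectory formats (XTC, DCD) are not supported by this package:
#' convert them to multi-model PDB with any trajectory tool first.
#'
#' @param path Path to a multi-model PDB file.
#' @param model `structure_model` the trajectory belongs to.
#' @param label Class label to attach (e.g. ligand or nanobody condition).
#' @return An `ensemble`.
#' @export
read_ensemble <- function(path, model, label) {
  if (!file.exists(path)) abort(sprintf("trajectory file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "dcd", "trr")) {
    abort(sprintf(
      "binary trajectory format '.%s' is not supported; convert to multi-model PDB first",
      ext
    ))
  }
  if (ext != "pdb") abort(sprintf("unsupported trajectory format '.%s'", ext))
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  model_starts <- which(rec == "MODEL")
  frames <- if (length(model_starts) == 0) {
    list(parse_pdb_atoms(lines))
  } else {
    ends <- c(model_starts[-1] - 1, length(lines))
    purrr::map2(model_starts, ends, function(s, e) parse_pdb_atoms(lines[s:e]))
  }
  n_atoms <- nrow(model$atoms)
  counts <- vapply(frames, nrow, integer(1))
  if (any(counts != n_atoms)) {
    abort(sprintf(
      "atom-count mismatch: trajectory frame has %d atoms, model has %d",
      counts[which(counts != n_atoms)[1]], n_atoms
    ))
  }
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
  for (f in seq_along(frames)) {
    coords[f, , ] <- as.matrix(frames[[f]][, c("x", "y", "z")])
  }
  new_ensemble(coords, label, model = model)
}

pdb_atom_line <- function(serial, name, resname, chain, resid, xyz, bfactor = 0,
                          element = "") {
  # names shorter than 4 characters start in column 14, per PDB convention
  name_field <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial %% 100000, name_field, substr(resname, 1, 3), substr(chain, 1, 1),
    resid %% 10000, xyz[1], xyz[2], xyz[3], 1.0, bfactor, substr(element, 1, 2)
  )
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble An `ensemble`.
#' @param model The matching `structure_model`.
#' @param path Output path.
#' @param bfactor Optional per-atom vector stamped into the B-factor column
#'   of every frame (used e.g. to colour structures by residue importance).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, model, path, bfactor = NULL) {
  atoms <- model$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(atoms))
  stopifnot(length(bfactor) == nrow(atoms))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(ensemble$frame_count)) {
    writeLines(sprintf("MODEL %8d", f), con)
    lines <- vapply(seq_len(nrow(atoms)), function(a) {
      pdb_atom_line(
        a, atoms$atom_name[a], atoms$resname[a], atoms$chain[a],
        atoms$residue_id[a], ensemble$coords[f, a, ], bfactor[a],
        element = atoms$element[a]
      )
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a generic-label map from a two-column TSV
#'
#' The file maps generic residue labels (e.g. Ballesteros-Weinstein numbers
#' such as `3.50`) to residue ids; columns are label then residue id, with
#' or without a header line.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector (names are labels).
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("label map file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(raw) != 2) abort("label map must have exactly two tab-separated columns")
  if (is.na(suppressWarnings(as.integer(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  stats::setNames(as.integer(raw[[2]]), trimws(raw[[1]]))
}

#' Attach a generic-label map to a structure model
#'
#' @param model A `structure_model`.
#' @param label_map Named integer vector, label -> residue id.
#' @return The model with `label_map` set.
#' @export
set_label_map <- function(model, label_map) {
  stopifnot(inherits(model, "structure_model"))
  ids <- as.integer(label_map)
  if (is.null(names(label_map)) || any(names(label_map) == "")) {
    abort("label_map must be a named vector (names are the generic labels)")
  }
  outside <- setdiff(ids, model$residue_ids)
  if (length(outside) > 0) {
    abort(paste0(
      "label_map refers to residue id(s) absent from the model: ",
      paste(outside, collapse = ", ")
    ))
  }
  model$label_map <- stats::setNames(ids, names(label_map))
  model
}

#' Resolve a generic residue label to a residue id
#'
#' @param model A `structure_model` with a label map attached.
#' @param label Generic label string, e.g. `"3.50"`.
#' @return The mapped residue id (integer).
#' @export
resolve_label <- function(model, label) {
  if (is.null(model$label_map)) abort("model has no label map attached")
  if (!label %in% names(model$label_map)) {
    abort(sprintf("unknown residue label '%s'", label))
  }
  unname(model$label_map[[label]])
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d residues, %d atoms (%d heavy), %d CA, label map: %s\n",
    length(x$residue_ids), nrow(x$atoms), sum(x$atoms$is_heavy),
    length(x$ca_index),
    if (is.null(x$label_map)) "none" else paste(length(x$label_map), "labels")
  ))
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> class '%s': %d frames x %d atoms\n",
    x$class_label, x$frame_count, dim(x$coords)[2]
  ))
  invisible(x)
}

heavy_atoms_of <- function(model, residue_id) {
  a <- model$atoms
  a$atom[a$residue_id == residue_id & a$is_heavy]
}

ca_of <- function(model, residue_id) {
  key <- as.character(residue_id)
  if (!key %in% names(model$ca_index)) {
    abort(sprintf("residue %s has no CA atom", key))
  }
  unname(model$ca_index[[key]])
}
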