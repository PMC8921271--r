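#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number distinct pull rename across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dnorm median sd cor lm coef setNames rnorm runif rpois
#' @importFrom utils head tail write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Crystal cell ---------------------------------------------------------------

#' Construct a crystal cell
#'
#' A unit cell is described by its edge lengths (angstroms), angles (degrees)
#' and the space-group symmetry operators expressed in fractional coordinates.
#'
#' @param a,b,c Cell edge lengths in angstroms. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param symops List of symmetry operators as returned by [parse_symop()].
#'   Must contain at least the identity; defaults to P1 (identity only).
#' @return An object of class `crystal_cell`.
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         symops = list(parse_symop("X,Y,Z"))) {
  stopifnot(is.numeric(c(a, b, c, alpha, beta, gamma)))
  if (any(c(a, b, c) <= 0)) {
    abort("Cell edge lengths must be positive.")
  }
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180)) {
    abort("Cell angles must lie strictly between 0 and 180 degrees.")
  }
  if (!length(symops)) {
    abort("Symmetry operator list must contain at least the identity.")
  }
  has_identity <- any(vapply(symops, function(op) {
    isTRUE(all.equal(op$rotation, diag(3))) && all(abs(op$translation) < 1e-9)
  }, logical(1)))
  if (!has_identity) {
    abort("Symmetry operator list must contain the identity operator X,Y,Z.")
  }
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         symops = symops),
    class = "crystal_cell"
  )
}

#' Orthogonalisation matrix of a cell
#'
#' Builds the standard crystallographic orthogonalisation matrix M such that
#' `xyz = M %*% frac` maps fractional coordinates to orthogonal angstroms
#' (a along x, b in the xy-plane).
#'
#' @param cell A `crystal_cell`.
#' @return A 3x3 numeric matrix.
#' @export
orthogonalisation_matrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
}

#' Convert between fractional and orthogonal coordinates
#'
#' @param cell A `crystal_cell`.
#' @param frac,xyz Numeric matrix with one row per atom (columns x, y, z).
#' @return Matrix of the same shape in the other coordinate system.
#' @export
frac_to_orth <- function(cell, frac) {
  frac <- rbind(frac)
  t(orthogonalisation_matrix(cell) %*% t(frac))
}

#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(cell, xyz) {
  xyz <- rbind(xyz)
  t(solve(orthogonalisation_matrix(cell)) %*% t(xyz))
}

# ---------------------------------------------------------------------------
# Symmetry operators ---------------------------------------------------------

#' Parse a symmetry operator string
#'
#' Parses an xyz-style operator such as `"-X,Y+1/2,-Z"` into a rotation
#' matrix and translation vector acting on fractional coordinates.
#'
#' @param text Operator string; case-insensitive, components comma-separated.
#' @return List with elements `rotation` (3x3) and `translation` (length 3),
#'   plus the normalised `text`.
#' @export
parse_symop <- function(text) {
  comps <- strsplit(toupper(gsub("[[:space:]]", "", text)), ",")[[1]]
  if (length(comps) != 3) {
    abort(paste0("Cannot parse symmetry operator '", text, "': expected 3 components."))
  }
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in seq_len(3)) {
    # split into signed terms: -X, +1/2, .5, Y ...
    terms <- regmatches(comps[i],
                        gregexpr("[+-]?[^+-]+", comps[i]))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("X", "Y", "Z")) {
        rot[i, match(body, c("X", "Y", "Z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        parts <- as.numeric(strsplit(body, "/")[[1]])
        trans[i] <- trans[i] + sign * parts[1] / parts[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else {
        abort(paste0("Cannot parse term '", tm, "' in symmetry operator '", text, "'."))
      }
    }
  }
  if (any(!rot %in% c(-1, 0, 1))) {
    warn("Symmetry operator has rotation entries outside {-1, 0, 1} (non-standard setting).")
  }
  list(rotation = rot, translation = trans,
       text = toupper(gsub("[[:space:]]", "", text)))
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op Operator from [parse_symop()].
#' @param frac Matrix of fractional coordinates (rows are atoms).
#' @return Transformed fractional coordinate matrix.
#' @export
apply_symop <- function(op, frac) {
  frac <- rbind(frac)
  sweep(t(op$rotation %*% t(frac)), 2, -op$translation)
}

# Bundled generators for common protein space groups, used when a file gives a
# Hermann-Mauguin symbol but no explicit operator records. Keys are symbols
# with spaces removed, upper case.
.spacegroup_table <- list(
  "P1"       = c("X,Y,Z"),
  "P-1"      = c("X,Y,Z", "-X,-Y,-Z"),
  "P121"     = c("X,Y,Z", "-X,Y,-Z"),
  "P1211"    = c("X,Y,Z", "-X,Y+1/2,-Z"),
  "C121"     = c("X,Y,Z", "-X,Y,-Z", "X+1/2,Y+1/2,Z", "-X+1/2,Y+1/2,-Z"),
  "P21212"   = c("X,Y,Z", "-X,-Y,Z", "-X+1/2,Y+1/2,-Z", "X+1/2,-Y+1/2,-Z"),
  "P212121"  = c("X,Y,Z", "-X+1/2,-Y,Z+1/2", "-X,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z"),
  "P41212"   = c("X,Y,Z", "-X,-Y,Z+1/2", "-Y+1/2,X+1/2,Z+1/4", "Y+1/2,-X+1/2,Z+3/4",
                 "-X+1/2,Y+1/2,-Z+1/4", "X+1/2,-Y+1/2,-Z+3/4", "Y,X,-Z", "-Y,-X,-Z+1/2"),
  "P43212"   = c("X,Y,Z", "-X,-Y,Z+1/2", "-Y+1/2,X+1/2,Z+3/4", "Y+1/2,-X+1/2,Z+1/4",
                 "-X+1/2,Y+1/2,-Z+3/4", "X+1/2,-Y+1/2,-Z+1/4", "Y,X,-Z", "-Y,-X,-Z+1/2"),
  "P3121"    = c("X,Y,Z", "-Y,X-Y,Z+1/3", "-X+Y,-X,Z+2/3",
                 "Y,X,-Z", "X-Y,-Y,-Z+2/3", "-X,-X+Y,-Z+1/3"),
  "P3221"    = c("X,Y,Z", "-Y,X-Y,Z+2/3", "-X+Y,-X,Z+1/3",
                 "Y,X,-Z", "X-Y,-Y,-Z+1/3", "-X,-X+Y,-Z+2/3")
)
# Aliases as written in PDB/mmCIF headers.
.spacegroup_aliases <- c(
  "P2"  = "P121", "P21" = "P1211", "P1211" = "P1211",
  "C2"  = "C121"
)

#' Look up symmetry operators for a space-group symbol
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"`.
#' @return List of parsed symmetry operators, or `NULL` if the symbol is not
#'   in the bundled table.
#' @export
spacegroup_symops <- function(symbol) {
  key <- toupper(gsub("[[:space:]]", "", symbol))
  if (key %in% names(.spacegroup_aliases)) key <- .spacegroup_aliases[[key]]
  ops <- .spacegroup_table[[key]]
  if (is.null(ops)) return(NULL)
  lapply(ops, parse_symop)
}

# ---------------------------------------------------------------------------
# Structure model ------------------------------------------------------------

.atom_columns <- c("serial", "element", "atom_name", "residue_name",
                   "chain_id", "residue_seq", "ins_code", "altloc",
                   "x", "y", "z", "occupancy", "b_iso", "is_hydrogen",
                   "record")

#' Construct a structure model
#'
#' Bundles the atoms of an asymmetric unit (a tibble, one row per atom) with
#' the crystal cell and structure-level metadata.
#'
#' @param atoms Tibble with columns `serial`, `element`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_seq`, `ins_code`, `altloc`, `x`,
#'   `y`, `z` (orthogonal angstroms), `occupancy`, `b_iso`, `is_hydrogen`,
#'   `record` (`"ATOM"`/`"HETATM"`).
#' @param cell A [crystal_cell()].
#' @param metadata Named list; recognised fields are `pdb_id`, `resolution`,
#'   `r_work`, `r_free`, `temperature`, `deposition_year`, `molecular_mass`
#'   and `b_factor_model`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell, metadata = list()) {
  atoms <- as_tibble(atoms)
  missing_cols <- setdiff(.atom_columns, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("Atom table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("Structure contains zero atoms.")
  for (col in c("x", "y", "z", "b_iso", "occupancy", "serial")) {
    atoms[[col]] <- unname(atoms[[col]])
  }
  if (anyDuplicated(atoms$serial)) abort("Atom serial numbers must be unique.")
  if (any(is.na(atoms$b_iso))) abort("Every atom must carry an isotropic B-factor.")
  if (any(atoms$b_iso < 0)) abort("Negative B-factor encountered (parse error).")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort("Occupancies must lie in [0, 1].")
  }
  if (!inherits(cell, "crystal_cell")) abort("`cell` must be a crystal_cell.")
  atoms$is_hydrogen <- toupper(atoms$element) %in% c("H", "D")
  defaults <- list(pdb_id = "XXXX", resolution = NA_real_, r_work = NA_real_,
                   r_free = NA_real_, temperature = NA_real_,
                   deposition_year = NA_integer_, molecular_mass = NA_real_,
                   b_factor_model = "unknown")
  metadata <- utils::modifyList(defaults, metadata[!vapply(metadata, is.null, logical(1))])
  if (!is.na(metadata$resolution) && metadata$resolution <= 0) {
    abort("Resolution must be positive when present.")
  }
  if (!is.na(metadata$r_free) && (metadata$r_free < 0 || metadata$r_free > 1)) {
    abort("R_free must lie in [0, 1] when present.")
  }
  structure(list(atoms = atoms, cell = cell, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, cell %.2f x %.2f x %.2f A, %d symop(s)\n",
              x$metadata$pdb_id, nrow(x$atoms),
              x$cell$a, x$cell$b, x$cell$c, length(x$cell$symops)))
  invisible(x)
}

#' Atoms of a structure model as a tibble
#'
#' @param model A `structure_model`.
#' @param include_hydrogens Keep hydrogen/deuterium rows? Default `TRUE`.
#' @return Tibble of atom records.
#' @export
atom_table <- function(model, include_hydrogens = TRUE) {
  atoms <- model$atoms
  if (!include_hydrogens) atoms <- atoms[!atoms$is_hydrogen, ]
  atoms
}

# Atoms that enter metric computation: non-hydrogen, occupancy > 0.
metric_atoms <- function(model) {
  dplyr::filter(model$atoms, !.data$is_hydrogen, .data$occupancy > 0)
}
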