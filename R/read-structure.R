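# Reading coordinate files -------------------------------------------------
#
# Two dialects are supported: PDBx/mmCIF (coordinate loop `_atom_site`, cell
# and symmetry key-value records, refine metadata) and legacy PDB fixed-column
# records (ATOM/HETATM, CRYST1, the parseable REMARKs). Both deliver the same
# atom tibble; coordinates always end up in orthogonal angstroms.

#' Read a crystal structure from an mmCIF or PDB file
#'
#' @param path Path to the coordinate file.
#' @param format `"mmcif"`, `"pdb"` or `"auto"` (default: decide from the
#'   file extension, falling back to content sniffing).
#' @return A [structure_model()].
#' @details Anisotropically refined files must report the equivalent
#'   isotropic B in the isotropic B-factor column (`B_iso_or_equiv` /
#'   PDB B column); that value is used as `b_iso`. Symmetry operators are
#'   taken from explicit operator records when present, otherwise from a
#'   bundled space-group-symbol table; a file whose space group cannot be
#'   resolved either way is rejected rather than silently assumed to be P1.
#'   Structures with TLS-partitioned B-factors (residual-only B column) are
#'   not detected automatically; supply files with total isotropic B-factors.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else {
                first <- readLines(path, n = 1L, warn = FALSE)
                if (grepl("^data_", first)) "mmcif" else "pdb"
              }
  }
  switch(format,
         mmcif = read_mmcif_file(path),
         pdb   = read_pdb_file(path))
}

# -- mmCIF ------------------------------------------------------------------

# Minimal whitespace tokenizer honouring single/double quotes.
cif_tokens <- function(line) {
  out <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line))[[1]]
  gsub("^['\"]|['\"]$", "", out)
}

cif_numeric <- function(x) {
  x[x %in% c(".", "?")] <- NA
  suppressWarnings(as.numeric(x))
}

# Parse an mmCIF file into key-value pairs and loops (as data frames).
parse_cif_blocks <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  kv <- list(); loops <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (ln == "" || grepl("^data_", ln)) { i <- i + 1L; next }
    if (identical(ln, "loop_")) {
      i <- i + 1L
      cols <- character(0)
      while (i <= n && grepl("^_", trimws(lines[[i]]))) {
        cols <- c(cols, strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]][1])
        i <- i + 1L
      }
      vals <- list()
      while (i <= n) {
        ln2 <- trimws(lines[[i]])
        if (ln2 == "" || ln2 == "#" || grepl("^(_|loop_|data_)", ln2)) break
        vals[[length(vals) + 1L]] <- cif_tokens(ln2)
        i <- i + 1L
      }
      if (length(vals) && length(cols)) {
        flat <- unlist(vals, use.names = FALSE)
        if (length(flat) %% length(cols) == 0) {
          m <- matrix(flat, ncol = length(cols), byrow = TRUE)
          df <- as.data.frame(m, stringsAsFactors = FALSE)
          names(df) <- cols
          loops[[length(loops) + 1L]] <- df
        }
      }
    } else if (grepl("^_", ln)) {
      toks <- cif_tokens(ln)
      if (length(toks) >= 2) {
        kv[[toks[1]]] <- paste(toks[-1], collapse = " ")
      } else if (i + 1L <= n) {
        # value on the following line (possibly ;-delimited)
        nxt <- trimws(lines[[i + 1L]])
        if (startsWith(nxt, ";")) {
          j <- i + 2L
          while (j <= n && !startsWith(trimws(lines[[j]]), ";")) j <- j + 1L
          kv[[toks[1]]] <- paste(trimws(lines[(i + 1L):(j - 1L)]), collapse = " ")
          i <- j
        } else {
          kv[[toks[1]]] <- gsub("^['\"]|['\"]$", "", nxt)
          i <- i + 1L
        }
      }
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(kv = kv, loops = loops)
}

cif_kv_num <- function(kv, keys) {
  for (k in keys) if (!is.null(kv[[k]])) return(cif_numeric(kv[[k]]))
  NA_real_
}

read_mmcif_file <- function(path) {
  parsed <- parse_cif_blocks(readLines(path, warn = FALSE))
  kv <- parsed$kv

  a <- cif_kv_num(kv, "_cell.length_a")
  b <- cif_kv_num(kv, "_cell.length_b")
  cc <- cif_kv_num(kv, "_cell.length_c")
  if (any(is.na(c(a, b, cc)))) {
    abort("mmCIF file lacks _cell.length_a/_b/_c records; cannot build the crystal cell.")
  }
  alpha <- cif_kv_num(kv, "_cell.angle_alpha")
  beta  <- cif_kv_num(kv, "_cell.angle_beta")
  gamma <- cif_kv_num(kv, "_cell.angle_gamma")

  # symmetry: explicit operator loop wins over the symbol table
  symops <- NULL
  for (lp in parsed$loops) {
    opcol <- intersect(c("_symmetry_equiv.pos_as_xyz",
                         "_space_group_symop.operation_xyz"), names(lp))
    if (length(opcol)) symops <- lapply(lp[[opcol[1]]], parse_symop)
  }
  op_keys <- c("_symmetry_equiv.pos_as_xyz", "_space_group_symop.operation_xyz")
  for (k in op_keys) if (is.null(symops) && !is.null(kv[[k]])) {
    symops <- list(parse_symop(kv[[k]]))
  }
  if (is.null(symops)) {
    sym <- kv[["_symmetry.space_group_name_H-M"]] %||%
      kv[["_space_group.name_H-M_alt"]]
    if (is.null(sym)) {
      abort("mmCIF file has neither symmetry operator records nor a space-group symbol.")
    }
    symops <- spacegroup_symops(sym)
    if (is.null(symops)) {
      abort(paste0("Space group '", sym, "' is not in the bundled symbol table ",
                   "and no explicit operator records were found."))
    }
  }
  cell <- crystal_cell(a, b, cc, alpha, beta, gamma, symops)

  atom_loop <- NULL
  for (lp in parsed$loops) {
    if ("_atom_site.id" %in% names(lp) || "_atom_site.group_PDB" %in% names(lp)) {
      atom_loop <- lp
    }
  }
  if (is.null(atom_loop) || nrow(atom_loop) == 0) {
    abort("mmCIF file contains no _atom_site coordinate loop (zero atoms).")
  }
  g <- function(keys, default = NA_character_) {
    for (k in keys) if (k %in% names(atom_loop)) return(atom_loop[[k]])
    rep(default, nrow(atom_loop))
  }
  x <- cif_numeric(g("_atom_site.Cartn_x"))
  y <- cif_numeric(g("_atom_site.Cartn_y"))
  z <- cif_numeric(g("_atom_site.Cartn_z"))
  if (all(is.na(x))) {
    fx <- cif_numeric(g("_atom_site.fract_x"))
    fy <- cif_numeric(g("_atom_site.fract_y"))
    fz <- cif_numeric(g("_atom_site.fract_z"))
    if (all(is.na(fx))) abort("Atom loop has neither Cartesian nor fractional coordinates.")
    xyz <- frac_to_orth(cell, cbind(fx, fy, fz))
    x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  }
  b_iso <- cif_numeric(g("_atom_site.B_iso_or_equiv"))
  if (any(is.na(b_iso))) {
    abort("One or more atoms lack an isotropic (or equivalent-isotropic) B-factor.")
  }
  altloc <- g(c("_atom_site.label_alt_id"), ".")
  altloc[altloc %in% c(".", "?")] <- ""
  ins <- g(c("_atom_site.pdbx_PDB_ins_code"), "?")
  ins[ins %in% c(".", "?")] <- ""
  element <- toupper(g("_atom_site.type_symbol"))
  atoms <- tibble(
    serial = as.integer(cif_numeric(g("_atom_site.id", "0"))),
    element = element,
    atom_name = g(c("_atom_site.auth_atom_id", "_atom_site.label_atom_id")),
    residue_name = g(c("_atom_site.auth_comp_id", "_atom_site.label_comp_id")),
    chain_id = g(c("_atom_site.auth_asym_id", "_atom_site.label_asym_id")),
    residue_seq = as.integer(cif_numeric(
      g(c("_atom_site.auth_seq_id", "_atom_site.label_seq_id"), "0"))),
    ins_code = ins,
    altloc = altloc,
    x = x, y = y, z = z,
    occupancy = cif_numeric(g("_atom_site.occupancy", "1")),
    b_iso = b_iso,
    is_hydrogen = element %in% c("H", "D"),
    record = g("_atom_site.group_PDB", "ATOM")
  )

  year_str <- kv[["_pdbx_database_status.recvd_initial_deposition_date"]]
  metadata <- list(
    pdb_id = kv[["_entry.id"]] %||% "XXXX",
    resolution = cif_kv_num(kv, c("_refine.ls_d_res_high",
                                  "_reflns.d_resolution_high")),
    r_work = cif_kv_num(kv, "_refine.ls_R_factor_R_work"),
    r_free = cif_kv_num(kv, "_refine.ls_R_factor_R_free"),
    temperature = cif_kv_num(kv, c("_diffrn.ambient_temp",
                                   "_exptl_crystal_grow.temp")),
    deposition_year = if (!is.null(year_str))
      suppressWarnings(as.integer(substr(year_str, 1, 4))) else NA_integer_,
    molecular_mass = cif_kv_num(kv, "_entity.formula_weight"),
    b_factor_model = kv[["_bnetr.b_factor_model"]] %||% "unknown"
  )
  structure_model(atoms, cell, metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- legacy PDB -------------------------------------------------------------

read_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cryst <- lines[startsWith(lines, "CRYST1")]
  if (!length(cryst)) {
    abort("PDB file lacks a CRYST1 record; cannot build the crystal cell.")
  }
  cr <- cryst[[1]]
  num <- function(from, to) suppressWarnings(as.numeric(substr(cr, from, to)))
  sym <- trimws(substr(cr, 56, 66))
  # explicit REMARK 290 fractional operator listing wins over the symbol table
  r290 <- regmatches(lines,
    regexpr("^REMARK 290[[:space:]]+[0-9]{4,6}[[:space:]]+(-?[XYZ0-9/+,-]+)$", lines))
  symops <- if (length(r290)) {
    lapply(sub("^REMARK 290[[:space:]]+[0-9]+[[:space:]]+", "", r290), parse_symop)
  } else {
    spacegroup_symops(sym)
  }
  if (is.null(symops)) {
    abort(paste0("Space group '", sym, "' is not in the bundled symbol table ",
                 "and no REMARK 290 operator listing was found."))
  }
  cell <- crystal_cell(num(7, 15), num(16, 24), num(25, 33),
                       num(34, 40), num(41, 47), num(48, 54), symops)

  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(at)) abort("PDB file contains zero ATOM/HETATM records.")
  f <- function(from, to) trimws(substr(at, from, to))
  fn <- function(from, to) suppressWarnings(as.numeric(f(from, to)))
  element <- toupper(f(77, 78))
  # fall back on the atom-name column when the element field is blank
  blank <- element == ""
  if (any(blank)) {
    element[blank] <- gsub("[0-9']", "", substr(f(13, 16)[blank], 1, 1))
  }
  b_iso <- fn(61, 66)
  if (any(is.na(b_iso))) abort("One or more ATOM records lack a B-factor value.")
  atoms <- tibble(
    serial = as.integer(fn(7, 11)),
    element = element,
    atom_name = f(13, 16),
    residue_name = f(18, 20),
    chain_id = f(22, 22),
    residue_seq = as.integer(fn(23, 26)),
    ins_code = f(27, 27),
    altloc = f(17, 17),
    x = fn(31, 38), y = fn(39, 46), z = fn(47, 54),
    occupancy = fn(55, 60),
    b_iso = b_iso,
    is_hydrogen = element %in% c("H", "D"),
    record = f(1, 6)
  )

  grab_remark <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*?:", "", hit[[1]])))
  }
  metadata <- list(
    pdb_id = {
      hdr <- lines[startsWith(lines, "HEADER")]
      if (length(hdr)) trimws(substr(hdr[[1]], 63, 66)) else "XXXX"
    },
    resolution = grab_remark("^REMARK   2 RESOLUTION\\."),
    r_work = grab_remark("^REMARK   3   R VALUE            \\(WORKING SET\\)"),
    r_free = grab_remark("^REMARK   3   FREE R VALUE                     :"),
    temperature = grab_remark("^REMARK 200  TEMPERATURE")
  )
  # "RESOLUTION.    2.00 ANGSTROMS." carries trailing text
  if (is.na(metadata$resolution)) {
    hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(hit)) {
      metadata$resolution <- suppressWarnings(
        as.numeric(regmatches(hit[[1]], regexpr("[0-9]+\\.[0-9]+", hit[[1]]))))
    }
  }
  structure_model(atoms, cell, metadata)
}
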