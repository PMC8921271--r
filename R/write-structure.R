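# Writing coordinate files --------------------------------------------------

fmt_atom_name <- function(name, element) {
  # PDB convention: element right-justified in cols 13-14, so 1-letter
  # elements with short names start in column 14.
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1 && nchar(name) < 4) {
    sprintf(" %-3s", name)
  } else {
    sprintf("%-4s", name)
  }
}

#' Write a structure model as a legacy PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @param b_override Optional numeric vector (named by atom serial) written
#'   into the temperature-factor column instead of `b_iso`.
#' @param spacegroup Symbol written into CRYST1 (default `"P 1"` when the
#'   model has one operator, else the stored symbol is not known and `"P 1"`
#'   is still written alongside an explicit REMARK 290 operator listing).
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path, b_override = NULL, spacegroup = NULL) {
  atoms <- model$atoms
  cell <- model$cell
  md <- model$metadata
  b <- atoms$b_iso
  if (!is.null(b_override)) {
    idx <- match(as.character(atoms$serial), names(b_override))
    if (any(is.na(idx))) {
      abort(paste0("No replacement B value for atom serial(s): ",
                   paste(atoms$serial[is.na(idx)], collapse = ", ")))
    }
    b <- unname(b_override[idx])
  }
  if (any(b > 999.99)) {
    warn("B column values exceed 999.99 and were clamped to the PDB column width.")
    b <- pmin(b, 999.99)
  }
  sg <- spacegroup %||% if (length(cell$symops) == 1) "P 1" else "P 1"
  out <- c(
    sprintf("HEADER    PSEUDO-PROTEIN                          01-JAN-26   %-4s", md$pdb_id),
    if (!is.na(md$resolution))
      sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", md$resolution),
    if (!is.na(md$r_work))
      sprintf("REMARK   3   R VALUE            (WORKING SET) : %.4f", md$r_work),
    if (!is.na(md$r_free))
      sprintf("REMARK   3   FREE R VALUE                     : %.4f", md$r_free),
    if (!is.na(md$temperature))
      sprintf("REMARK 200  TEMPERATURE           (KELVIN) : %.1f", md$temperature),
    vapply(seq_along(cell$symops), function(i) {
      sprintf("REMARK 290    %6d   %s", i * 1000 + 555, cell$symops[[i]]$text)
    }, character(1)),
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma, sg, 1L)
  )
  rec <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 atoms$record, atoms$serial,
                 vapply(seq_len(nrow(atoms)),
                        function(i) fmt_atom_name(atoms$atom_name[i], atoms$element[i]),
                        character(1)),
                 atoms$altloc, atoms$residue_name, atoms$chain_id,
                 atoms$residue_seq, atoms$ins_code,
                 atoms$x, atoms$y, atoms$z, atoms$occupancy, b,
                 atoms$element)
  writeLines(c(out, rec, "END"), path)
  invisible(path)
}

#' Write a structure model as an mmCIF file
#'
#' @inheritParams write_pdb
#' @return Invisibly, `path`.
#' @export
write_mmcif <- function(model, path) {
  atoms <- model$atoms
  cell <- model$cell
  md <- model$metadata
  num_or_q <- function(x, fmt) if (is.null(x) || is.na(x)) "?" else sprintf(fmt, x)
  header <- c(
    sprintf("data_%s", md$pdb_id),
    "#",
    sprintf("_entry.id %s", md$pdb_id),
    sprintf("_cell.length_a    %.3f", cell$a),
    sprintf("_cell.length_b    %.3f", cell$b),
    sprintf("_cell.length_c    %.3f", cell$c),
    sprintf("_cell.angle_alpha %.2f", cell$alpha),
    sprintf("_cell.angle_beta  %.2f", cell$beta),
    sprintf("_cell.angle_gamma %.2f", cell$gamma),
    sprintf("_refine.ls_d_res_high %s", num_or_q(md$resolution, "%.2f")),
    sprintf("_refine.ls_R_factor_R_work %s", num_or_q(md$r_work, "%.4f")),
    sprintf("_refine.ls_R_factor_R_free %s", num_or_q(md$r_free, "%.4f")),
    sprintf("_diffrn.ambient_temp %s", num_or_q(md$temperature, "%.1f")),
    sprintf("_bnetr.b_factor_model %s", md$b_factor_model),
    "#",
    "loop_",
    "_symmetry_equiv.id",
    "_symmetry_equiv.pos_as_xyz",
    vapply(seq_along(cell$symops), function(i) {
      sprintf("%d '%s'", i, cell$symops[[i]]$text)
    }, character(1)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv"
  )
  rows <- sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
                  atoms$record, atoms$serial, atoms$element, atoms$atom_name,
                  ifelse(atoms$altloc == "", ".", atoms$altloc),
                  atoms$residue_name, atoms$chain_id, atoms$residue_seq,
                  ifelse(atoms$ins_code == "", "?", atoms$ins_code),
                  atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_iso)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Write coordinates coloured by B_Damage
#'
#' Writes a PDB-format file whose temperature-factor column carries each
#' atom's B_Damage value (2 decimal places, the column's precision), so any
#' molecular viewer can colour the structure by damage signal.
#'
#' @param model A [structure_model()].
#' @param bdamage A [compute_bdamage()] result for the same model.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bdamage_coordinates <- function(model, bdamage, path) {
  stopifnot(inherits(bdamage, "bdamage_result"))
  heavy <- model$atoms[!model$atoms$is_hydrogen & model$atoms$occupancy > 0, ]
  missing <- setdiff(heavy$serial, bdamage$atoms$serial)
  if (length(missing)) {
    abort(paste0("No B_Damage value for atom serial(s): ",
                 paste(missing, collapse = ", ")))
  }
  values <- setNames(bdamage$atoms$bdamage, as.character(bdamage$atoms$serial))
  # hydrogens / zero-occupancy atoms have no B_Damage; write 0.00 for them
  all_serials <- as.character(model$atoms$serial)
  b_override <- setNames(rep(0, length(all_serials)), all_serials)
  b_override[names(values)] <- round(values, 2)
  sub <- model
  write_pdb(sub, path, b_override = b_override)
}

#' Export per-atom records to CSV
#'
#' @param tbl A tibble (e.g. from [compute_bdamage()]'s `$atoms` or
#'   [packing_density()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_atom_csv <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
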