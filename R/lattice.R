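# Crystalline environment --------------------------------------------------
#
# Packing density is counted in the context of the full crystal, so the
# asymmetric unit must be surrounded by its symmetry mates and lattice
# translations before neighbours are counted. The expansion is the explicit
# route: every symmetry operator applied in fractional space (wrapped into
# the unit cell), replicated over the 3x3x3 block of lattice translations,
# then trimmed to a shell around the asymmetric unit's bounding box.

#' Expand the asymmetric unit into its crystalline environment
#'
#' Applies every symmetry operator of the cell to the asymmetric unit in
#' fractional coordinates (wrapping each copy into the unit cell), replicates
#' the result over the 27 lattice translations \{-1, 0, +1\}^3, converts to
#' orthogonal angstroms, and trims to positions within `radius` + `margin`
#' of the asymmetric unit's axis-aligned bounding box. Hydrogens and
#' zero-occupancy atoms never enter the cloud.
#'
#' @param model A [structure_model()].
#' @param radius Neighbour-count radius in angstroms the cloud must support
#'   (default 7).
#' @param margin Extra trim margin in angstroms guarding against edge loss
#'   (default 0.5).
#' @return A `crystal_context`: list with `model`, the `cloud` tibble
#'   (`x`, `y`, `z`, `serial`, `symop`, `tx`, `ty`, `tz`, `is_identity`),
#'   `radius` and `margin`.
#' @export
expand_lattice <- function(model, radius = 7, margin = 0.5) {
  stopifnot(inherits(model, "structure_model"))
  if (radius <= 0) abort("Expansion radius must be positive.")
  asu <- metric_atoms(model)
  if (nrow(asu) == 0) abort("No non-hydrogen, occupancy > 0 atoms to expand.")
  cell <- model$cell
  xyz <- as.matrix(asu[, c("x", "y", "z")])
  frac <- orth_to_frac(cell, xyz)

  shifts <- as.matrix(expand.grid(tx = -1:1, ty = -1:1, tz = -1:1))
  pieces <- vector("list", length(cell$symops) * nrow(shifts))
  k <- 0L
  for (i in seq_along(cell$symops)) {
    op <- cell$symops[[i]]
    f <- apply_symop(op, frac)
    f <- f - floor(f)                       # wrap into [0, 1)
    for (s in seq_len(nrow(shifts))) {
      k <- k + 1L
      fs <- sweep(f, 2, -as.numeric(shifts[s, ]))
      o <- frac_to_orth(cell, fs)
      pieces[[k]] <- tibble(
        x = o[, 1], y = o[, 2], z = o[, 3],
        serial = asu$serial,
        symop = i, tx = shifts[s, 1], ty = shifts[s, 2], tz = shifts[s, 3]
      )
    }
  }
  cloud <- dplyr::bind_rows(pieces)

  # identity copies of the asymmetric unit: the wrap plus some unit
  # translation reproduces the original positions; tag them by coordinates
  lo <- apply(xyz, 2, min) - (radius + margin)
  hi <- apply(xyz, 2, max) + (radius + margin)
  keep <- cloud$x >= lo[1] & cloud$x <= hi[1] &
          cloud$y >= lo[2] & cloud$y <= hi[2] &
          cloud$z >= lo[3] & cloud$z <= hi[3]
  cloud <- cloud[keep, ]

  orig <- xyz[match(cloud$serial, asu$serial), , drop = FALSE]
  cloud$is_identity <- cloud$symop == 1L &
    abs(cloud$x - orig[, 1]) < 1e-6 &
    abs(cloud$y - orig[, 2]) < 1e-6 &
    abs(cloud$z - orig[, 3]) < 1e-6

  if (!all(asu$serial %in% cloud$serial[cloud$is_identity])) {
    abort("Internal error: identity copy of the asymmetric unit lost in trimming.")
  }

  # special-position diagnostics: a non-identity copy essentially on top of
  # its source atom
  non_id <- which(!cloud$is_identity)
  if (length(non_id)) {
    src <- xyz[match(cloud$serial[non_id], asu$serial), , drop = FALSE]
    d2 <- (cloud$x[non_id] - src[, 1])^2 + (cloud$y[non_id] - src[, 2])^2 +
          (cloud$z[non_id] - src[, 3])^2
    if (any(d2 < 0.25)) {
      warn(sprintf("%d symmetry copies lie within 0.5 A of their source atom (special positions?).",
                   sum(d2 < 0.25)))
    }
  }

  structure(list(model = model, cloud = cloud, radius = radius, margin = margin),
            class = "crystal_context")
}

#' @export
print.crystal_context <- function(x, ...) {
  cat(sprintf("<crystal_context> %d cloud positions (%d symops x 27 translations, trimmed at %.1f + %.1f A)\n",
              nrow(x$cloud), length(x$model$cell$symops), x$radius, x$margin))
  invisible(x)
}

#' Per-atom packing density
#'
#' Counts, for every non-hydrogen occupancy > 0 atom of the asymmetric unit,
#' the number of non-hydrogen atoms of the crystalline environment within
#' `radius` angstroms (closed ball: a neighbour at exactly `radius` counts).
#' The atom's own identity copy is excluded from its count. Counting uses a
#' cell-list spatial grid with bin edge equal to `radius`, so cost is close
#' to linear in the cloud size.
#'
#' @param ctx A `crystal_context` from [expand_lattice()], built with an
#'   expansion radius at least as large as `radius`.
#' @param radius Count radius in angstroms (default 7).
#' @return Tibble with columns `serial`, `atom_name`, `residue_name`,
#'   `chain_id`, `residue_seq`, `packing_density`.
#' @export
packing_density <- function(ctx, radius = 7) {
  stopifnot(inherits(ctx, "crystal_context"))
  if (radius <= 0) abort("Packing-density radius must be positive.")
  if (radius > ctx$radius) {
    abort("Context was expanded for a smaller radius than requested; rebuild with expand_lattice().")
  }
  asu <- metric_atoms(ctx$model)
  cloud <- ctx$cloud
  cm <- cbind(cloud$x, cloud$y, cloud$z)

  # cell lists: integer bin per cloud position, bin edge = radius
  bin <- floor(cm / radius)
  key <- paste(bin[, 1], bin[, 2], bin[, 3], sep = ",")
  bins <- split(seq_len(nrow(cm)), key)

  qxyz <- as.matrix(asu[, c("x", "y", "z")])
  qbin <- floor(qxyz / radius)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- radius^2

  counts <- integer(nrow(asu))
  for (i in seq_len(nrow(asu))) {
    neigh_keys <- paste(qbin[i, 1] + offsets[, 1],
                        qbin[i, 2] + offsets[, 2],
                        qbin[i, 3] + offsets[, 3], sep = ",")
    idx <- unlist(bins[neigh_keys], use.names = FALSE)
    if (!length(idx)) next
    dx <- cm[idx, 1] - qxyz[i, 1]
    dy <- cm[idx, 2] - qxyz[i, 2]
    dz <- cm[idx, 3] - qxyz[i, 3]
    inside <- (dx * dx + dy * dy + dz * dz) <= r2 + 1e-9
    n_self <- sum(inside & cloud$is_identity[idx] & cloud$serial[idx] == asu$serial[i])
    counts[i] <- sum(inside) - n_self
  }
  tibble(
    serial = asu$serial,
    atom_name = asu$atom_name,
    residue_name = asu$residue_name,
    chain_id = asu$chain_id,
    residue_seq = asu$residue_seq,
    packing_density = counts
  )
}
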