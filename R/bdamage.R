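# B_Damage ------------------------------------------------------------------
#
# An atom's B-factor reflects both genuine disorder/damage and its local
# environment: loosely packed atoms are intrinsically more mobile. B_Damage
# removes the environmental component by dividing each atom's B-factor by
# the mean B-factor of atoms occupying a similar packing-density
# environment. "Similar" is realised as a rank-based contiguous sliding
# window over atoms sorted by packing density: deterministic,
# resolution-free, and exposed through two parameters.

#' Compute per-atom B_Damage values
#'
#' Atoms are sorted by packing density (ties broken by serial number for
#' determinism). For each atom the comparison window is the contiguous run
#' of `w = max(min_window, round(window_fraction * N))` atoms centred on its
#' rank, shifted inward at the ends of the ranking so the window always has
#' exactly `w` members (`w` is capped at `N`). The atom's B_Damage is its
#' B-factor divided by the arithmetic mean B-factor over the window, the
#' atom itself included. Hydrogens and zero-occupancy atoms are excluded
#' throughout.
#'
#' @param model A [structure_model()].
#' @param pd Packing densities from [packing_density()] covering every
#'   non-hydrogen, occupancy > 0 atom of `model`.
#' @param window_fraction Window size as a fraction of the atom count
#'   (default 0.02).
#' @param min_window Minimum window size (default 11).
#' @return A `bdamage_result`: list with `atoms` (tibble: `serial`,
#'   `atom_name`, `residue_name`, `chain_id`, `residue_seq`,
#'   `packing_density`, `window_size`, `bdamage`), `median_all` (median
#'   B_Damage over all included atoms) and the window parameters used.
#' @export
compute_bdamage <- function(model, pd, window_fraction = 0.02, min_window = 11) {
  stopifnot(inherits(model, "structure_model"))
  asu <- metric_atoms(model)
  if (!all(asu$serial %in% pd$serial)) {
    abort("Packing-density table does not cover every included atom.")
  }
  n <- nrow(asu)
  if (n < min_window) {
    abort(sprintf(
      "Structure has only %d included atoms; at least %d are needed for the sliding-window normalisation.",
      n, min_window))
  }
  if (any(asu$b_iso <= 0)) {
    abort("All B-factors must be positive to form B_Damage ratios.")
  }
  dat <- dplyr::left_join(asu, pd[, c("serial", "packing_density")], by = "serial")
  ord <- order(dat$packing_density, dat$serial)
  dat <- dat[ord, ]
  w <- max(min_window, round(window_fraction * n))
  w <- min(w, n)
  half <- (w - 1L) %/% 2L
  starts <- pmin(pmax(seq_len(n) - half, 1L), n - w + 1L)
  csum <- cumsum(c(0, dat$b_iso))
  win_mean <- (csum[starts + w] - csum[starts]) / w
  bdamage <- dat$b_iso / win_mean

  atoms <- tibble(
    serial = dat$serial,
    atom_name = dat$atom_name,
    residue_name = dat$residue_name,
    chain_id = dat$chain_id,
    residue_seq = dat$residue_seq,
    packing_density = dat$packing_density,
    window_size = w,
    window_start_rank = starts,
    bdamage = bdamage
  )
  atoms <- atoms[order(atoms$serial), ]
  structure(
    list(atoms = atoms, median_all = median(bdamage),
         window_fraction = window_fraction, min_window = min_window,
         window_size = w, n_atoms = n),
    class = "bdamage_result"
  )
}

#' @export
print.bdamage_result <- function(x, ...) {
  cat(sprintf("<bdamage_result> %d atoms, window %d, median B_Damage %.4f\n",
              x$n_atoms, x$window_size, x$median_all))
  invisible(x)
}

#' Serials of the atoms in one atom's comparison window
#'
#' @param bd A `bdamage_result`.
#' @param serial Atom serial number.
#' @return Integer vector of window member serials (includes `serial`).
#' @export
bdamage_window <- function(bd, serial) {
  ranked <- bd$atoms[order(bd$atoms$packing_density, bd$atoms$serial), ]
  i <- match(serial, ranked$serial)
  if (is.na(i)) abort(paste0("Atom serial ", serial, " has no B_Damage value."))
  start <- bd$atoms$window_start_rank[match(serial, bd$atoms$serial)]
  ranked$serial[start:(start + bd$window_size - 1L)]
}

#' Descriptive statistics of a B_Damage distribution
#'
#' @param bd A `bdamage_result`.
#' @return One-row tibble: `n`, `median`, `mean`, `sd`, `skewness`
#'   (adjusted Fisher-Pearson), `min`, `max`.
#' @export
summarise_bdamage <- function(bd) {
  v <- bd$atoms$bdamage
  n <- length(v)
  s <- sd(v)
  skew <- if (n > 2 && s > 0) {
    (n / ((n - 1) * (n - 2))) * sum(((v - mean(v)) / s)^3)
  } else {
    NA_real_
  }
  tibble(n = n, median = median(v), mean = mean(v), sd = s,
         skewness = skew, min = min(v), max = max(v))
}

#' @rdname tidy-bnetr
#' @export
tidy.bdamage_result <- function(x, ...) x$atoms

#' @rdname tidy-bnetr
#' @export
glance.bdamage_result <- function(x, ...) {
  dplyr::bind_cols(summarise_bdamage(x),
                   tibble(window_size = x$window_size,
                          window_fraction = x$window_fraction,
                          min_window = x$min_window,
                          median_all = x$median_all))
}
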