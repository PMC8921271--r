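# Hand-built models and independent brute-force oracles used across tests.

# Build a minimal structure model from a compact atom description.
tiny_model <- function(xyz, cell = crystal_cell(100, 100, 100),
                       atom_name = "CA", residue_name = "ALA",
                       element = "C", chain_id = "A",
                       b_iso = 15, occupancy = 1, residue_seq = NULL,
                       metadata = list()) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  atoms <- tibble::tibble(
    serial = seq_len(n),
    element = rep_len(element, n),
    atom_name = rep_len(atom_name, n),
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    residue_seq = if (is.null(residue_seq)) seq_len(n) else rep_len(residue_seq, n),
    ins_code = "",
    altloc = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = rep_len(occupancy, n),
    b_iso = rep_len(b_iso, n),
    is_hydrogen = FALSE,
    record = "ATOM"
  )
  structure_model(atoms, cell, metadata)
}

# Independent packing-density oracle: untrimmed 27-copy expansion of every
# symmetry operator, all-pairs distances, closed ball. No grid, no trimming.
oracle_packing_density <- function(model, radius = 7) {
  asu <- model$atoms[!model$atoms$is_hydrogen & model$atoms$occupancy > 0, ]
  cell <- model$cell
  xyz <- as.matrix(asu[, c("x", "y", "z")])
  frac <- orth_to_frac(cell, xyz)
  cloud <- list()
  for (i in seq_along(cell$symops)) {
    f <- apply_symop(cell$symops[[i]], frac)
    f <- f - floor(f)
    for (tx in -1:1) for (ty in -1:1) for (tz in -1:1) {
      o <- frac_to_orth(cell, sweep(f, 2, -c(tx, ty, tz)))
      cloud[[length(cloud) + 1L]] <- list(
        pos = o, identity = (i == 1L && tx == 0 && ty == 0 && tz == 0))
    }
  }
  counts <- integer(nrow(asu))
  for (j in seq_len(nrow(asu))) {
    total <- 0L
    for (piece in cloud) {
      d2 <- rowSums(sweep(piece$pos, 2, xyz[j, ])^2)
      inside <- d2 <= radius^2 + 1e-9
      if (piece$identity) inside[j] <- FALSE   # the atom's own copy
      total <- total + sum(inside)
    }
    counts[j] <- total
  }
  tibble::tibble(serial = asu$serial, packing_density = counts)
}

# Independent B_Damage oracle: explicit sort / slice / mean loops.
oracle_bdamage <- function(model, pd, window_fraction = 0.02, min_window = 11) {
  asu <- model$atoms[!model$atoms$is_hydrogen & model$atoms$occupancy > 0, ]
  asu$pd <- pd$packing_density[match(asu$serial, pd$serial)]
  asu <- asu[order(asu$pd, asu$serial), ]
  n <- nrow(asu)
  w <- min(max(min_window, round(window_fraction * n)), n)
  out <- numeric(n)
  for (j in seq_len(n)) {
    start <- j - (w - 1L) %/% 2L
    start <- max(1L, min(start, n - w + 1L))
    out[j] <- asu$b_iso[j] / mean(asu$b_iso[start:(start + w - 1L)])
  }
  tibble::tibble(serial = asu$serial, bdamage = out)
}

# Fine-grid quadrature oracle for the KDE area ratio: same estimator and the
# same split boundary (the right edge of the 99-trapezium partition's
# median-containing trapezium, per the area-assignment convention), but each
# side integrated on a dense grid. Checks integration coarseness, not the
# split convention itself.
oracle_bnet_finegrid <- function(values, median_all, n_points = 1e5) {
  n <- length(values)
  h <- stats::sd(values) * n^(-1 / 5)
  lo <- min(values) - 3 * h
  hi <- max(values) + 3 * h
  coarse <- seq(lo, hi, length.out = 100)
  k <- findInterval(median_all, coarse)
  stopifnot(k >= 1, k < 100)
  boundary <- coarse[k + 1]
  dense_area <- function(a, b) {
    g <- seq(a, b, length.out = n_points)
    d <- sapply(g, function(x) mean(stats::dnorm(x, values, h)))
    sum(diff(g) * (d[-length(d)] + d[-1]) / 2)
  }
  dense_area(boundary, hi) / dense_area(lo, boundary)
}

# Brute-force percentile oracle: literal loops over every structure.
oracle_percentile <- function(tbl, window_size) {
  n <- nrow(tbl)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(tbl$resolution - tbl$resolution[i])
    ord <- order(d, as.character(tbl$structure_id))
    win <- ord[seq_len(min(window_size, n))]
    rng <- range(tbl$resolution[win])
    comp <- which(tbl$resolution >= rng[1] & tbl$resolution <= rng[2])
    out[i] <- sum(tbl$bnet[comp] <= tbl$bnet[i]) / length(comp)
  }
  out
}

# A hand-made bdamage_result for feeding compute_bnet() directly.
fake_bdamage <- function(values, median_all, serials = seq_along(values)) {
  structure(
    list(atoms = tibble::tibble(serial = serials, bdamage = values),
         median_all = median_all, n_atoms = length(values)),
    class = "bdamage_result"
  )
}

fake_selection <- function(serials, mode = "asp_glu") {
  tibble::tibble(serial = serials, selection_mode = mode)
}
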