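# Synthetic fixtures --------------------------------------------------------
#
# Deterministic toy crystal structures with a controllable damage signal.
# Pseudo-protein chains are laid out on a coarse self-avoiding lattice path
# (a serpentine walk, so self-avoidance is guaranteed by construction), each
# residue carrying a backbone quartet plus side-chain pseudo-atoms with the
# crystallographic atom names the selection rules key on. The baseline
# B-factor field is anti-correlated with local crowding, which gives the
# packing-density normalisation something real to remove, and a damage
# perturbation multiplies the labelled carboxyl-oxygen B-factors.

#' Specification of a synthetic crystal fixture
#'
#' @param n_chains Number of pseudo-protein chains (default 2).
#' @param residues_per_chain Residues per chain (default 60; at least 10).
#' @param composition Named weights over residue types `ASP`, `GLU`, `ASN`,
#'   `GLN`, `ALA` used to draw each residue's identity.
#' @param baseline_b Mean of the baseline B-factor field, A^2 (default 20).
#' @param packing_coupling A^2 decrease in baseline B per unit of local
#'   crowding above the average (default 0.3); models the tighter, stiffer
#'   core of a real protein.
#' @param damage_factor Multiplier >= 1 applied to the B-factors of the
#'   labelled Asp/Glu carboxyl oxygens (default 1: null fixture).
#' @param damage_fraction Fraction of carboxyl oxygens receiving the
#'   perturbation (default 0.5: specific damage affects a subset of sites,
#'   so part of the selection stays at the baseline and keeps the
#'   below-median KDE area populated).
#' @param noise_sd Gaussian jitter on B-factors, A^2 (default 1).
#' @param cell_padding Solvent gap added to the chain extent when sizing
#'   the P1 cell, A (default 15).
#' @param seed Integer seed; identical specs give bit-identical fixtures.
#' @param metadata Named list merged over the default fixture metadata
#'   (resolution 2.0 A, R_work 0.18, R_free 0.22, 100 K).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chains = 2, residues_per_chain = 60,
                         composition = c(ASP = 0.15, GLU = 0.15, ASN = 0.12,
                                         GLN = 0.12, ALA = 0.46),
                         baseline_b = 20, packing_coupling = 0.3,
                         damage_factor = 1, damage_fraction = 0.5,
                         noise_sd = 1, cell_padding = 15, seed = 1,
                         metadata = list()) {
  if (residues_per_chain < 10) {
    abort("residues_per_chain must be at least 10 (carboxyl-oxygen eligibility).")
  }
  if (damage_factor < 1) abort("damage_factor must be >= 1.")
  structure(
    list(n_chains = n_chains, residues_per_chain = residues_per_chain,
         composition = composition, baseline_b = baseline_b,
         packing_coupling = packing_coupling, damage_factor = damage_factor,
         damage_fraction = damage_fraction, noise_sd = noise_sd,
         cell_padding = cell_padding, seed = as.integer(seed),
         metadata = metadata),
    class = "fixture_spec"
  )
}

.sidechain_atoms <- list(
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  ALA = c("CB")
)
.carboxyl_names <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# serpentine walk through a cubic lattice: guaranteed self-avoiding
serpentine <- function(n, step, per_row, per_layer) {
  i <- seq_len(n) - 1L
  layer <- i %/% per_layer
  in_layer <- i %% per_layer
  row <- in_layer %/% per_row
  col <- in_layer %% per_row
  # reverse alternate rows/layers so consecutive residues stay adjacent
  col <- ifelse(row %% 2 == 1, per_row - 1 - col, col)
  row <- ifelse(layer %% 2 == 1, (per_layer %/% per_row) - 1 - row, row)
  cbind(col, row, layer) * step
}

#' Generate a synthetic crystal structure
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, `<tag>.cif`, `<tag>.pdb` and
#'   `<tag>_labels.csv` are written there.
#' @param tag File/entry tag (default `"SYNT"`).
#' @return A [structure_model()] with a `damage_labels` attribute (tibble
#'   `serial`, `is_damaged`).
#' @export
generate_fixture <- function(spec, dir = NULL, tag = "SYNT") {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    n_res_total <- spec$n_chains * spec$residues_per_chain
    # realise the nominal composition exactly (largest-remainder rounding),
    # then shuffle placement: oxygen counts do not wobble between seeds
    w <- spec$composition / sum(spec$composition)
    counts <- floor(w * n_res_total)
    rem <- n_res_total - sum(counts)
    if (rem > 0) {
      extra <- order(w * n_res_total - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    res_types <- sample(rep(names(spec$composition), counts))

    step <- 5.5                      # coarse lattice pitch, A
    per_row <- max(3L, ceiling(spec$residues_per_chain^(1 / 3)))
    per_layer <- per_row^2
    rows <- list()
    serial <- 0L
    for (ch in seq_len(spec$n_chains)) {
      ca <- serpentine(spec$residues_per_chain, step, per_row, per_layer)
      # offset chains along x so they pack side by side
      ca[, 1] <- ca[, 1] + (ch - 1) * (per_row * step + 4)
      for (r in seq_len(spec$residues_per_chain)) {
        res <- res_types[(ch - 1) * spec$residues_per_chain + r]
        names_r <- c("N", "CA", "C", "O", .sidechain_atoms[[res]])
        offs <- rbind(
          N  = c(-1.2,  0.8, 0.3), CA = c(0, 0, 0),
          C  = c( 1.2,  0.8, -0.3), O = c(1.6, 1.9, -0.4),
          CB = c( 0.2, -1.4, 0.6), CG = c(0.3, -2.6, -0.2),
          CD = c( 0.4, -3.8, 0.5), OD1 = c(1.3, -3.3, -0.5),
          OD2 = c(-0.8, -3.4, -0.7), OE1 = c(1.4, -4.4, 0.2),
          OE2 = c(-0.7, -4.6, 0.6), ND2 = c(1.3, -3.3, -0.5),
          NE2 = c(1.4, -4.4, 0.2)
        )
        # small deterministic wobble so geometry is not perfectly repetitive
        wob <- matrix(runif(3 * length(names_r), -0.25, 0.25), ncol = 3)
        xyz <- sweep(offs[names_r, , drop = FALSE] + wob, 2, -ca[r, ])
        el <- substr(names_r, 1, 1)
        for (k in seq_along(names_r)) {
          serial <- serial + 1L
          rows[[serial]] <- list(serial = serial, element = el[k],
                                 atom_name = names_r[k], residue_name = res,
                                 chain_id = LETTERS[ch], residue_seq = r,
                                 x = xyz[k, 1], y = xyz[k, 2], z = xyz[k, 3])
        }
      }
    }
    atoms <- dplyr::bind_rows(rows)
    atoms$ins_code <- ""
    atoms$altloc <- ""
    atoms$occupancy <- 1
    atoms$record <- "ATOM"
    atoms$is_hydrogen <- FALSE

    # baseline B anti-correlated with local crowding inside the asu
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    crowd <- unname(rowSums(d <= 7)) - 1L
    b <- spec$baseline_b - spec$packing_coupling * (crowd - mean(crowd)) +
      rnorm(nrow(atoms), sd = spec$noise_sd)
    b <- pmax(b, 2)

    # damage perturbation on the labelled carboxyl oxygens: every site gets
    # a uniform damage-onset threshold, and the fixture damages the sites
    # whose onset lies below damage_fraction (nested subsets, so fixtures
    # differing only in damage_fraction are comparable site-by-site)
    is_carboxyl <- (atoms$residue_name == "ASP" & atoms$atom_name %in% c("OD1", "OD2")) |
                   (atoms$residue_name == "GLU" & atoms$atom_name %in% c("OE1", "OE2"))
    idx <- which(is_carboxyl)
    # stratified susceptibility spectrum: onsets evenly spaced in (0, 1),
    # assigned to sites in a shuffled order, so any damaged fraction f
    # damages round(f * n_sites) sites -- no binomial gaps in a dose series
    onset <- rep(NA_real_, nrow(atoms))
    onset[idx] <- (sample(length(idx)) - 0.5) / length(idx)
    damaged <- !is.na(onset) & onset <= spec$damage_fraction
    b[damaged] <- b[damaged] * spec$damage_factor
    atoms$b_iso <- round(b, 2)       # PDB-column precision, keeps round-trips lossless

    # P1 cell sized to the extent plus the solvent padding; shift the model
    # so it sits centred inside the cell
    lo <- unname(apply(xyz, 2, min)); hi <- unname(apply(xyz, 2, max))
    lens <- (hi - lo) + spec$cell_padding
    shift <- -lo + spec$cell_padding / 2
    atoms$x <- round(atoms$x + shift[1], 3)
    atoms$y <- round(atoms$y + shift[2], 3)
    atoms$z <- round(atoms$z + shift[3], 3)

    md <- utils::modifyList(
      list(pdb_id = tag, resolution = 2.0, r_work = 0.18, r_free = 0.22,
           temperature = 100, b_factor_model = "per_atom_iso"),
      spec$metadata)
    model <- structure_model(atoms, crystal_cell(lens[1], lens[2], lens[3]), md)
    attr(model, "damage_labels") <- tibble(serial = atoms$serial,
                                           is_damaged = damaged,
                                           onset = onset)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_mmcif(model, file.path(dir, paste0(tag, ".cif")))
      write_pdb(model, file.path(dir, paste0(tag, ".pdb")))
      write.csv(attr(model, "damage_labels"),
                file.path(dir, paste0(tag, "_labels.csv")), row.names = FALSE)
    }
    model
  })
}

#' Generate a synthetic radiation-damage series
#'
#' All structures in the series share the same crystal (one seed, one
#' backbone, one noise realisation and one set of per-site damage-onset
#' thresholds); what grows with dose is the fraction of carboxyl-oxygen
#' sites whose onset the dose has passed, mirroring how increasing numbers
#' of sites acquire above-median B_Damage in real damage series. Because
#' the KDE-area ratio is count-driven, the damaged fraction
#' `lambda = slope * dose / (2 + slope * dose)` gives, to first order,
#' `B_net = (1 + lambda) / (1 - lambda) = 1 + slope * dose` -- the fixed
#' monotone calibration. Damaged sites are inflated by `site_factor`.
#'
#' @param spec A [fixture_spec()]; its `damage_factor`/`damage_fraction`
#'   are overridden per dose point.
#' @param doses Strictly increasing absorbed doses in MGy (at least 3).
#' @param slope Target fitted B_net-per-MGy gradient (default 0.1).
#' @param site_factor B-factor inflation applied to a damaged site
#'   (default 1.6, comfortably above the B-factor noise).
#' @param damage_cap Ceiling on the targeted B_net (default 6): the damaged
#'   fraction saturates at `(damage_cap - 1) / (damage_cap + 1)`, producing
#'   the B_net-vs-dose plateau seen in heavily damaged series.
#' @return List of [structure_model()]s, with a `doses` attribute and each
#'   model carrying `dose` and `damage_level` attributes.
#' @export
generate_damage_series <- function(spec, doses, slope = 0.1, site_factor = 1.45,
                                   damage_cap = 6) {
  if (length(doses) < 3) abort("A damage series needs at least 3 doses.")
  if (any(diff(doses) <= 0)) abort("Doses must be strictly increasing.")
  base <- generate_fixture(spec)
  labels <- attr(base, "damage_labels")
  # undo any damage baked into the fixture specification: the series starts pristine
  pristine_b <- base$atoms$b_iso
  pre <- labels$is_damaged[match(base$atoms$serial, labels$serial)]
  pristine_b[pre] <- round(pristine_b[pre] / spec$damage_factor, 2)
  lambda_max <- (damage_cap - 1) / (damage_cap + 1)
  series <- lapply(seq_along(doses), function(i) {
    lam <- min(slope * doses[i] / (2 + slope * doses[i]), lambda_max)
    m <- base
    m$atoms$b_iso <- pristine_b
    sel <- !is.na(labels$onset) & labels$onset <= lam
    sel <- sel[match(m$atoms$serial, labels$serial)]
    m$atoms$b_iso[sel] <- round(m$atoms$b_iso[sel] * site_factor, 2)
    m$metadata$pdb_id <- sprintf("%s%02d", substr(base$metadata$pdb_id, 1, 2), i)
    attr(m, "dose") <- doses[i]
    attr(m, "damage_level") <- lam
    attr(m, "damage_labels") <- tibble(serial = labels$serial,
                                       is_damaged = !is.na(labels$onset) &
                                         labels$onset <= lam,
                                       onset = labels$onset)
    m
  })
  attr(series, "doses") <- doses
  series
}

#' Generate a synthetic screening cohort
#'
#' Emits a metadata-level cohort table whose B_net values follow a
#' controllable log-linear dependence on resolution with independent
#' lognormal noise, plus independent noise on the remaining covariates
#' (R factors correlated with resolution, as in real cohorts). With
#' `write_structures = TRUE` a full fixture file pair is also written per
#' row (intended for small `n`).
#'
#' @param n Cohort size (at least 10).
#' @param resolution_range Range of resolutions in angstroms
#'   (default `c(1.0, 3.5)`).
#' @param coupling Coefficient of standardised resolution in
#'   `log(bnet)` (default -0.8; 0 gives a null cohort).
#' @param noise_sd SD of the lognormal noise on B_net (default 0.35).
#' @param seed Integer seed.
#' @param write_structures Also generate fixture files per row?
#' @param dir Output directory when `write_structures = TRUE`.
#' @return Cohort tibble with `structure_id`, `bnet`, the eight standard
#'   covariates and `deposition_year`.
#' @export
generate_cohort <- function(n, resolution_range = c(1.0, 3.5), coupling = -0.8,
                            noise_sd = 0.35, seed = 1,
                            write_structures = FALSE, dir = NULL) {
  if (n < 10) abort("Cohort size must be at least 10.")
  withr::with_seed(as.integer(seed), {
    res <- seq(resolution_range[1], resolution_range[2], length.out = n) +
      runif(n, -0.01, 0.01)
    z <- as.numeric(scale(res))
    bnet <- exp(0.2 + coupling * z + noise_sd * rnorm(n))
    r_work <- pmin(pmax(0.10 + 0.035 * res + 0.015 * rnorm(n), 0.05), 0.45)
    tbl <- tibble(
      structure_id = sprintf("SYN%04d", seq_len(n)),
      bnet = bnet,
      resolution = res,
      r_work = r_work,
      r_free = pmin(r_work + 0.04 + 0.01 * abs(rnorm(n)), 0.5),
      temperature = runif(n, 80, 120),
      molecular_mass = exp(rnorm(n, 10.5, 0.6)),
      n_carboxyl_oxygens = 20L + rpois(n, 40),
      pct_asp_glu_residues = runif(n, 5, 18),
      bfactor_restraint_weight = exp(rnorm(n, 0, 0.4)),
      deposition_year = sample(1995:2020, n, replace = TRUE)
    )
    if (write_structures) {
      if (is.null(dir)) abort("`dir` is required when write_structures = TRUE.")
      for (i in seq_len(n)) {
        sp <- fixture_spec(seed = seed + i,
                           metadata = list(resolution = tbl$resolution[i]))
        generate_fixture(sp, dir = dir, tag = tbl$structure_id[i])
      }
    }
    tbl
  })
}

#' Canonical damage-series study conditions
#'
#' The fixture and dose design used throughout the package's dose-response
#' validation: a 4 x 80-residue crystal with real-protein carboxyl-oxygen
#' dilution (ASP/GLU 4.5% each), a large amide-oxygen control pool
#' (ASN/GLN 18% each), B-factor noise 1.5 A^2, and a five-point dose ladder
#' spaced uniformly in damage level at a target gradient of 0.2 per MGy.
#'
#' @param seed Integer seed for the fixture.
#' @return List with `spec` (a [fixture_spec()]), `doses` (MGy), `slope`
#'   (target B_net gradient per MGy) and `site_factor`.
#' @export
damage_series_conditions <- function(seed = 1) {
  list(
    spec = fixture_spec(
      n_chains = 4, residues_per_chain = 80,
      composition = c(ASP = 0.045, GLU = 0.045, ASN = 0.18, GLN = 0.18,
                      ALA = 0.55),
      noise_sd = 1.5, seed = seed),
    doses = c(0, 1.43, 3.33, 6, 10),
    slope = 0.2,
    site_factor = 1.45
  )
}
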