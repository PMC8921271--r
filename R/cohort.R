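# Cohort analysis -----------------------------------------------------------
#
# Screening a cohort requires (1) per-structure eligibility filtering, since
# B_net is only meaningful for cryo-cooled, per-atom-B protein structures
# with enough carboxyl oxygens; (2) a resolution-windowed percentile that
# makes B_net comparable across resolutions; and (3) the validation
# statistics: least-squares dose fits, relative-SD summaries of fit
# coefficients, and Spearman correlation scans over structure covariates.

.nucleic_codes <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")

#' Check a structure's eligibility for B_net screening
#'
#' Evaluates the per-structure filters: protein with no nucleic-acid
#' component; data-collection temperature in 80--120 K; resolution 3.5 A or
#' better; R_free at most 0.4; per-atom (not flat, not per-residue)
#' B-factors; every Asp/Glu side-chain oxygen at full total occupancy
#' across conformers; and at least `min_oxygens` Asp/Glu side-chain
#' oxygens. A criterion that cannot be evaluated (missing metadata) fails
#' with an explanatory reason.
#'
#' @param model A [structure_model()].
#' @param min_oxygens Carboxyl-oxygen count threshold (default 20).
#' @return An `eligibility_report`: list with the per-criterion logicals
#'   (`is_protein_no_nucleic`, `temperature_in_80_120K`,
#'   `resolution_le_3p5`, `rfree_le_0p4`, `per_atom_bfactors_not_flat`,
#'   `asp_glu_full_occupancy`, `ge_20_carboxyl_oxygens`, `has_asp_glu`),
#'   `overall` and `failure_reasons`.
#' @export
check_eligibility <- function(model, min_oxygens = 20) {
  md <- model$metadata
  atoms <- model$atoms
  reasons <- character(0)

  crit <- list()
  crit$is_protein_no_nucleic <- !any(atoms$residue_name %in% .nucleic_codes &
                                       atoms$record == "ATOM")
  if (!crit$is_protein_no_nucleic) {
    reasons <- c(reasons, "structure contains nucleic-acid polymer residues")
  }

  crit$temperature_in_80_120K <- !is.na(md$temperature) &&
    md$temperature >= 80 && md$temperature <= 120
  if (!crit$temperature_in_80_120K) {
    reasons <- c(reasons, if (is.na(md$temperature)) {
      "data-collection temperature unknown"
    } else {
      sprintf("temperature %.1f K outside 80-120 K", md$temperature)
    })
  }

  crit$resolution_le_3p5 <- !is.na(md$resolution) && md$resolution <= 3.5
  if (!crit$resolution_le_3p5) {
    reasons <- c(reasons, if (is.na(md$resolution)) {
      "resolution unknown"
    } else {
      sprintf("resolution %.2f A worse than 3.5 A", md$resolution)
    })
  }

  crit$rfree_le_0p4 <- !is.na(md$r_free) && md$r_free <= 0.4
  if (!crit$rfree_le_0p4) {
    reasons <- c(reasons, if (is.na(md$r_free)) {
      "R_free unknown"
    } else {
      sprintf("R_free %.3f greater than 0.4", md$r_free)
    })
  }

  # flat-B detection: structure-wide sd below 1e-6 A^2; per-residue-B
  # heuristic: every residue internally constant while the whole is not
  heavy <- metric_atoms(model)
  global_sd <- sd(heavy$b_iso)
  flat <- is.na(global_sd) || global_sd < 1e-6
  per_residue <- FALSE
  if (!flat) {
    res_sd <- dplyr::summarise(
      dplyr::group_by(heavy, .data$chain_id, .data$residue_seq, .data$ins_code),
      s = if (dplyr::n() > 1) sd(.data$b_iso) else 0, .groups = "drop")$s
    per_residue <- all(res_sd < 1e-9) && any(table(paste(heavy$chain_id, heavy$residue_seq)) > 1)
  }
  crit$per_atom_bfactors_not_flat <- !flat && !per_residue
  if (!crit$per_atom_bfactors_not_flat) {
    reasons <- c(reasons, if (flat) {
      "flat B-factor model (all B identical)"
    } else {
      "per-residue B-factor model (heuristic: every residue internally constant)"
    })
  }

  sel <- select_oxygens_any_occ(model)
  crit$has_asp_glu <- nrow(sel) > 0
  if (!crit$has_asp_glu) reasons <- c(reasons, "no Asp/Glu residues")

  # total occupancy across conformers of each carboxyl oxygen site
  occ_ok <- TRUE
  if (nrow(sel)) {
    site_occ <- dplyr::summarise(
      dplyr::group_by(sel, .data$chain_id, .data$residue_seq, .data$ins_code,
                      .data$atom_name),
      occ = sum(.data$occupancy), .groups = "drop")$occ
    occ_ok <- all(site_occ >= 1 - 1e-6)
  }
  crit$asp_glu_full_occupancy <- crit$has_asp_glu && occ_ok
  if (crit$has_asp_glu && !occ_ok) {
    reasons <- c(reasons, "Asp/Glu side-chain oxygen with total occupancy below 1")
  }

  n_ox <- nrow(select_oxygens(model, "asp_glu"))
  crit$ge_20_carboxyl_oxygens <- n_ox >= min_oxygens
  if (!crit$ge_20_carboxyl_oxygens) {
    reasons <- c(reasons, sprintf("%d Asp/Glu side-chain oxygens, need >= %d",
                                  n_ox, min_oxygens))
  }

  structure(
    c(crit, list(n_carboxyl_oxygens = n_ox,
                 overall = all(unlist(crit)),
                 failure_reasons = reasons)),
    class = "eligibility_report"
  )
}

# like select_oxygens() but keeps zero-occupancy rows (occupancy bookkeeping)
select_oxygens_any_occ <- function(model) {
  rules <- .oxygen_selection[["asp_glu"]]
  atoms <- model$atoms[!model$atoms$is_hydrogen, ]
  keep <- rep(FALSE, nrow(atoms))
  for (res in names(rules)) {
    keep <- keep | (atoms$residue_name == res & atoms$atom_name %in% rules[[res]])
  }
  atoms[keep, ]
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> overall: %s\n",
              if (x$overall) "PASS" else "FAIL"))
  for (r in x$failure_reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Resolution-windowed B_net percentile
#'
#' For each structure: (1) the `window_size` structures closest in
#' resolution (ties on distance broken by structure id) define a closed
#' resolution range; (2) the comparison set is every cohort structure whose
#' resolution lies in that range (possibly more than `window_size`); (3)
#' the percentile is the fraction of the comparison set with B_net less
#' than or equal to the structure's own, so the top structure of its window
#' scores exactly 1.
#'
#' @param table Cohort tibble with at least `structure_id`, `bnet`,
#'   `resolution` columns.
#' @param window_size Number of nearest-in-resolution structures defining
#'   the range (default 1000, capped at the cohort size).
#' @return The input tibble with a `bnet_percentile` column (NA, with a
#'   warning, for rows lacking a resolution).
#' @export
bnet_percentile <- function(table, window_size = 1000) {
  stopifnot(all(c("structure_id", "bnet", "resolution") %in% names(table)))
  n <- nrow(table)
  if (sum(!is.na(table$resolution)) < 2) {
    abort("Need at least 2 structures with a resolution to rank against.")
  }
  window_size <- min(window_size, sum(!is.na(table$resolution)))
  res <- table$resolution
  ids <- as.character(table$structure_id)
  pct <- rep(NA_real_, n)
  have <- which(!is.na(res))
  for (i in seq_len(n)) {
    if (is.na(res[i])) next
    d <- abs(res[have] - res[i])
    ord <- order(d, ids[have])
    win <- have[ord[seq_len(window_size)]]
    rng <- range(res[win])
    comp <- have[res[have] >= rng[1] & res[have] <= rng[2]]
    pct[i] <- sum(table$bnet[comp] <= table$bnet[i]) / length(comp)
  }
  if (any(is.na(res))) {
    warn(sprintf("%d structure(s) lack a resolution; their percentile is NA.",
                 sum(is.na(res))))
  }
  table$bnet_percentile <- pct
  table
}

#' Least-squares fit of B_net against absorbed dose
#'
#' Ordinary least squares of B_net on dose for one damage series,
#' optionally excluding high-dose plateau points first.
#'
#' @param series Tibble/data frame with columns `dose` (MGy) and `bnet`.
#' @param exclude_above_dose Optional dose cutoff (MGy); points with dose
#'   strictly greater are excluded before fitting and listed in the result.
#' @param series_id Identifier carried into the result.
#' @return A `dose_series_fit`: list with `gradient` (per MGy),
#'   `y_intercept`, `r_squared`, `n_points`, `excluded_points` and
#'   `series_id`.
#' @export
fit_dose_series <- function(series, exclude_above_dose = NULL,
                            series_id = "series") {
  stopifnot(all(c("dose", "bnet") %in% names(series)))
  excluded <- tibble(dose = numeric(0), bnet = numeric(0), reason = character(0))
  keep <- series
  if (!is.null(exclude_above_dose)) {
    drop <- series$dose > exclude_above_dose
    excluded <- tibble(dose = series$dose[drop], bnet = series$bnet[drop],
                       reason = sprintf("dose above %.3g MGy plateau cutoff",
                                        exclude_above_dose))
    keep <- series[!drop, ]
  }
  if (nrow(keep) < 3) {
    abort(sprintf("Dose series has %d points after exclusions; need >= 3.",
                  nrow(keep)))
  }
  if (diff(range(keep$dose)) == 0) {
    abort("All doses identical: degenerate design, no gradient is estimable.")
  }
  fit <- lm(bnet ~ dose, data = keep)
  # collinear input is legitimate here; summary() warns about perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(series_id = series_id,
         gradient = unname(coef(fit)[["dose"]]),
         y_intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         n_points = nrow(keep),
         excluded_points = excluded),
    class = "dose_series_fit"
  )
}

#' @export
print.dose_series_fit <- function(x, ...) {
  cat(sprintf("<dose_series_fit> %s: gradient %.4g /MGy, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$series_id, x$gradient, x$y_intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname tidy-bnetr
#' @export
glance.dose_series_fit <- function(x, ...) {
  tibble(series_id = x$series_id, gradient = x$gradient,
         y_intercept = x$y_intercept, r_squared = x$r_squared,
         n_points = x$n_points, n_excluded = nrow(x$excluded_points))
}

#' Consistency of dose-fit coefficients across series
#'
#' Relative standard deviation (sample SD over absolute mean) of the
#' gradients and intercepts of a set of dose fits. A mean of zero is
#' reported as the absolute SD with a flag.
#'
#' @param fits List of `dose_series_fit` objects.
#' @return One-row tibble: `n_series`, `gradient_mean`, `gradient_rsd`,
#'   `intercept_mean`, `intercept_rsd`, `gradient_rsd_is_absolute`,
#'   `intercept_rsd_is_absolute`.
#' @export
summarise_fit_consistency <- function(fits) {
  if (length(fits) < 2) abort("Need at least 2 dose fits to summarise consistency.")
  g <- vapply(fits, function(f) f$gradient, numeric(1))
  ic <- vapply(fits, function(f) f$y_intercept, numeric(1))
  rsd <- function(x) {
    m <- mean(x)
    if (m == 0) list(value = sd(x), absolute = TRUE)
    else list(value = sd(x) / abs(m), absolute = FALSE)
  }
  rg <- rsd(g); ri <- rsd(ic)
  tibble(n_series = length(fits),
         gradient_mean = mean(g), gradient_rsd = rg$value,
         intercept_mean = mean(ic), intercept_rsd = ri$value,
         gradient_rsd_is_absolute = rg$absolute,
         intercept_rsd_is_absolute = ri$absolute)
}

.cohort_covariates <- c("resolution", "r_work", "r_free", "temperature",
                        "molecular_mass", "n_carboxyl_oxygens",
                        "pct_asp_glu_residues", "bfactor_restraint_weight")

#' Spearman correlation scan over cohort covariates
#'
#' Spearman rank correlation (average ranks on ties) of the target metric
#' against each covariate; pairs with missing values are dropped per
#' covariate, and a covariate that is constant (or has fewer than 3
#' complete pairs) is reported as NA.
#'
#' @param table Cohort tibble.
#' @param target `"bnet"` (default) or `"bnet_percentile"`.
#' @param covariates Character vector of covariate columns; defaults to the
#'   eight standard structure variables present in `table`.
#' @return Tibble with `covariate`, `rho`, `n`.
#' @export
spearman_matrix <- function(table, target = c("bnet", "bnet_percentile"),
                            covariates = NULL) {
  target <- match.arg(target)
  if (!target %in% names(table)) {
    abort(paste0("Column '", target, "' not present in the cohort table."))
  }
  covariates <- covariates %||% intersect(.cohort_covariates, names(table))
  y <- table[[target]]
  rows <- lapply(covariates, function(cv) {
    x <- table[[cv]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
      return(tibble(covariate = cv, rho = NA_real_, n = sum(ok)))
    }
    tibble(covariate = cv,
           rho = cor(x[ok], y[ok], method = "spearman"),
           n = sum(ok))
  })
  dplyr::bind_rows(rows)
}

#' Advisory damage flag for a structure
#'
#' A structure merits further inspection when its B_net exceeds 3.0 or its
#' B_net-percentile exceeds 0.95 (both strict inequalities). Advisory only:
#' the flag never filters data.
#'
#' @param bnet B_net value (scalar or vector).
#' @param bnet_percentile Optional percentile value(s); NA ignored.
#' @return Logical vector.
#' @export
flag_suspect <- function(bnet, bnet_percentile = NA_real_) {
  p <- ifelse(is.na(bnet_percentile), -Inf, bnet_percentile)
  bnet > 3.0 | p > 0.95
}
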