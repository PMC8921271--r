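# B_net ---------------------------------------------------------------------
#
# Aspartate/glutamate side chains decarboxylate early under X-ray
# irradiation; when the damaged side chain is still refined at full
# occupancy its carboxyl oxygens acquire inflated B-factors, and hence
# B_Damage values sitting to the right of the structure's overall median.
# B_net summarises this as the ratio of the area under a Gaussian kernel
# density estimate of the carboxyl-oxygen B_Damage values to the right (B)
# versus left (A) of the median B_Damage of all atoms: B_net = B / A.

.oxygen_selection <- list(
  asp_glu = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 DAS = c("OD1", "OD2"), DGL = c("OE1", "OE2")),
  asn_gln = list(ASN = "OD1", GLN = "OE1",
                 DSG = "OD1", DGN = "OE1")
)

#' Select side-chain oxygen atoms
#'
#' `asp_glu` mode selects the carboxyl oxygens OD1/OD2 of aspartate and
#' OE1/OE2 of glutamate (D-isomer codes DAS/DGL included); `asn_gln` mode
#' selects the single amide oxygen OD1 of asparagine and OE1 of glutamine
#' (the undamaged control selection). Hydrogens and zero-occupancy atoms
#' are never selected.
#'
#' @param model A [structure_model()].
#' @param mode `"asp_glu"` (default) or `"asn_gln"`.
#' @return Tibble of the selected atom rows with a `selection_mode` column;
#'   zero rows when nothing matches.
#' @export
select_oxygens <- function(model, mode = c("asp_glu", "asn_gln")) {
  mode <- match.arg(mode)
  rules <- .oxygen_selection[[mode]]
  atoms <- metric_atoms(model)
  keep <- rep(FALSE, nrow(atoms))
  for (res in names(rules)) {
    keep <- keep | (atoms$residue_name == res & atoms$atom_name %in% rules[[res]])
  }
  out <- atoms[keep, ]
  out$selection_mode <- mode
  out
}

#' Compute B_net from B_Damage values of selected oxygens
#'
#' Fits a Gaussian kernel density estimate to the B_Damage values of the
#' selected oxygen atoms with Scott's bandwidth `h = sd(v) * n^(-1/5)`
#' (Bessel-corrected standard deviation), evaluates it on 100 equally spaced
#' points spanning `[min(v) - 3h, max(v) + 3h]` (99 trapeziums), and splits
#' the trapezium-rule area at the median B_Damage of all atoms in the
#' structure. The trapezium containing the median counts towards the
#' below-median area A; B_net = B / A where B is the remainder.
#'
#' @param bd A `bdamage_result` for the structure.
#' @param selection Tibble from [select_oxygens()].
#' @param min_oxygens Minimum number of selected oxygens (default 20,
#'   mirroring the cohort eligibility rule). Lowering it triggers a loud
#'   warning; intended for exploratory use only.
#' @param n_grid Number of KDE evaluation points (default 100).
#' @return A `bnet_result`: list with `bnet`, `area_below` (A), `area_above`
#'   (B), `median_all`, `bandwidth`, `n_selected`, `selection_mode`,
#'   `kde` (tibble `x`, `density`), `total_area` and `flag` (`"ok"`,
#'   `"median_below_grid"` or `"median_above_grid"`).
#' @export
compute_bnet <- function(bd, selection, min_oxygens = 20, n_grid = 100) {
  stopifnot(inherits(bd, "bdamage_result"))
  if (min_oxygens < 20) {
    warn(paste0("min_oxygens lowered below 20: B_net values from so few oxygens ",
                "are noisy and not comparable with screening thresholds."))
  }
  n <- nrow(selection)
  if (n < min_oxygens) {
    abort(sprintf(
      "Structure is ineligible for B_net: %d selected side-chain oxygens, need >= %d.",
      n, min_oxygens))
  }
  missing <- setdiff(selection$serial, bd$atoms$serial)
  if (length(missing)) {
    abort(paste0("Selected oxygens without a B_Damage value: ",
                 paste(missing, collapse = ", ")))
  }
  v <- bd$atoms$bdamage[match(selection$serial, bd$atoms$serial)]
  sigma <- sd(v)
  if (!is.finite(sigma) || sigma == 0) {
    abort(sprintf(
      "Degenerate B_Damage distribution: all %d selected values equal %.6g; the KDE bandwidth is zero.",
      n, v[1]))
  }
  h <- sigma * n^(-1 / 5)
  grid <- seq(min(v) - 3 * h, max(v) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = v, sd = h)), numeric(1))

  dx <- diff(grid)
  trap <- dx * (head(dens, -1) + tail(dens, -1)) / 2
  total <- sum(trap)
  m <- bd$median_all
  flag <- "ok"
  if (m < grid[1]) {
    area_below <- 0; area_above <- total; flag <- "median_below_grid"
  } else if (m >= grid[n_grid]) {
    area_below <- total; area_above <- 0; flag <- "median_above_grid"
  } else {
    k <- findInterval(m, grid)          # trapezium k spans grid[k]..grid[k+1]
    area_below <- sum(trap[seq_len(k)])
    area_above <- total - area_below
  }
  bnet <- if (area_below == 0) {
    warn("Median B_Damage lies below the KDE grid; B_net is +Inf.")
    Inf
  } else {
    area_above / area_below
  }
  structure(
    list(bnet = bnet, area_below = area_below, area_above = area_above,
         median_all = m, bandwidth = h, n_selected = n,
         selection_mode = selection$selection_mode[1] %||% NA_character_,
         kde = tibble(x = grid, density = dens),
         total_area = total, flag = flag, n_grid = n_grid),
    class = "bnet_result"
  )
}

#' @export
print.bnet_result <- function(x, ...) {
  cat(sprintf("<bnet_result> B_net (%s) = %s from %d oxygens (bandwidth %.4f, median_all %.4f)\n",
              x$selection_mode, signif(x$bnet, 3), x$n_selected, x$bandwidth,
              x$median_all))
  invisible(x)
}

#' Full single-structure pipeline: lattice, B_Damage, B_net
#'
#' Runs [expand_lattice()], [packing_density()], [compute_bdamage()],
#' [select_oxygens()] and [compute_bnet()] in sequence for the Asp/Glu
#' selection and, when enough amide oxygens are present, the Asn/Gln
#' control selection.
#'
#' @param model A [structure_model()].
#' @param config A [run_config()] (or individual parameter overrides via
#'   `...` passed to [run_config()]).
#' @return A `structure_report`: list with `bnet` (`bnet_result`),
#'   `bnet_asn_gln` (`bnet_result` or `NULL` when fewer than `min_oxygens`
#'   amide oxygens exist), `bdamage` (`bdamage_result`), `pd` (packing
#'   densities), `model` and `config`.
#' @export
compute_bnet_for_structure <- function(model, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  ctx <- stage("lattice_expansion", expand_lattice(model, radius = config$radius))
  pd <- stage("packing_density", packing_density(ctx, radius = config$radius))
  bd <- stage("bdamage", compute_bdamage(model, pd,
                                         window_fraction = config$window_fraction,
                                         min_window = config$min_window))
  sel <- stage("selection", select_oxygens(model, "asp_glu"))
  bnet <- stage("bnet", compute_bnet(bd, sel, min_oxygens = config$min_oxygens,
                                     n_grid = config$kde_points))
  sel_ctrl <- select_oxygens(model, "asn_gln")
  bnet_ctrl <- if (nrow(sel_ctrl) >= config$min_oxygens) {
    stage("bnet_asn_gln", compute_bnet(bd, sel_ctrl,
                                       min_oxygens = config$min_oxygens,
                                       n_grid = config$kde_points))
  } else {
    NULL
  }
  structure(
    list(bnet = bnet, bnet_asn_gln = bnet_ctrl, bdamage = bd, pd = pd,
         model = model, config = config),
    class = "structure_report"
  )
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report> %s: B_net = %s", x$model$metadata$pdb_id,
              signif(x$bnet$bnet, 3)))
  if (!is.null(x$bnet_asn_gln)) {
    cat(sprintf(", B_net(Asn/Gln) = %s", signif(x$bnet_asn_gln$bnet, 3)))
  }
  cat("\n")
  invisible(x)
}

#' Tidiers for bnetr result objects
#'
#' `tidy()` returns the per-observation table (atoms for `bdamage_result`,
#' the KDE curve for `bnet_result`); `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name tidy-bnetr
NULL

#' @rdname tidy-bnetr
#' @export
tidy.bnet_result <- function(x, ...) x$kde

#' @rdname tidy-bnetr
#' @export
glance.bnet_result <- function(x, ...) {
  tibble(bnet = x$bnet, area_below = x$area_below, area_above = x$area_above,
         median_all = x$median_all, bandwidth = x$bandwidth,
         n_selected = x$n_selected, selection_mode = x$selection_mode,
         total_area = x$total_area, flag = x$flag)
}

#' @rdname tidy-bnetr
#' @export
glance.structure_report <- function(x, ...) {
  out <- glance(x$bnet)
  out$bnet_asn_gln <- if (is.null(x$bnet_asn_gln)) NA_real_ else x$bnet_asn_gln$bnet
  out$n_atoms <- x$bdamage$n_atoms
  out$pdb_id <- x$model$metadata$pdb_id
  out
}

#' Plot a B_net kernel density estimate
#'
#' Draws the KDE of the selected oxygens' B_Damage values with the all-atom
#' median marked and the below/above-median areas shaded.
#'
#' @param object A `bnet_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bnet_result <- function(object, ...) {
  kde <- object$kde
  kde$side <- ifelse(kde$x <= object$median_all, "A (below median)", "B (above median)")
  ggplot2::ggplot(kde, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$side), alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$median_all, linetype = "dashed") +
    ggplot2::labs(
      x = "B_Damage", y = "Density", fill = NULL,
      title = sprintf("B_net (%s) = %s", object$selection_mode,
                      signif(object$bnet, 3)),
      subtitle = sprintf("%d oxygens, Scott bandwidth %.3f",
                         object$n_selected, object$bandwidth)
    ) +
    ggplot2::theme_minimal()
}

#' Write a per-structure JSON report
#'
#' @param report A `structure_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure_report <- function(report, path) {
  x <- report
  out <- list(
    pdb_id = x$model$metadata$pdb_id,
    bnet = x$bnet$bnet,
    bnet_3sf = signif(x$bnet$bnet, 3),
    bnet_asn_gln = if (is.null(x$bnet_asn_gln)) NULL else x$bnet_asn_gln$bnet,
    median_all = x$bnet$median_all,
    n_selected = x$bnet$n_selected,
    bandwidth = x$bnet$bandwidth,
    area_below = x$bnet$area_below,
    area_above = x$bnet$area_above,
    flag = x$bnet$flag,
    config = x$config[setdiff(names(x$config), c("output_dir"))]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
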