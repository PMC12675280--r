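#' Configuration for synthetic single-cell in situ intensity tables
#'
#' Emulates per-cell fluorescent in situ hybridization intensities for an
#' astrocyte panel. Each cell draws a log-normal soma-size factor through
#' the pan-astrocyte marker Slc1a3; every other gene's intensity is the
#' marker intensity times a gene-level log-normal with condition-specific
#' multipliers, so dividing by the marker removes the size factor exactly.
#' The Adrb1 and Igfbp2 latent Gaussian factors are correlated at
#' `adrb1_igfbp2_corr` (a Gaussian copula on the log scale). A designated
#' fraction of cells receives an elevated Fos multiplier and is labelled
#' in the ground truth.
#'
#' @param n_cells_per_sample Cells per section/sample.
#' @param n_samples_per_condition Samples (sections or mice) per
#'   condition.
#' @param conditions Character vector of condition labels.
#' @param base_means Named vector of log-normal location parameters
#'   (arbitrary intensity units); must include `Slc1a3`. Defaults cover
#'   the probe panel Slc1a3, Fos, Adra1a, Adrb1, Igfbp2.
#' @param marker_cv Coefficient of variation of the Slc1a3 soma-size
#'   factor.
#' @param gene_sigma Log-scale SD of each non-marker gene's own
#'   variability.
#' @param condition_effects Named list `gene -> named numeric` of
#'   condition multipliers (default 1 for every gene/condition).
#' @param fos_high_fraction Fraction of cells receiving the elevated Fos
#'   multiplier (Bernoulli per cell).
#' @param fos_high_multiplier Fold elevation of Fos in Fos-high cells.
#' @param adrb1_igfbp2_corr Latent correlation between Adrb1 and Igfbp2,
#'   in \[-1, 1\].
#' @param seed Integer seed.
#' @return A list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_cells_per_sample = 30,
                            n_samples_per_condition = 5,
                            conditions = c("NoFC", "FC", "NoFR", "FR"),
                            base_means = c(Slc1a3 = 100, Fos = 5,
                                           Adra1a = 8, Adrb1 = 8, Igfbp2 = 10),
                            marker_cv = 0.3,
                            gene_sigma = 0.4,
                            condition_effects = list(),
                            fos_high_fraction = 0.031,
                            fos_high_multiplier = 8,
                            adrb1_igfbp2_corr = 0.8,
                            seed = 0) {
  if (!length(conditions)) abort("`conditions` must be non-empty.")
  if (!"Slc1a3" %in% names(base_means)) abort("`base_means` must include Slc1a3.")
  if (fos_high_fraction < 0 || fos_high_fraction > 1) {
    abort("`fos_high_fraction` must lie in [0, 1].")
  }
  if (abs(adrb1_igfbp2_corr) > 1) {
    abort("`adrb1_igfbp2_corr` must lie in [-1, 1].")
  }
  if (marker_cv < 0 || gene_sigma < 0) {
    abort("`marker_cv` and `gene_sigma` must be non-negative.")
  }
  for (g in names(condition_effects)) {
    if (!g %in% names(base_means)) {
      abort(sprintf("condition_effects names a gene not in base_means: %s", g))
    }
  }
  structure(
    list(n_cells_per_sample = n_cells_per_sample,
         n_samples_per_condition = n_samples_per_condition,
         conditions = conditions, base_means = base_means,
         marker_cv = marker_cv, gene_sigma = gene_sigma,
         condition_effects = condition_effects,
         fos_high_fraction = fos_high_fraction,
         fos_high_multiplier = fos_high_multiplier,
         adrb1_igfbp2_corr = adrb1_igfbp2_corr, seed = seed),
    class = "cell_sim_config"
  )
}

#' Generate a synthetic per-cell intensity table
#'
#' @param config A [cell_sim_config()].
#' @return A list of class `cell_sim`:
#'   * `cells` - tibble `cell_id`, `sample_id`, `condition`, then one
#'     intensity column per gene;
#'   * `truth` - per-cell `fos_high` labels, the configured latent
#'     correlation and the seed.
#' @examples
#' sim <- simulate_cell_table(cell_sim_config(n_cells_per_sample = 10,
#'                                            n_samples_per_condition = 2))
#' head(sim$cells)
#' @export
simulate_cell_table <- function(config = cell_sim_config()) {
  genes <- names(config$base_means)
  other <- setdiff(genes, "Slc1a3")
  n_per_cond <- config$n_cells_per_sample * config$n_samples_per_condition
  n <- n_per_cond * length(config$conditions)

  condition <- rep(config$conditions, each = n_per_cond)
  sample_id <- sprintf(
    "%s_s%d", condition,
    rep(rep(seq_len(config$n_samples_per_condition),
            each = config$n_cells_per_sample),
        times = length(config$conditions))
  )
  cell_id <- sprintf("cell_%05d", seq_len(n))

  cond_mult <- function(gene) {
    eff <- config$condition_effects[[gene]]
    m <- rep(1, n)
    if (!is.null(eff)) {
      hit <- condition %in% names(eff)
      m[hit] <- unname(eff[condition[hit]])
    }
    m
  }

  rho <- config$adrb1_igfbp2_corr
  out <- with_seed(config$seed, {
    sigma_s <- sqrt(log(1 + config$marker_cv^2))
    slc <- config$base_means[["Slc1a3"]] * exp(sigma_s * rnorm(n))
    fos_high <- runif(n) < config$fos_high_fraction

    z <- matrix(rnorm(n * length(other)), nrow = n,
                dimnames = list(NULL, other))
    if (all(c("Adrb1", "Igfbp2") %in% other) && rho != 0) {
      # Gaussian copula: correlate the two latent factors
      z1 <- z[, "Adrb1"]
      z2 <- z[, "Igfbp2"]
      z[, "Igfbp2"] <- rho * z1 + sqrt(1 - rho^2) * z2
    }

    intensities <- list(Slc1a3 = slc)
    for (g in other) {
      mult <- config$base_means[[g]] * cond_mult(g)
      if (g == "Fos") mult <- mult * ifelse(fos_high, config$fos_high_multiplier, 1)
      intensities[[g]] <- slc * mult * exp(config$gene_sigma * z[, g])
    }
    list(intensities = intensities, fos_high = fos_high)
  })

  cells <- tibble::tibble(cell_id = cell_id, sample_id = sample_id,
                          condition = condition)
  for (g in genes) cells[[g]] <- out$intensities[[g]]

  structure(
    list(cells = cells,
         truth = list(fos_high = tibble::tibble(cell_id = cell_id,
                                                fos_high = out$fos_high),
                      adrb1_igfbp2_corr = rho, seed = config$seed)),
    class = "cell_sim"
  )
}
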