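#' Configuration for synthetic brain-region count tables
#'
#' Region-by-subject Fos-tagged astrocyte counts are drawn independently
#' from a negative binomial with `variance = mean + mean^2 / dispersion`.
#' The four-group design defaults to the study layout NoFC = 6, FC = 4,
#' NoFR = 4, FR = 4 subjects. Designated effect regions have their
#' FR-group mean multiplied by `effect_multiplier`; `effect_multiplier = 1`
#' gives a global null in which no region's generating distribution
#' depends on group.
#'
#' @param n_regions Number of analysable regions.
#' @param group_sizes Named integer vector, subjects per group.
#' @param nb_mean Negative-binomial mean of the baseline count.
#' @param nb_dispersion Negative-binomial dispersion (`size`); smaller
#'   values mean more overdispersion.
#' @param effect_regions Integer indices (1-based) of regions whose FR
#'   mean is shifted.
#' @param effect_multiplier Multiplier applied to the FR-group mean in
#'   effect regions.
#' @param region_sizes Region volumes in mm^3 (recycled across regions).
#' @param n_ventricular,n_aggregate Number of additional flagged regions
#'   appended to the ontology (and count table) that a density screen
#'   should exclude: ventricular-niche regions prone to neuronal leakage
#'   and high-level aggregate structures. Defaults 0.
#' @param seed Integer seed.
#' @return A list of class `region_sim_config`.
#' @export
region_sim_config <- function(n_regions = 100,
                              group_sizes = c(NoFC = 6, FC = 4, NoFR = 4, FR = 4),
                              nb_mean = 20,
                              nb_dispersion = 2,
                              effect_regions = integer(),
                              effect_multiplier = 1,
                              region_sizes = 1,
                              n_ventricular = 0,
                              n_aggregate = 0,
                              seed = 0) {
  if (n_regions < 1) abort("`n_regions` must be at least 1.")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a named vector.")
  }
  if (any(group_sizes < 1)) abort("Every group needs at least one subject.")
  if (nb_mean <= 0 || nb_dispersion <= 0 || effect_multiplier <= 0) {
    abort("`nb_mean`, `nb_dispersion` and `effect_multiplier` must be positive.")
  }
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 1) || any(effect_regions > n_regions))) {
    abort("`effect_regions` must index regions 1..n_regions.")
  }
  if (any(region_sizes <= 0)) abort("Region sizes must be positive.")
  structure(
    list(n_regions = n_regions, group_sizes = group_sizes, nb_mean = nb_mean,
         nb_dispersion = nb_dispersion, effect_regions = effect_regions,
         effect_multiplier = effect_multiplier, region_sizes = region_sizes,
         n_ventricular = n_ventricular, n_aggregate = n_aggregate,
         seed = seed),
    class = "region_sim_config"
  )
}

#' Generate a synthetic region ontology and count table
#'
#' @param config A [region_sim_config()].
#' @return A list of class `region_sim`:
#'   * `ontology` - tibble with `id`, `acronym`, `name`, `parent_id`,
#'     `size_mm3`, `is_ventricular`, `is_aggregate`. Aggregate regions are
#'     parents of the analysable regions that follow them; analysable and
#'     ventricular regions are leaves.
#'   * `counts` - long tibble `region_id`, `subject_id`, `group`, `count`
#'     covering every region (flagged ones included, so exclusion is
#'     exercisable downstream).
#'   * `subjects` - tibble `subject_id`, `group`.
#'   * `truth` - effect-region ids, multiplier and seed.
#' @examples
#' sim <- simulate_region_counts(region_sim_config(n_regions = 5, seed = 1))
#' head(sim$counts)
#' @export
simulate_region_counts <- function(config = region_sim_config()) {
  groups <- rep(names(config$group_sizes), config$group_sizes)
  subjects <- tibble::tibble(
    subject_id = sprintf("%s_%d", groups,
                         unlist(lapply(config$group_sizes, seq_len))),
    group = groups
  )

  n_core <- config$n_regions
  n_extra <- config$n_ventricular + config$n_aggregate
  ids <- seq_len(n_core + n_extra)
  is_vent <- c(rep(FALSE, n_core), rep(TRUE, config$n_ventricular),
               rep(FALSE, config$n_aggregate))
  is_agg <- c(rep(FALSE, n_core + config$n_ventricular),
              rep(TRUE, config$n_aggregate))
  # aggregates act as parents of a slice of the analysable regions
  parent <- rep(NA_integer_, length(ids))
  if (config$n_aggregate > 0) {
    agg_ids <- ids[is_agg]
    slice <- if (config$n_aggregate == 1) rep(1L, n_core) else
      cut(seq_len(n_core), breaks = config$n_aggregate, labels = FALSE)
    parent[seq_len(n_core)] <- agg_ids[slice]
  }
  ontology <- tibble::tibble(
    id = ids,
    acronym = sprintf("R%03d", ids),
    name = sprintf("synthetic region %d", ids),
    parent_id = parent,
    size_mm3 = rep_len(config$region_sizes, length(ids)),
    is_ventricular = is_vent,
    is_aggregate = is_agg
  )

  mu <- matrix(config$nb_mean, nrow = length(ids), ncol = nrow(subjects))
  if (length(config$effect_regions)) {
    fr_cols <- which(subjects$group == "FR")
    mu[config$effect_regions, fr_cols] <-
      mu[config$effect_regions, fr_cols] * config$effect_multiplier
  }
  counts <- with_seed(config$seed, {
    matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
           nrow = nrow(mu))
  })

  counts_tbl <- tibble::tibble(
    region_id = rep(ids, times = nrow(subjects)),
    subject_id = rep(subjects$subject_id, each = length(ids)),
    group = rep(subjects$group, each = length(ids)),
    count = as.integer(counts)
  )

  structure(
    list(ontology = ontology, counts = counts_tbl, subjects = subjects,
         truth = list(effect_regions = config$effect_regions,
                      effect_multiplier = config$effect_multiplier,
                      seed = config$seed)),
    class = "region_sim"
  )
}
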