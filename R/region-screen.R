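#' Convert region counts to densities
#'
#' Divides each region-by-subject count by the region's size taken from
#' the ontology: cells per mm^3 in volumetric (`"3D"`) mode, cells per
#' mm^2 in slice (`"2D"`) mode (where the ontology sizes are areas).
#'
#' @param counts Long tibble with `region_id`, `subject_id`, `group`,
#'   `count`.
#' @param ontology Tibble with `id` and `size_mm3` (interpreted as mm^2 in
#'   2D mode).
#' @param mode `"3D"` (volume) or `"2D"` (slice).
#' @return The input tibble with a `density` column added; the mode is
#'   recorded in the `"mode"` attribute.
#' @examples
#' counts <- tibble::tibble(region_id = 1, subject_id = "a",
#'                          group = "FR", count = 30L)
#' ont <- tibble::tibble(id = 1, size_mm3 = 0.2)
#' make_density(counts, ont)$density  # 150 cells / mm^3
#' @export
make_density <- function(counts, ontology, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  missing <- setdiff(unique(counts$region_id), ontology$id)
  if (length(missing)) {
    abort(sprintf("Regions missing from the ontology: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sizes <- ontology$size_mm3[match(counts$region_id, ontology$id)]
  if (any(sizes <= 0)) abort("Region sizes must be positive.")
  out <- counts
  out$density <- counts$count / sizes
  attr(out, "mode") <- mode
  out
}

#' Drop flagged regions from a count or density table
#'
#' Removes rows for regions flagged as ventricular niches (where
#' neuronal leakage contaminates astrocyte counts) and/or high-level
#' aggregate structures (for example whole midbrain or thalamus). Only
#' the flagged rows themselves are removed: children of a dropped
#' aggregate are kept.
#'
#' @param table Tibble with a `region_id` column.
#' @param ontology Tibble with `id`, `is_ventricular`, `is_aggregate`.
#' @param drop_ventricular,drop_aggregates Which flags to apply.
#' @return The filtered table. The removals (region id and reason) are
#'   recorded in the `"exclusion_log"` attribute.
#' @export
filter_regions <- function(table, ontology, drop_ventricular = TRUE,
                           drop_aggregates = TRUE) {
  flags <- ontology[match(unique(table$region_id), ontology$id), ]
  if (anyNA(flags$id)) abort("Some regions in the table lack ontology flags.")
  drop <- character(0)
  log <- tibble::tibble(region_id = flags$id[0], reason = character(0))
  if (drop_ventricular) {
    v <- flags$id[flags$is_ventricular]
    log <- dplyr::bind_rows(log, tibble::tibble(region_id = v,
                                                reason = "ventricular_niche"))
  }
  if (drop_aggregates) {
    a <- flags$id[flags$is_aggregate & !(drop_ventricular & flags$is_ventricular)]
    log <- dplyr::bind_rows(log, tibble::tibble(region_id = a,
                                                reason = "aggregate_structure"))
  }
  out <- table[!table$region_id %in% log$region_id, , drop = FALSE]
  if (!nrow(out)) warn("All regions were excluded.")
  attr(out, "exclusion_log") <- log
  out
}

value_column <- function(table) {
  for (col in c("density", "count", "value")) {
    if (col %in% names(table)) return(col)
  }
  abort("Table needs a `density`, `count` or `value` column.")
}

#' Group fold changes per region
#'
#' For each region, the fold change of group g is the mean value
#' (density by default) of g divided by the mean of the reference group.
#' When the reference mean is zero the fold change is undefined and
#' returned as `NA` (never infinite).
#'
#' @param table Long tibble with `region_id`, `group` and a `density`,
#'   `count` or `value` column.
#' @param reference_group Reference group name (default `"NoFC"`, the
#'   non-shocked control).
#' @return Tibble `region_id`, `group`, `fold_change`.
#' @export
fold_changes <- function(table, reference_group = "NoFC") {
  col <- value_column(table)
  if (!reference_group %in% table$group) {
    abort(sprintf("Reference group '%s' not present.", reference_group))
  }
  means <- table |>
    dplyr::group_by(.data$region_id, .data$group) |>
    dplyr::summarise(m = mean(.data[[col]]), .groups = "drop")
  ref <- means |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::select("region_id", ref_m = "m")
  means |>
    dplyr::left_join(ref, by = "region_id") |>
    dplyr::mutate(fold_change = dplyr::if_else(.data$ref_m > 0,
                                               .data$m / .data$ref_m,
                                               NA_real_)) |>
    dplyr::select("region_id", "group", "fold_change")
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate adjustment over one pooled family of
#' p-values, with flags at `q < alpha`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return Tibble `p`, `q`, `significant`.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  tibble::tibble(p = pvalues, q = q, significant = !is.na(q) & q < alpha)
}

# Closed-form one-way decomposition. The screen visits thousands of
# regions per dataset, so the routed tests are computed directly from
# group sums; stats::aov / TukeyHSD / kruskal.test / car::leveneTest are
# the independent oracles for these formulas in the test suite.
oneway_decomp <- function(value, group) {
  gs <- split(value, group)
  ns <- lengths(gs)
  k <- length(gs)
  n <- length(value)
  means <- vapply(gs, mean, numeric(1))
  grand <- mean(value)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(gs, function(x) sum((x - mean(x))^2), numeric(1)))
  df2 <- n - k
  mse <- ssw / df2
  f <- if (mse > 0) (ssb / (k - 1)) / mse else if (ssb > 0) Inf else NaN
  p <- if (is.nan(f)) NA_real_ else
    stats::pf(f, k - 1, df2, lower.tail = FALSE)
  list(f = f, p = p, k = k, df2 = df2, mse = mse, means = means, ns = ns)
}

# Brown-Forsythe variant of Levene's test: one-way ANOVA on absolute
# deviations from the group medians.
levene_bf_p <- function(value, group) {
  gs <- split(value, group)
  z <- unlist(lapply(gs, function(x) abs(x - stats::median(x))),
              use.names = FALSE)
  g <- rep(names(gs), lengths(gs))
  oneway_decomp(z, g)$p
}

# Tukey-Kramer honest significant difference p-values from a one-way fit.
tukey_posthoc <- function(dec) {
  cmb <- utils::combn(names(dec$means), 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  diff <- dec$means[b] - dec$means[a]   # "B-A" labelling, as TukeyHSD
  se <- sqrt(dec$mse / 2 * (1 / dec$ns[a] + 1 / dec$ns[b]))
  q <- abs(diff) / se
  q[se == 0] <- Inf
  list(comparison = paste(b, a, sep = "-"), statistic = unname(diff),
       p = stats::ptukey(q, dec$k, dec$df2, lower.tail = FALSE))
}

# Kruskal-Wallis omnibus p with tie correction.
kruskal_p <- function(value, group) {
  rk <- rank(value)
  n <- length(value)
  gs <- split(rk, group)
  ns <- lengths(gs)
  h <- 12 / (n * (n + 1)) *
    sum(ns * (vapply(gs, mean, numeric(1)) - (n + 1) / 2)^2)
  ties <- table(value)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  stats::pchisq(h / corr, length(gs) - 1, lower.tail = FALSE)
}

# Dunn's post hoc test on the pooled Kruskal-Wallis ranking, with tie
# correction; p-values are Bonferroni-adjusted over the m pairwise
# comparisons.
dunn_posthoc <- function(value, group) {
  rk <- rank(value)
  n <- length(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  gs <- split(rk, group)
  means <- vapply(gs, mean, numeric(1))
  ns <- lengths(gs)
  cmb <- utils::combn(names(gs), 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  z <- (means[b] - means[a]) / sqrt(sigma2 * (1 / ns[a] + 1 / ns[b]))
  m <- ncol(cmb)
  list(comparison = paste(b, a, sep = "-"), statistic = unname(z),
       p = pmin(1, 2 * stats::pnorm(-abs(z)) * m))
}

screen_one_region <- function(value, group, min_n, levene_alpha) {
  ns <- table(group)
  if (length(ns) < 2 || any(ns < min_n)) {
    return(list(skip = "insufficient_n"))
  }
  if (length(unique(value)) == 1) {
    return(list(skip = "degenerate_values"))
  }
  levene_p <- levene_bf_p(value, group)
  # groups internally constant: deviations all zero, Levene undefined;
  # variances are (vacuously) homogeneous, so take the parametric route
  homogeneous <- is.na(levene_p) || levene_p > levene_alpha
  if (homogeneous) {
    route <- "anova_tukey"
    dec <- oneway_decomp(value, group)
    omnibus <- dec$p
    post <- tukey_posthoc(dec)
  } else {
    route <- "kw_dunn"
    omnibus <- kruskal_p(value, group)
    post <- dunn_posthoc(value, group)
  }
  list(route = route, levene_p = levene_p, omnibus_p = omnibus, post = post)
}

#' Screen regions for group-dependent ensemble density
#'
#' Per region the analysis is routed by a Brown-Forsythe (median-centred)
#' Levene test: regions with homogeneous variances (Levene p > 0.05) get
#' a one-way ANOVA with Tukey's honest significant difference post hoc
#' test; regions failing Levene's test get a Kruskal-Wallis test with
#' Dunn's post hoc test, Bonferroni-adjusted over the pairwise
#' comparisons. All post hoc p-values are then pooled into a single
#' family - across regions and comparisons - and Benjamini-Hochberg
#' adjusted; a region/comparison is significant at `q < alpha`. Regions
#' with a group below `min_n` subjects, or with all values identical, are
#' skipped with a reason and never enter the FDR family. Omnibus
#' p-values are reported but not FDR-adjusted.
#'
#' @param table Long tibble with `region_id`, `group` and a `density`,
#'   `count` or `value` column (density recommended).
#' @param alpha FDR level for the significance flags.
#' @param min_n Minimum subjects per group for a region to be analysed.
#' @param levene_alpha Routing threshold on the Levene p-value.
#' @return A tibble of class `gliatrace_screen`, one row per region x
#'   pairwise comparison: `region_id`, `route`, `levene_p`, `omnibus_p`,
#'   `comparison`, `statistic`, `p`, `q`, `significant`, `fold_change`
#'   (ratio of the comparison's first group mean to its second group
#'   mean; `NA` when the denominator mean is zero). Skipped regions are
#'   recorded in the `"skipped"` attribute.
#' @export
screen_regions <- function(table, alpha = 0.05, min_n = 3,
                           levene_alpha = 0.05) {
  col <- value_column(table)
  split_tbl <- split(table, table$region_id)
  if (!length(split_tbl)) abort("No regions to analyse.")

  rows <- vector("list", length(split_tbl))
  skipped <- list()
  for (i in seq_along(split_tbl)) {
    d <- split_tbl[[i]]
    rid <- d$region_id[1]
    res <- screen_one_region(d[[col]], d$group, min_n, levene_alpha)
    if (!is.null(res$skip)) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(region_id = rid, reason = res$skip)
      next
    }
    gm <- tapply(d[[col]], d$group, mean)
    post <- res$post
    parts <- strsplit(post$comparison, "-", fixed = TRUE)
    fc <- vapply(parts, function(p) {
      den <- gm[[p[2]]]
      if (is.na(den) || den == 0) NA_real_ else gm[[p[1]]] / den
    }, numeric(1))
    m <- length(post$comparison)
    rows[[i]] <- list(
      region_id = rep(rid, m), route = rep(res$route, m),
      levene_p = rep(res$levene_p, m), omnibus_p = rep(res$omnibus_p, m),
      comparison = post$comparison, statistic = post$statistic,
      p = unname(post$p), fold_change = fc
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- tibble::as_tibble(lapply(
    stats::setNames(nm = c("region_id", "route", "levene_p", "omnibus_p",
                           "comparison", "statistic", "p", "fold_change")),
    function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE)
  ))
  if (!nrow(out)) abort("No analysable region.")
  adj <- bh_adjust(out$p, alpha = alpha)
  out$q <- adj$q
  out$significant <- adj$significant
  out <- out[, c("region_id", "route", "levene_p", "omnibus_p", "comparison",
                 "statistic", "p", "q", "significant", "fold_change")]
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  attr(out, "alpha") <- alpha
  class(out) <- c("gliatrace_screen", class(out))
  out
}

#' Neuron-astrocyte ensemble correlation across selected regions
#'
#' Pearson correlation between two per-region quantities - typically the
#' change in Fos-positive neuron counts and the change in Fos-positive
#' astrocyte counts, each computed as group mean minus reference-group
#' mean - over the regions that survive selection. Selection starts from
#' regions flagged engram-significant and excludes ventricular-leakage
#' regions and high-level aggregate structures; every exclusion is
#' logged.
#'
#' @param regions Tibble with `region_id`, `delta_a`, `delta_b`, and
#'   optional logical columns `engram_significant` (default `TRUE`),
#'   `is_ventricular` and `is_aggregate` (default `FALSE`).
#' @return An object of class `gliatrace_cor`: list with `r`, `p`,
#'   `n_regions` and `selection_log` (tibble `region_id`, `kept`,
#'   `reason`). [tidy()] and [glance()] methods are available.
#' @export
engram_correlation <- function(regions) {
  eng <- if ("engram_significant" %in% names(regions)) {
    regions$engram_significant
  } else rep(TRUE, nrow(regions))
  vent <- if ("is_ventricular" %in% names(regions)) {
    regions$is_ventricular
  } else rep(FALSE, nrow(regions))
  agg <- if ("is_aggregate" %in% names(regions)) {
    regions$is_aggregate
  } else rep(FALSE, nrow(regions))

  reason <- dplyr::case_when(
    !eng ~ "not_engram_significant",
    vent ~ "ventricular_leakage",
    agg ~ "aggregate_structure",
    TRUE ~ "kept"
  )
  keep <- reason == "kept"
  log <- tibble::tibble(region_id = regions$region_id, kept = keep,
                        reason = reason)
  x <- regions$delta_a[keep]
  y <- regions$delta_b[keep]
  if (sum(keep) < 3) abort("Fewer than 3 regions selected; r undefined.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in a selected variable; r undefined.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n_regions = sum(keep),
         selection_log = log),
    class = "gliatrace_cor"
  )
}

#' @export
print.gliatrace_cor <- function(x, ...) {
  cat(sprintf("<gliatrace_cor> Pearson r = %.3f (p = %.3g) over %d regions\n",
              x$r, x$p, x$n_regions))
  dropped <- x$selection_log[!x$selection_log$kept, ]
  if (nrow(dropped)) {
    cat(sprintf("  excluded %d regions (%s)\n", nrow(dropped),
                paste(names(table(dropped$reason)), collapse = ", ")))
  }
  invisible(x)
}
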