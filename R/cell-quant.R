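#' Normalize per-cell gene intensities by the astrocyte marker
#'
#' Divides each gene's intensity by the cell's Slc1a3 (pan-astrocyte
#' marker) intensity, removing soma-size differences. Cells with a
#' non-positive marker intensity cannot be normalized and are excluded
#' (never imputed); exclusions are logged.
#'
#' @param cells Wide tibble: `cell_id`, `sample_id`, `condition`, then one
#'   intensity column per gene, including the marker.
#' @param marker Marker gene column name (default `"Slc1a3"`).
#' @return A long tibble of class `gliatrace_cells`: `cell_id`,
#'   `sample_id`, `condition`, `gene`, `intensity`, `normalized` (the
#'   marker itself is kept as a gene, normalized to 1). Excluded cells are
#'   listed in the `"exclusion_log"` attribute.
#' @export
normalize_by_marker <- function(cells, marker = "Slc1a3") {
  if (!marker %in% names(cells)) {
    abort(sprintf("Marker column '%s' not found.", marker))
  }
  if (anyDuplicated(cells$cell_id)) abort("Duplicate cell ids.")
  bad <- cells[[marker]] <= 0 | !is.finite(cells[[marker]])
  log <- tibble::tibble(cell_id = cells$cell_id[bad],
                        reason = "nonpositive_marker")
  kept <- cells[!bad, , drop = FALSE]
  genes <- setdiff(names(kept), c("cell_id", "sample_id", "condition"))
  long <- kept |>
    tidyr::pivot_longer(dplyr::all_of(genes), names_to = "gene",
                        values_to = "intensity") |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(normalized = .data$intensity /
                    .data$intensity[.data$gene == marker]) |>
    dplyr::ungroup()
  attr(long, "exclusion_log") <- log
  attr(long, "marker") <- marker
  class(long) <- c("gliatrace_cells", class(long))
  long
}

#' Z-score normalized intensities within each sample
#'
#' Standardizes the marker-normalized value of each gene within each
#' sample (section or mouse, as supplied in `sample_id`), using the
#' sample mean and the n-1 standard deviation, so expression can be
#' compared across a heterogeneous cell population.
#'
#' @param stats A `gliatrace_cells` tibble from [normalize_by_marker()].
#' @return The tibble with a `z` column added. Within each sample and
#'   gene, `z` has mean 0 and unit sample variance. The marker gene
#'   itself (normalized identically to 1) gets `NA`.
#' @export
zscore_by_sample <- function(stats) {
  marker <- attr(stats, "marker") %||% "Slc1a3"
  work <- stats[stats$gene != marker, , drop = FALSE]
  check <- work |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(n = dplyr::n(), spread = stats::sd(.data$normalized),
                     .groups = "drop")
  bad <- check[check$n < 2 | check$spread == 0 | !is.finite(check$spread), ]
  if (nrow(bad)) {
    abort(sprintf(
      "Cannot z-score: sample '%s', gene '%s' has %s.",
      bad$sample_id[1], bad$gene[1],
      if (bad$n[1] < 2) "fewer than 2 cells" else "zero spread"
    ))
  }
  out <- stats |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::mutate(z = if (.data$gene[1] == marker) NA_real_ else
      (.data$normalized - mean(.data$normalized)) /
        stats::sd(.data$normalized)) |>
    dplyr::ungroup()
  class(out) <- unique(c("gliatrace_cells", class(out)))
  for (a in c("exclusion_log", "marker")) attr(out, a) <- attr(stats, a)
  out
}

#' Default high-expression z cut-offs
#'
#' Strict thresholds on the within-sample z-score: Fos-high at z > 2
#' (capturing roughly the top 2-3% of cells), Adrb1-high and Igfbp2-high
#' at z > 0.5 (roughly the top quarter). A cell exactly at the cut-off is
#' classified low.
#'
#' @return Named numeric vector of z cut-offs.
#' @export
default_thresholds <- function() {
  c(Fos = 2, Adrb1 = 0.5, Igfbp2 = 0.5)
}

#' Classify cells as high or low expressers
#'
#' Labels a cell "high" for a gene when its within-sample z-score
#' strictly exceeds the gene's cut-off. Genes without a cut-off get `NA`
#' labels.
#'
#' @param stats A z-scored `gliatrace_cells` tibble
#'   ([zscore_by_sample()]).
#' @param thresholds Named numeric vector of z cut-offs; see
#'   [default_thresholds()]. Every named gene must be present in the
#'   data.
#' @return The tibble with a `label` column (`"high"`/`"low"`/`NA`). The
#'   high-cell counts per condition and gene are in the `"label_counts"`
#'   attribute.
#' @export
classify_high <- function(stats, thresholds = default_thresholds()) {
  if (!"z" %in% names(stats)) abort("Run zscore_by_sample() first.")
  missing <- setdiff(names(thresholds), unique(stats$gene))
  if (length(missing)) {
    abort(sprintf("Thresholds name genes absent from the data: %s",
                  paste(missing, collapse = ", ")))
  }
  cut <- thresholds[stats$gene]
  out <- stats
  out$label <- dplyr::if_else(is.na(cut), NA_character_,
                              dplyr::if_else(stats$z > cut, "high", "low"))
  counts <- out |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::group_by(.data$condition, .data$gene) |>
    dplyr::summarise(n_high = sum(.data$label == "high"),
                     n_cells = dplyr::n(),
                     fraction_high = .data$n_high / .data$n_cells,
                     .groups = "drop")
  for (a in c("exclusion_log", "marker")) attr(out, a) <- attr(stats, a)
  attr(out, "label_counts") <- counts
  class(out) <- unique(c("gliatrace_cells", class(out)))
  out
}

#' Per-cell receptor co-expression index
#'
#' For each cell, the product of the two receptors' marker-normalized
#' expression levels, each taken relative to the median of the reference
#' condition (pooled across that condition's samples):
#' `CI = (Adra1a / median_ref(Adra1a)) * (Adrb1 / median_ref(Adrb1))`.
#' A cell sitting at both reference medians has CI = 1. The index uses
#' marker-normalized values (a ratio scale), not z-scores.
#'
#' @param stats A `gliatrace_cells` tibble with `normalized` values.
#' @param gene_a,gene_b The two receptor genes (defaults Adra1a, Adrb1).
#' @param reference_condition Condition whose medians anchor the relative
#'   levels (default `"NoFC"`).
#' @return Tibble `cell_id`, `sample_id`, `condition`,
#'   `coexpression_index`; per-condition medians and IQRs are in the
#'   `"summary"` attribute.
#' @export
coexpression_index <- function(stats, gene_a = "Adra1a", gene_b = "Adrb1",
                               reference_condition = "NoFC") {
  if (!reference_condition %in% stats$condition) {
    abort(sprintf("Reference condition '%s' not present.", reference_condition))
  }
  wide <- stats |>
    dplyr::filter(.data$gene %in% c(gene_a, gene_b)) |>
    dplyr::select("cell_id", "sample_id", "condition", "gene", "normalized") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "normalized")
  if (!all(c(gene_a, gene_b) %in% names(wide))) {
    abort("Both receptor genes must be present.")
  }
  ref <- wide[wide$condition == reference_condition, ]
  med_a <- stats::median(ref[[gene_a]])
  med_b <- stats::median(ref[[gene_b]])
  if (med_a <= 0 || med_b <= 0) {
    abort("Reference-condition median must be positive for both genes.")
  }
  out <- wide |>
    dplyr::mutate(coexpression_index = (.data[[gene_a]] / med_a) *
                    (.data[[gene_b]] / med_b)) |>
    dplyr::select("cell_id", "sample_id", "condition", "coexpression_index")
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(median_ci = stats::median(.data$coexpression_index),
                     iqr_ci = stats::IQR(.data$coexpression_index),
                     n_cells = dplyr::n(), .groups = "drop")
  attr(out, "reference_medians") <- stats::setNames(c(med_a, med_b),
                                                    c(gene_a, gene_b))
  out
}

#' Pearson correlation between two genes' z-scores
#'
#' @param stats A z-scored `gliatrace_cells` tibble.
#' @param gene_a,gene_b Gene names.
#' @param scope `"all"` for one pooled estimate or `"per_condition"` for
#'   one row per condition.
#' @return Tibble `condition` (`"all"` under pooled scope), `r`, `p`,
#'   `n`.
#' @export
gene_correlation <- function(stats, gene_a, gene_b,
                             scope = c("all", "per_condition")) {
  scope <- match.arg(scope)
  if (!"z" %in% names(stats)) abort("Run zscore_by_sample() first.")
  wide <- stats |>
    dplyr::filter(.data$gene %in% c(gene_a, gene_b)) |>
    dplyr::select("cell_id", "condition", "gene", "z") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "z")
  one <- function(d, label) {
    if (nrow(d) < 3) abort("Need at least 3 cells for a correlation.")
    if (stats::sd(d[[gene_a]]) == 0 || stats::sd(d[[gene_b]]) == 0) {
      abort("Degenerate (zero-variance) gene; correlation undefined.")
    }
    ct <- stats::cor.test(d[[gene_a]], d[[gene_b]], method = "pearson")
    tibble::tibble(condition = label, r = unname(ct$estimate),
                   p = ct$p.value, n = nrow(d))
  }
  if (scope == "all") {
    one(wide, "all")
  } else {
    purrr::map_dfr(split(wide, wide$condition),
                   function(d) one(d, d$condition[1]))
  }
}

#' Mann-Whitney rank test between two groups
#'
#' Two-sided Mann-Whitney U test. The p-value is exact (by enumeration of
#' the rank distribution) when both groups have at most 8 observations
#' and there are no ties; otherwise a normal approximation with tie
#' correction is used. `u` is the U statistic of the first group.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @return One-row tibble: `u`, `p`, `n_a`, `n_b`, `method`
#'   (`"exact"`/`"normal"`).
#' @examples
#' rank_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    abort("Both groups must be non-empty.")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = FALSE,
                       alternative = "two.sided")
  )
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 method = if (exact) "exact" else "normal")
}
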