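#' Tidy a region screen result
#'
#' @param x A `gliatrace_screen` object.
#' @param ... Unused.
#' @return The per-region, per-comparison results as a plain tibble.
#' @export
tidy.gliatrace_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gliatrace_screen")
  attr(out, "skipped") <- NULL
  attr(out, "alpha") <- NULL
  tibble::as_tibble(out)
}

#' Summarise a region screen in one row
#'
#' @param x A `gliatrace_screen` object.
#' @param ... Unused.
#' @return One-row tibble: regions analysed/skipped, comparisons, routes,
#'   significant comparisons and regions, and the FDR level.
#' @export
glance.gliatrace_screen <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble::tibble(
    n_regions = dplyr::n_distinct(x$region_id),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped),
    n_comparisons = nrow(x),
    n_anova_tukey = dplyr::n_distinct(x$region_id[x$route == "anova_tukey"]),
    n_kw_dunn = dplyr::n_distinct(x$region_id[x$route == "kw_dunn"]),
    n_significant = sum(x$significant),
    n_significant_regions = dplyr::n_distinct(x$region_id[x$significant]),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' Tidy an ensemble correlation result
#'
#' @param x A `gliatrace_cor` object.
#' @param ... Unused.
#' @return One-row tibble with `r`, `p`, `n_regions`.
#' @export
tidy.gliatrace_cor <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_regions = x$n_regions)
}

#' Summarise an ensemble correlation, including the selection
#'
#' @param x A `gliatrace_cor` object.
#' @param ... Unused.
#' @return One-row tibble with the estimate and selection bookkeeping.
#' @export
glance.gliatrace_cor <- function(x, ...) {
  tibble::tibble(
    r = x$r, p = x$p, n_regions = x$n_regions,
    n_candidates = nrow(x$selection_log),
    n_excluded = sum(!x$selection_log$kept)
  )
}
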