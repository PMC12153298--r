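# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname ifrc_correlates
#' @param x An `ifrc_fit`.
#' @param ... Unused.
#' @export
tidy.ifrc_fit <- function(x, ...) {
  cf <- stats::coef(summary(x$model))
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
}

#' @rdname ifrc_correlates
#' @export
glance.ifrc_fit <- function(x, ...) {
  tibble(
    slope = unname(stats::coef(x$model)[2]),
    r = x$r, p = x$p, r_undefined = x$r_undefined,
    n = nrow(x$data), response = x$response,
    log_response = x$log_response
  )
}

#' @rdname ifrc_summary
#' @param x An `ifrc_profile`.
#' @param ... Unused.
#' @export
tidy.ifrc_profile <- function(x, ...) as_tibble(x)

#' @rdname ifrc_summary
#' @export
glance.ifrc_profile <- function(x, ...) attr(x, "aggregate")

#' Aggregate statistics of an ifRC profile
#'
#' @param profile An `ifrc_profile`.
#' @return One-row tibble of the pooled statistics.
#' @export
ifrc_aggregate <- function(profile) attr(profile, "aggregate")

#' @rdname filtered_3utr_set
#' @param x A `filtered_utr_set`.
#' @param ... Unused.
#' @export
glance.filtered_utr_set <- function(x, ...) {
  tibble(
    fraction = attr(x, "fraction"),
    n = nrow(x),
    mean_gc_downstream = mean(x$gc_downstream, na.rm = TRUE),
    n_short_flank = sum(x$short_flank)
  )
}

#' @rdname resampled_binomial_test
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @rdname resampled_binomial_test
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_sites = attr(x, "n_sites"),
    n_iter = attr(x, "n_iter") %||% NA_integer_,
    n_sample = attr(x, "n_sample") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_,
    m = attr(x, "m") %||% NA_integer_,
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_
  )
}

#' @rdname call_somy
#' @param x A `somy_calls` tibble.
#' @param ... Unused.
#' @export
glance.somy_calls <- function(x, ...) {
  cls <- table(x$somy_class)
  bind_cols(
    tibble(median_coverage = attr(x, "median_coverage"),
           n_scaffolds = nrow(x), n_used = attr(x, "n_used")),
    as_tibble(as.list(cls))
  )
}

#' @rdname category_compare
#' @param x A `category_comparison`.
#' @param ... Unused.
#' @export
tidy.category_comparison <- function(x, ...) as_tibble(x)

#' @rdname category_compare
#' @export
glance.category_comparison <- function(x, ...) {
  tibble(n_pairs = nrow(x), n_significant = sum(x$p_adj < 0.05),
         n_sub = attr(x, "n_sub"), seed = attr(x, "seed"))
}
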