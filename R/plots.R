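# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile geom_hline geom_smooth facet_wrap labs scale_fill_gradient2
#'   theme_minimal
#' @export
ggplot2::autoplot

#' @rdname downstream_stop_profile
#' @param object A `stop_context_profile`.
#' @param ... Unused.
#' @export
autoplot.stop_context_profile <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(rate = .data$count / pmax(1L, .data$denominator),
           frame = paste("frame", .data$frame))
  ggplot(d, aes(x = .data$position, y = .data$rate)) +
    geom_col(fill = "grey25") +
    facet_wrap(~frame, ncol = 1) +
    labs(x = "triplet position after the genuine stop",
         y = "fraction of genes with a stop triplet") +
    theme_minimal()
}

#' @rdname upstream_stop_profile
#' @param profile Output tibble of [upstream_stop_profile()].
#' @export
plot_upstream_stops <- function(profile) {
  d <- profile %>% mutate(rate = .data$count / pmax(1L, .data$denominator))
  ggplot(d, aes(x = .data$position, y = .data$rate, fill = .data$triplet)) +
    geom_col(position = "dodge") +
    labs(x = "codon position before the genuine stop", y = "fraction of genes",
         fill = "triplet") +
    theme_minimal()
}

#' @rdname resampled_binomial_test
#' @param object An `enrichment_result`.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(position = factor(.data$position, levels = unique(.data$position)))
  p <- ggplot(d, aes(x = .data$position, y = .data$nt,
                     fill = .data$log2_enrichment)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0) +
    labs(x = "position relative to anchor codon", y = NULL,
         fill = "log2 enrichment") +
    theme_minimal()
  if ("significant" %in% names(d)) {
    p <- p + geom_point(data = d %>% filter(.data$significant),
                        aes(x = .data$position, y = .data$nt),
                        shape = 8, size = 2, inherit.aes = FALSE)
  }
  p
}

#' @rdname zigzag_au_profile
#' @param object A `zigzag_profile`.
#' @param ... Unused.
#' @export
autoplot.zigzag_profile <- function(object, ...) {
  d <- as_tibble(object) %>% filter(.data$nt %in% c("A", "T"))
  ggplot(d, aes(x = .data$position, y = .data$freq, colour = .data$nt)) +
    geom_line() +
    facet_wrap(~side, ncol = 1) +
    labs(x = "position relative to the terminator", y = "frequency",
         colour = "nucleotide") +
    theme_minimal()
}

#' @rdname call_somy
#' @param object A `somy_calls` tibble.
#' @param ... Unused.
#' @export
autoplot.somy_calls <- function(object, ...) {
  d <- as_tibble(object) %>% mutate(rank = rank(-.data$length, ties.method = "first"))
  ggplot(d, aes(x = .data$rank, y = .data$ratio, colour = .data$somy_class)) +
    geom_point() +
    geom_hline(yintercept = c(0.5, 1, 1.5, 2), linetype = "dotted") +
    labs(x = "scaffold (by size rank)", y = "coverage ratio R",
         colour = "somy") +
    theme_minimal()
}

#' @rdname ifrc_correlates
#' @param object An `ifrc_fit`.
#' @export
autoplot.ifrc_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$ifrc_freq, y = .data$response)) +
    geom_point(alpha = 0.4) +
    geom_smooth(method = "lm", formula = y ~ x, colour = "deeppink",
                se = FALSE) +
    labs(x = "ifRC frequency",
         y = if (object$log_response) paste0("log(", object$response, ")") else object$response) +
    theme_minimal()
}
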