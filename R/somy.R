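# Scaffold somy classification from window read depths via median-of-means
# coverage ratios.

SOMY_LEVELS <- c("sub_monosomic", "monosomic", "disomic", "trisomic",
                 "tetrasomic", "pentasomic_or_higher")

#' Median-of-means coverage per scaffold
#'
#' The median of the non-overlapping window mean depths of each scaffold, a
#' robust per-scaffold coverage estimate.
#'
#' @param windows Tibble `scaffold`, `start`, `end`, `depth` (as from
#'   [read_coverage_bedgraph()] or [simulate_coverage_track()]).
#' @return Tibble `scaffold`, `mom`, `n_windows`.
#' @export
scaffold_mom <- function(windows) {
  if (!nrow(windows)) abort("scaffold_mom: no windows.")
  windows %>%
    group_by(.data$scaffold) %>%
    summarise(mom = stats::median(.data$depth), n_windows = dplyr::n(),
              .groups = "drop")
}

#' Median genome coverage from the largest scaffolds
#'
#' The median of the per-scaffold MOM estimates of the 100 largest
#' scaffolds, assuming most scaffolds are disomic. When fewer scaffolds are
#' available all are used and the result is flagged.
#'
#' @param moms Tibble `scaffold`, `mom` (from [scaffold_mom()]).
#' @param lengths Tibble `scaffold`, `length`.
#' @param n_largest Number of scaffolds entering the median (default 100).
#' @return List with `median_coverage`, `n_used`, `all_used`.
#' @export
genome_median_coverage <- function(moms, lengths, n_largest = 100) {
  d <- moms %>% inner_join(lengths, by = "scaffold") %>%
    arrange(desc(.data$length))
  if (!nrow(d)) abort("genome_median_coverage: no scaffolds.")
  used <- utils::head(d, n_largest)
  list(median_coverage = stats::median(used$mom),
       n_used = nrow(used), all_used = nrow(d) <= n_largest)
}

#' Classify somy from the coverage ratio R
#'
#' R is the scaffold's MOM coverage divided by the median genome coverage.
#' Bins: R < 0.25 sub-monosomic; \[0.25, 0.75) monosomic; \[0.75, 1.25\]
#' disomic; (1.25, 1.75\] trisomic; (1.75, 2.25\] tetrasomic; > 2.25
#' pentasomic or higher (bin centres at k/2).
#'
#' @param R Numeric vector of coverage ratios (>= 0).
#' @return Factor with the somy class levels.
#' @export
classify_somy <- function(R) {
  if (any(R < 0)) abort("coverage ratio R must be non-negative.")
  cls <- dplyr::case_when(
    R < 0.25 ~ "sub_monosomic",
    R < 0.75 ~ "monosomic",
    R <= 1.25 ~ "disomic",
    R <= 1.75 ~ "trisomic",
    R <= 2.25 ~ "tetrasomic",
    TRUE ~ "pentasomic_or_higher"
  )
  factor(cls, levels = SOMY_LEVELS)
}

#' Call somy for every scaffold
#'
#' Runs [scaffold_mom()], [genome_median_coverage()] and [classify_somy()]
#' over a window depth table.
#'
#' @param windows Tibble `scaffold`, `start`, `end`, `depth`.
#' @param lengths Tibble `scaffold`, `length`; inferred from the windows'
#'   maximal `end` when omitted.
#' @param n_largest Scaffolds entering the genome median (default 100).
#' @return Tibble `scaffold`, `length`, `mom`, `ratio`, `somy_class` of
#'   class `somy_calls`, with the genome median in the `median_coverage`
#'   attribute.
#' @export
call_somy <- function(windows, lengths = NULL, n_largest = 100) {
  if (is.null(lengths)) {
    lengths <- windows %>% group_by(.data$scaffold) %>%
      summarise(length = max(.data$end), .groups = "drop")
  }
  moms <- scaffold_mom(windows)
  med <- genome_median_coverage(moms, lengths, n_largest)
  calls <- moms %>%
    inner_join(lengths, by = "scaffold") %>%
    mutate(ratio = .data$mom / med$median_coverage,
           somy_class = classify_somy(.data$ratio)) %>%
    select("scaffold", "length", "mom", "ratio", "somy_class")
  structure(calls, class = c("somy_calls", class(tibble())),
            median_coverage = med$median_coverage, n_used = med$n_used,
            all_used = med$all_used)
}
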