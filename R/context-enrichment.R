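# Background-normalised nucleotide enrichment around anchored codons, the
# resampled Bonferroni-binomial significance procedure, and Cohen's-h sample
# sizing.

NT4 <- c("A", "C", "G", "T")

motif_cell_counts <- function(motifs) {
  width <- nchar(motifs[1])
  if (any(nchar(motifs) != width)) abort("motif windows must have equal width.")
  counts <- matrix(0L, nrow = width, ncol = 4, dimnames = list(NULL, NT4))
  denom <- integer(width)
  for (k in seq_len(width)) {
    b <- substring(motifs, k, k)
    for (nt in NT4) counts[k, nt] <- sum(b == nt)
    denom[k] <- sum(b %in% NT4)
  }
  list(counts = counts, denom = denom, width = width)
}

motif_labels_for <- function(motifs) {
  flank <- attr(motifs, "flank")
  width <- nchar(motifs[1])
  if (!is.null(flank) && width == 2 * flank + 3) return(motif_position_labels(flank))
  as.character(seq_len(width))
}

#' Background-normalised enrichment logo
#'
#' Per position and nucleotide, the observed probability across motif
#' windows divided by the background probability ("normalised to the average
#' nucleotide content of all coding sequences"), with the log2 display
#' transform. `N` symbols are excluded from per-position denominators.
#'
#' @param motifs Character vector of equal-width windows (e.g. from
#'   [simulate_motifs()] or cut around stop codons); a `flank` attribute
#'   labels positions relative to the anchor codon.
#' @param background Named probabilities over A, C, G, T summing to 1.
#' @return Tibble `position`, `offset`, `nt`, `n`, `denominator`, `prob`,
#'   `p0`, `enrichment`, `log2_enrichment` of class `enrichment_result`.
#' @export
enrichment_logo <- function(motifs, background) {
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1.")
  cc <- motif_cell_counts(motifs)
  labels <- motif_labels_for(motifs)
  res <- purrr::map_dfr(seq_len(cc$width), function(k) {
    purrr::map_dfr(NT4, function(nt) {
      x <- unname(cc$counts[k, nt])
      p0 <- unname(background[[nt]])
      if (p0 == 0 && x > 0) {
        abort(sprintf("nucleotide %s observed at position %s but has zero background probability.",
                      nt, labels[k]))
      }
      prob <- if (cc$denom[k] > 0) x / cc$denom[k] else NA_real_
      tibble(position = labels[k], offset = k, nt = nt,
             n = as.integer(x), denominator = cc$denom[k],
             prob = prob, p0 = p0,
             enrichment = if (p0 > 0) prob / p0 else NA_real_,
             log2_enrichment = if (p0 > 0 && !is.na(prob) && prob > 0) log2(prob / p0) else NA_real_)
    })
  })
  structure(res, class = c("enrichment_result", class(tibble())),
            n_sites = length(motifs))
}

#' Required sample size from Cohen's h
#'
#' Two-proportion sizing with Cohen's effect size for proportions,
#' h = 2 asin(sqrt(p0 + delta)) - 2 asin(sqrt(p0)), and the two-tailed
#' Z-test approximation: n = ceil(((z_{1-alpha/2} + z_{power}) / h)^2).
#'
#' @param p0 Baseline proportion.
#' @param delta Detectable difference (default 0.10).
#' @param power Statistical power (default 0.9).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Required sample size per group (integer).
#' @export
required_sample_size <- function(p0, delta = 0.10, power = 0.9, alpha = 0.05) {
  if (any(delta <= 0)) abort("delta must be positive.")
  if (any(p0 <= 0) || any(p0 + delta >= 1)) {
    abort("need 0 < p0 and p0 + delta < 1.")
  }
  h <- 2 * asin(sqrt(p0 + delta)) - 2 * asin(sqrt(p0))
  as.integer(ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / h)^2))
}

# Memoised two-sided exact binomial p-value.
binom_p_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(x, n, p0) {
    key <- paste(x, n, format(p0, digits = 12), sep = "|")
    got <- env[[key]]
    if (is.null(got)) {
      got <- stats::binom.test(x, n, p0, alternative = "two.sided")$p.value
      env[[key]] <- got
    }
    got
  }
}

#' Resampled Bonferroni-binomial enrichment test
#'
#' Significance of positional nucleotide enrichment assessed by a
#' Bonferroni-corrected exact binomial test on `n_iter` iterations of
#' randomly subsampled motifs (`n_sample` windows per iteration, without
#' replacement), with per-cell p-values averaged over iterations to account
#' for sampling variability and then corrected over the family of
#' window-positions x 4 nucleotides. With `n_iter = 1` and `n_sample` equal
#' to the site count the averaged p-value reduces to the plain exact
#' binomial p-value.
#'
#' @param motifs Character vector of equal-width windows.
#' @param background Named probabilities over A, C, G, T.
#' @param n_iter Number of resampling iterations (default 40).
#' @param n_sample Motifs per iteration (default 200); when fewer motifs are
#'   available, sampling is with replacement and the result is flagged.
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed.
#' @param correct_then_average Apply the Bonferroni correction within each
#'   iteration before averaging instead of after (alternative reading,
#'   off by default).
#' @return An `enrichment_result` tibble with `p_mean`, `p_bonf` and
#'   `significant` columns; metadata (`n_iter`, `n_sample`, `alpha`, `seed`,
#'   `m`, `with_replacement`) as attributes.
#' @export
resampled_binomial_test <- function(motifs, background, n_iter = 40,
                                    n_sample = 200, alpha = 0.05, seed = 1,
                                    correct_then_average = FALSE) {
  base <- enrichment_logo(motifs, background)
  width <- max(base$offset)
  m <- width * 4
  replace <- length(motifs) < n_sample
  if (replace) {
    warn("fewer motifs than n_sample; sampling with replacement.")
  }
  pv <- binom_p_cache()
  with_seed_(seed, {
    acc <- matrix(0, nrow = width, ncol = 4, dimnames = list(NULL, NT4))
    for (it in seq_len(n_iter)) {
      sub <- motifs[sample.int(length(motifs), n_sample, replace = replace)]
      cc <- motif_cell_counts(sub)
      pit <- matrix(1, nrow = width, ncol = 4, dimnames = list(NULL, NT4))
      for (k in seq_len(width)) {
        for (nt in NT4) {
          if (cc$denom[k] > 0 && background[[nt]] > 0) {
            pit[k, nt] <- pv(cc$counts[k, nt], cc$denom[k], background[[nt]])
          }
        }
      }
      if (correct_then_average) pit <- pmin(1, m * pit)
      acc <- acc + pit
    }
    pmean <- acc / n_iter
    res <- base %>%
      mutate(
        p_mean = pmean[cbind(.data$offset, match(.data$nt, NT4))],
        p_bonf = if (correct_then_average) .data$p_mean else pmin(1, m * .data$p_mean),
        significant = .data$p_bonf < alpha
      )
    structure(res, class = c("enrichment_result", class(tibble())),
              n_sites = length(motifs), n_iter = n_iter, n_sample = n_sample,
              alpha = alpha, seed = seed, m = m, with_replacement = replace,
              correct_then_average = correct_then_average)
  })
}

#' Cut motif windows around the terminator of gene models
#'
#' @param genes Tibble with `id`, `scaffold`, `strand`, `start`, `end`
#'   (terminator = last triplet of `[start, end)` in sense orientation).
#' @param genome Genome tibble.
#' @param flank Flank width (nt) on each side of the terminator.
#' @return Character vector of windows with a `flank` attribute; genes too
#'   close to a scaffold edge are dropped.
#' @export
stop_context_motifs <- function(genes, genome, flank = 6) {
  seqs <- stats::setNames(genome$seq, genome$scaffold)
  lens <- stats::setNames(nchar(genome$seq), genome$scaffold)
  L <- lens[genes$scaffold]
  plus <- genes$strand == "+"
  a <- ifelse(plus, genes$end - 3L - flank, genes$start - flank)
  b <- ifelse(plus, genes$end + flank, genes$start + 3L + flank)
  ok <- a >= 0 & b <= L
  w <- substring(seqs[genes$scaffold[ok]], a[ok] + 1L, b[ok])
  minus <- !plus[ok]
  if (any(minus)) w[minus] <- revcomp(w[minus])
  structure(unname(w), flank = flank, anchor = "stop")
}
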