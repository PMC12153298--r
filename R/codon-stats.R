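# In-frame reassigned-codon statistics, codon adaptation index, ortholog
# abundance transfer, regressions and category comparisons.

GLU1 <- c("GAA", "TAA")
GLU2 <- c("GAG", "TAG")
TRPF <- c("TGG", "TGA")
IFRC <- c("TAA", "TAG", "TGA")

profile_from_counts <- function(counts_wide) {
  g <- function(cod) unname(rowSums(counts_wide[, cod, drop = FALSE]))
  total <- unname(rowSums(counts_wide))
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  col <- function(cod) unname(counts_wide[, cod])
  taa <- col("TAA"); tag <- col("TAG"); tga <- col("TGA")
  gaa <- col("GAA"); gag <- col("GAG"); tgg <- col("TGG")
  denom <- gaa + taa + gag + tag + tgg + tga
  tibble(
    n_codons = as.integer(total),
    glu1 = ifelse(total > 0, g(GLU1) / total, NA_real_),
    glu2 = ifelse(total > 0, g(GLU2) / total, NA_real_),
    trp = ifelse(total > 0, g(TRPF) / total, NA_real_),
    ifrc_freq = ifelse(denom > 0, (taa + tag + tga) / denom, 0),
    pct_uaa = pct(taa, taa + gaa),
    pct_uag = pct(tag, tag + gag),
    pct_uga = pct(tga, tga + tgg)
  )
}

counts_to_wide <- function(counts, ids) {
  wide <- matrix(0L, nrow = length(ids), ncol = 64,
                 dimnames = list(ids, all_codons()))
  wide[cbind(match(counts$id, ids), match(counts$codon, all_codons()))] <- counts$count
  wide
}

#' Per-CDS and aggregate ifRC usage statistics
#'
#' Computes, over internal (terminal-stop-excluded) codons, the Glu1
#' ((GAA+UAA)/codons), Glu2 ((GAG+UAG)/codons) and Trp ((UGG+UGA)/codons)
#' fractions, the ifRC frequency (UAA+UAG+UGA)/(GAA+UAA+GAG+UAG+UGG+UGA),
#' and the per-class percentages UAA% = UAA/(UAA+GAA)*100 (and likewise UAG%
#' and UGA%). Percentages with a zero denominator are reported as `NA`
#' (undefined), not 0.
#'
#' @param cds A `cds_set`.
#' @return Tibble of class `ifrc_profile` with one row per CDS; the same
#'   statistics over the pooled counts are in the `aggregate` attribute and
#'   via [glance.ifrc_profile()].
#' @export
ifrc_summary <- function(cds) {
  counts <- count_codons(cds, drop_terminal = TRUE)
  ids <- cds$id
  wide <- counts_to_wide(counts, ids)
  per_cds <- bind_cols(tibble(id = ids), profile_from_counts(wide))
  agg <- profile_from_counts(matrix(colSums(wide), nrow = 1,
                                    dimnames = list(NULL, colnames(wide))))
  structure(per_cds, class = c("ifrc_profile", class(tibble())),
            aggregate = agg, counts = counts)
}

#' Relative adaptiveness of codons from a reference set
#'
#' For each amino-acid family of the active code (UAA/UAG join the Glu
#' family and UGA the Trp family under the reassigned code), each codon's
#' frequency in the reference set is divided by that of the family's most
#' frequent codon. The reference is either all CDSs with abundance above a
#' threshold or the top-k most abundant; both rules select the highly
#' expressed gene set the index is anchored to. Codons never observed in the
#' reference receive w = 0.5 / (count of the family's most frequent codon).
#'
#' @param cds A `cds_set` (the candidate reference CDSs).
#' @param abundance Optional tibble `id`, `abundance` used to select the
#'   reference subset.
#' @param rule `"abundance"` (keep `abundance > min_abundance`) or `"top_k"`
#'   (keep the `top_k` most abundant).
#' @param min_abundance,top_k Parameters of the two rules (defaults 0.1 A.U.
#'   and 290).
#' @return Tibble `codon`, `aa`, `count`, `w` of class `w_table`.
#' @export
relative_adaptiveness <- function(cds, abundance = NULL,
                                  rule = c("abundance", "top_k"),
                                  min_abundance = 0.1, top_k = 290) {
  rule <- match.arg(rule)
  code <- cds_code(cds)
  if (!is.null(abundance)) {
    sel <- if (rule == "abundance") {
      abundance$id[abundance$abundance > min_abundance]
    } else {
      abundance %>% arrange(desc(.data$abundance)) %>%
        utils::head(top_k) %>% pull(.data$id)
    }
    cds <- cds_set(cds %>% filter(.data$id %in% sel), code)
  }
  if (!nrow(cds)) abort("relative_adaptiveness: empty reference set.")
  agg <- aggregate_codon_counts(count_codons(cds, drop_terminal = TRUE))
  fams <- codon_families(code)
  tab <- fams %>%
    left_join(agg, by = "codon") %>%
    group_by(.data$aa) %>%
    mutate(
      w = {
        mx <- max(.data$count)
        if (mx == 0) rep(NA_real_, length(.data$count))
        else ifelse(.data$count > 0, .data$count / mx, 0.5 / mx)
      }
    ) %>%
    ungroup()
  structure(tab, class = c("w_table", class(tibble())), code = code$name)
}

single_codon_families <- function(code) {
  codon_families(code) %>% count(.data$aa) %>% filter(.data$n == 1) %>% pull(.data$aa)
}

#' Codon adaptation index per CDS
#'
#' CAI is the geometric mean of the relative-adaptiveness values w over a
#' CDS's counted codons. Codons of single-codon families (Met; Trp under the
#' canonical code) carry no usage information and are excluded from the
#' mean, as are canonical-stop triplets outside the active code's sense set.
#'
#' @param cds A `cds_set`.
#' @param w A `w_table` from [relative_adaptiveness()].
#' @return Tibble `id`, `n_codons_scored`, `cai` (`NA` when no codon is
#'   scorable).
#' @export
cai_score <- function(cds, w) {
  code <- cds_code(cds)
  skip_aa <- single_codon_families(code)
  wmap <- w %>% filter(!.data$aa %in% skip_aa)
  lw <- stats::setNames(log(wmap$w), wmap$codon)
  counts <- count_codons(cds, drop_terminal = TRUE) %>%
    filter(.data$codon %in% names(lw))
  res <- counts %>%
    group_by(.data$id) %>%
    summarise(
      n_codons_scored = sum(.data$count),
      cai = exp(sum(.data$count * lw[.data$codon]) / sum(.data$count)),
      .groups = "drop"
    )
  tibble(id = cds$id) %>% left_join(res, by = "id") %>%
    mutate(n_codons_scored = dplyr::coalesce(.data$n_codons_scored, 0L))
}

#' Reciprocal best BLAST hits
#'
#' Pairs (a, b) such that b is a's best hit in the forward table and a is
#' b's best hit in the reverse table. Best = highest bitscore, ties broken
#' by lower e-value then subject id.
#'
#' @param hits_ab,hits_ba Tibbles with `qseqid`, `sseqid`, `bitscore`,
#'   `evalue`.
#' @return Tibble `id_a`, `id_b` of reciprocal pairs.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best <- function(h) {
    h %>%
      arrange(.data$qseqid, desc(.data$bitscore), .data$evalue, .data$sseqid) %>%
      distinct(.data$qseqid, .keep_all = TRUE) %>%
      select("qseqid", "sseqid")
  }
  fwd <- best(hits_ab)
  rev_ <- best(hits_ba)
  fwd %>%
    inner_join(rev_, by = c(qseqid = "sseqid", sseqid = "qseqid")) %>%
    transmute(id_a = .data$qseqid, id_b = .data$sseqid)
}

#' Regress a response (abundance or CAI) on ifRC frequency
#'
#' Least-squares fit of the per-CDS response against ifRC frequency with the
#' Pearson correlation. A log-response option covers skewed abundances; the
#' raw scale is the default.
#'
#' @param profile An `ifrc_profile` (or tibble with `id`, `ifrc_freq`).
#' @param values Tibble `id` plus one response column (e.g. `abundance` or
#'   `cai`).
#' @param log_response Regress `log(response)` instead of the raw response.
#' @return Object of class `ifrc_fit` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
ifrc_correlates <- function(profile, values, log_response = FALSE) {
  resp_col <- setdiff(names(values), "id")[1]
  d <- tibble(id = profile$id, ifrc_freq = profile$ifrc_freq) %>%
    inner_join(values %>% select("id", response = all_of(resp_col)), by = "id") %>%
    filter(!is.na(.data$ifrc_freq), !is.na(.data$response))
  if (nrow(d) < 3) abort("ifrc_correlates needs at least 3 complete pairs.")
  if (log_response) d$response <- log(d$response)
  fit <- stats::lm(response ~ ifrc_freq, data = d)
  constant <- stats::sd(d$response) == 0 || stats::sd(d$ifrc_freq) == 0
  if (constant) {
    r <- 0; p <- NA_real_
  } else {
    ct <- stats::cor.test(d$ifrc_freq, d$response)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(
    list(model = fit, data = d, response = resp_col,
         log_response = log_response, r = r, p = p,
         r_undefined = constant),
    class = "ifrc_fit"
  )
}

#' @export
print.ifrc_fit <- function(x, ...) {
  cat("<ifrc_fit> ", x$response,
      if (x$log_response) " (log)" else "", " ~ ifrc_freq\n", sep = "")
  cat(sprintf("  slope = %.4g, r = %.3f%s, n = %d\n",
              stats::coef(x$model)[2], x$r,
              if (x$r_undefined) " (undefined; constant input)" else "",
              nrow(x$data)))
  invisible(x)
}

#' Pairwise category comparison of a per-gene metric
#'
#' For every pair of categories, `n_sub` genes are subsampled without
#' replacement from each (all genes, flagged, when a category is smaller)
#' and compared by the two-sided Mann-Whitney U test; p-values are
#' Benjamini-Hochberg adjusted across all pairs. Genes annotated with
#' several categories are counted once per category. Categories with fewer
#' than 2 genes are skipped with a warning.
#'
#' @param metric Tibble `id`, `value`.
#' @param categories Tibble `id`, `category` (one row per id-category pair).
#' @param n_sub Subsample size per category (default 40).
#' @param seed Integer seed for the subsampling.
#' @return Tibble `cat_a`, `cat_b`, `n_a`, `n_b`, `used_all`, `statistic`,
#'   `p`, `p_adj` of class `category_comparison`.
#' @export
category_compare <- function(metric, categories, n_sub = 40, seed = 1) {
  d <- categories %>% inner_join(metric, by = "id")
  sizes <- d %>% count(.data$category)
  small <- sizes %>% filter(.data$n < 2)
  if (nrow(small)) {
    warn(paste("categories skipped (<2 genes):",
               paste(small$category, collapse = ", ")))
  }
  cats <- sort(sizes$category[sizes$n >= 2])
  if (length(cats) < 2) abort("category_compare needs at least two usable categories.")
  pairs <- utils::combn(cats, 2)
  with_seed_(seed, {
    res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      xa <- d$value[d$category == a]
      xb <- d$value[d$category == b]
      sub <- function(x) if (length(x) > n_sub) sample(x, n_sub) else x
      sa <- sub(xa); sb <- sub(xb)
      wt <- suppressWarnings(stats::wilcox.test(sa, sb, alternative = "two.sided"))
      tibble(cat_a = a, cat_b = b, n_a = length(sa), n_b = length(sb),
             used_all = length(xa) <= n_sub | length(xb) <= n_sub,
             statistic = unname(wt$statistic), p = wt$p.value)
    })
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    structure(res, class = c("category_comparison", class(tibble())),
              n_sub = n_sub, seed = seed)
  })
}

#' Per-codon usage of cytosolic vs mitochondrial ribosomal gene sets
#'
#' Codon counts are normalised to the total codon count within each gene
#' set, giving comparable per-codon frequencies for the two categories.
#'
#' @param cds A `cds_set`.
#' @param groups Tibble `id`, `group` with groups `"cyto"` and `"mito"`.
#' @return Tibble `codon`, `freq_cyto`, `freq_mito`, `ifrc`.
#' @export
ribosomal_codon_usage <- function(cds, groups) {
  counts <- count_codons(cds, drop_terminal = TRUE) %>%
    inner_join(groups, by = "id") %>%
    group_by(.data$group, .data$codon) %>%
    summarise(count = sum(.data$count), .groups = "drop_last") %>%
    mutate(freq = .data$count / sum(.data$count)) %>%
    ungroup()
  tibble(codon = all_codons()) %>%
    left_join(counts %>% filter(.data$group == "cyto") %>%
                select("codon", freq_cyto = "freq"), by = "codon") %>%
    left_join(counts %>% filter(.data$group == "mito") %>%
                select("codon", freq_mito = "freq"), by = "codon") %>%
    mutate(
      freq_cyto = dplyr::coalesce(.data$freq_cyto, 0),
      freq_mito = dplyr::coalesce(.data$freq_mito, 0),
      ifrc = .data$codon %in% IFRC
    )
}
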