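# GC metrics and ifRC proportions at conserved alignment columns across
# species, with cross-species correlations.

#' Four-fold degenerate codon families
#'
#' Families whose first two bases fix the amino acid under the canonical
#' code (third position free): Ala, Arg4, Gly, Leu4, Pro, Ser4, Thr, Val.
#' The canonical code determines the families for every taxon, since the
#' stop/Glu/Trp reassignments touch no 4-fold family.
#'
#' @return Tibble `prefix`, `aa`, `codon` listing the 32 member codons.
#' @export
fourfold_families <- function() {
  tab <- stats::setNames(STANDARD_AA, all_codons())
  prefixes <- unique(substring(all_codons(), 1, 2))
  purrr::map_dfr(prefixes, function(pre) {
    cods <- paste0(pre, DNA_BASES)
    aas <- unique(unname(tab[cods]))
    if (length(aas) == 1 && aas != "*") {
      tibble(prefix = pre, aa = aas, codon = cods)
    } else {
      tibble(prefix = character(0), aa = character(0), codon = character(0))
    }
  })
}

#' GC content of ORFs and of 4-fold degenerate third positions
#'
#' `gc_orf` is the GC fraction over all counted CDS nucleotides; `gc_4fds`
#' is the GC fraction at third positions of 4-fold degenerate codons, the
#' neutrally evolving proxy for mutational pressure.
#'
#' @param cds A `cds_set` of 5'-complete records.
#' @param drop_terminal Exclude the terminator triplet (default TRUE).
#' @return One-row tibble `gc_orf`, `gc_4fds`, `n_codons`, `n_codons_4fds`,
#'   `flagged` (TRUE when no 4fds codon was seen and `gc_4fds` is `NA`).
#' @export
gc_metrics <- function(cds, drop_terminal = TRUE) {
  counts <- count_codons(cds, drop_terminal = drop_terminal)
  agg <- aggregate_codon_counts(counts)
  bases <- strsplit(agg$codon, "")
  gc_in <- vapply(bases, function(b) sum(b %in% c("G", "C")), numeric(1))
  total_nt <- 3 * sum(agg$count)
  gc_orf <- if (total_nt > 0) sum(agg$count * gc_in) / total_nt else NA_real_
  ff <- fourfold_families()
  agg4 <- agg %>% filter(.data$codon %in% ff$codon)
  n4 <- sum(agg4$count)
  third_gc <- substring(agg4$codon, 3, 3) %in% c("G", "C")
  gc_4fds <- if (n4 > 0) sum(agg4$count[third_gc]) / n4 else NA_real_
  tibble(gc_orf = gc_orf, gc_4fds = gc_4fds,
         n_codons = sum(agg$count), n_codons_4fds = n4,
         flagged = n4 == 0)
}

# Map alignment columns to per-taxon codons; errors name the offending
# row/column when the back-map disagrees with the aligned residues.
align_codon_matrix <- function(alignment, cds_map, code) {
  codes <- resolve_codes(code, alignment$taxon)
  n_taxa <- nrow(alignment)
  aln <- strsplit(alignment$aligned_seq, "")
  width <- length(aln[[1]])
  if (any(vapply(aln, length, integer(1)) != width)) {
    abort("alignment rows have unequal widths.")
  }
  cod <- matrix(NA_character_, nrow = n_taxa, ncol = width)
  aa <- matrix(NA_character_, nrow = n_taxa, ncol = width)
  for (t in seq_len(n_taxa)) {
    codons <- codon_split(cds_map$cds[match(alignment$taxon[t], cds_map$taxon)])
    tab <- internal_table(codes[[t]])
    res <- aln[[t]]
    non_gap <- which(!res %in% c("-", ".", "X", "?"))
    if (length(non_gap) != length(codons)) {
      abort(sprintf("back-map frame inconsistency for taxon %s: %d residues vs %d codons.",
                    alignment$taxon[t], length(non_gap), length(codons)))
    }
    tr <- unname(tab[codons])
    bad <- which(tr != res[non_gap])
    if (length(bad)) {
      abort(sprintf("back-map mismatch for taxon %s at alignment column %d (%s -> %s, aligned %s).",
                    alignment$taxon[t], non_gap[bad[1]], codons[bad[1]],
                    tr[bad[1]], res[non_gap[bad[1]]]))
    }
    cod[t, non_gap] <- codons
    aa[t, ] <- res
  }
  list(codons = cod, aa = aa, taxa = alignment$taxon)
}

resolve_codes <- function(code, taxa) {
  if (inherits(code, "genetic_code")) {
    rep(list(code), length(taxa))
  } else {
    stopifnot(is.list(code), !is.null(names(code)))
    lapply(taxa, function(t) code[[t]])
  }
}

#' ifRC proportions at conserved amino-acid columns
#'
#' Alignment columns where every taxon shows the target amino acid with no
#' gaps or missing data qualify; for each taxon, the proportion of
#' qualifying columns encoded by the reassigned codon is returned:
#' UAR/(UAR+GAR) for glutamate, UGA/(UGA+UGG) for tryptophan.
#'
#' @param alignment Tibble `taxon`, `aligned_seq` (protein alignment).
#' @param cds_map Tibble `taxon`, `cds` (codons of the ungapped residues in
#'   order).
#' @param target_aa `"E"` (Glu) or `"W"` (Trp).
#' @param code A `genetic_code` for all taxa, or a named list per taxon.
#' @return Tibble `taxon`, `target_aa`, `n_cols`, `n_ifrc`, `proportion`.
#' @export
conserved_site_ifrc <- function(alignment, cds_map, target_aa = c("E", "W"),
                                code = build_genetic_code("blastocrithidia")) {
  target_aa <- match.arg(target_aa)
  acm <- align_codon_matrix(alignment, cds_map, code)
  conserved <- which(apply(acm$aa == target_aa, 2, all))
  ifrc_set <- if (target_aa == "E") c("TAA", "TAG") else "TGA"
  purrr::map_dfr(seq_along(acm$taxa), function(t) {
    cods <- acm$codons[t, conserved]
    tibble(taxon = acm$taxa[t], target_aa = target_aa,
           n_cols = length(conserved),
           n_ifrc = sum(cods %in% ifrc_set),
           proportion = if (length(conserved)) mean(cods %in% ifrc_set) else NA_real_)
  })
}

#' Per-species conservation and GC summary
#'
#' Combines [gc_metrics()] on each taxon's back-mapped CDS with the
#' conserved-column ifRC proportions for Glu and Trp.
#'
#' @param alignment,cds_map,code As in [conserved_site_ifrc()].
#' @return Tibble `species`, `gc_orf`, `gc_4fds`, `p_uar`, `p_uga`,
#'   `n_glu_cols`, `n_trp_cols` of class `conservation_summary`.
#' @export
conservation_summary <- function(alignment, cds_map,
                                 code = build_genetic_code("blastocrithidia")) {
  glu <- conserved_site_ifrc(alignment, cds_map, "E", code)
  trp <- conserved_site_ifrc(alignment, cds_map, "W", code)
  codes <- resolve_codes(code, alignment$taxon)
  gc <- purrr::map_dfr(seq_len(nrow(cds_map)), function(t) {
    set <- cds_set(tibble(id = cds_map$taxon[t], scaffold = "aln",
                          start = 0L, end = nchar(cds_map$cds[t]),
                          strand = "+", seq = cds_map$cds[t],
                          complete5 = TRUE, complete3 = FALSE),
                   codes[[t]])
    gc_metrics(set, drop_terminal = FALSE) %>%
      mutate(species = cds_map$taxon[t])
  })
  out <- gc %>%
    select("species", "gc_orf", "gc_4fds") %>%
    left_join(glu %>% select(species = "taxon", p_uar = "proportion",
                             n_glu_cols = "n_cols"), by = "species") %>%
    left_join(trp %>% select(species = "taxon", p_uga = "proportion",
                             n_trp_cols = "n_cols"), by = "species")
  structure(out, class = c("conservation_summary", class(tibble())))
}

#' Correlate species-level GC and ifRC metrics
#'
#' Pearson correlation with two-sided p-value for the pairs (gc_orf,
#' gc_4fds), (gc_orf, p_uar) and (gc_orf, p_uga) across species. Pairs with
#' zero variance are flagged with an undefined r.
#'
#' @param summary A `conservation_summary` (or tibble with those columns).
#' @return Tibble `metric_x`, `metric_y`, `r`, `p`, `n`, `flagged`.
#' @export
correlate_species_metrics <- function(summary) {
  if (nrow(summary) < 3) abort("correlate_species_metrics needs >= 3 species.")
  pairs <- list(c("gc_orf", "gc_4fds"), c("gc_orf", "p_uar"), c("gc_orf", "p_uga"))
  purrr::map_dfr(pairs, function(pr) {
    x <- summary[[pr[1]]]; y <- summary[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    degenerate <- length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0
    if (degenerate) {
      tibble(metric_x = pr[1], metric_y = pr[2], r = NA_real_, p = NA_real_,
             n = length(x), flagged = TRUE)
    } else {
      ct <- stats::cor.test(x, y)
      tibble(metric_x = pr[1], metric_y = pr[2], r = unname(ct$estimate),
             p = ct$p.value, n = length(x), flagged = FALSE)
    }
  })
}
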