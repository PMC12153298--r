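# Homology-guided gene-model construction under the reassigned code:
# HSP merging, boundary extension to in-frame ATG/TAA, spliced-leader start
# correction, overlap reduction, transcript-evidence rescue, and length
# filtering.

#' Configuration for gene-model construction
#'
#' Defaults are the thresholds of the annotation procedure: TBLASTN e-value
#' 1e-10 (max 100 targets), BLASTX e-value 1e-5 for transcript-region rescue
#' at minimum read coverage 10, the spliced-leader sequence with a 6-nt
#' minimum match, up to 10-nt overlaps between gene models, and a 30-aa
#' minimum protein length.
#'
#' @param tblastn_evalue_max,max_targets,blastx_evalue_max,min_transcript_cov
#'   Homology and coverage thresholds.
#' @param sl_seq,sl_min_match Spliced-leader sequence and minimum suffix
#'   match length (nt) for read-based SL scanning.
#' @param max_overlap Maximum tolerated genomic overlap (nt) between models.
#' @param min_protein_aa Minimum predicted protein length (aa).
#' @param start_search_limit,stop_search_limit Search limits (nt) for the
#'   in-frame ATG / terminator scans.
#' @return List of class `gene_model_config`.
#' @export
gene_model_config <- function(tblastn_evalue_max = 1e-10,
                              max_targets = 100,
                              blastx_evalue_max = 1e-5,
                              min_transcript_cov = 10,
                              sl_seq = "AGTTTCTGTACTTTATTG",
                              sl_min_match = 6,
                              max_overlap = 10,
                              min_protein_aa = 30,
                              start_search_limit = 3000,
                              stop_search_limit = 3000,
                              sl_search_window = 500) {
  cfg <- list(tblastn_evalue_max = tblastn_evalue_max,
              max_targets = max_targets,
              blastx_evalue_max = blastx_evalue_max,
              min_transcript_cov = min_transcript_cov,
              sl_seq = sl_seq, sl_min_match = sl_min_match,
              max_overlap = max_overlap, min_protein_aa = min_protein_aa,
              start_search_limit = start_search_limit,
              stop_search_limit = stop_search_limit,
              sl_search_window = sl_search_window)
  if (any(vapply(cfg[!names(cfg) %in% "sl_seq"], function(x) x <= 0, logical(1)))) {
    abort("gene_model_config thresholds must be positive.")
  }
  structure(cfg, class = "gene_model_config")
}

hsp_frame <- function(hsps, scaffold_len) {
  L <- scaffold_len[hsps$sseqid]
  ifelse(hsps$strand == "+", hsps$sstart %% 3L, (L - hsps$send) %% 3L)
}

#' Merge HSPs into candidate ranges
#'
#' Rows above the e-value threshold are dropped. For each query-target pair,
#' only HSPs sharing the strand and frame of the best (highest bitscore) HSP
#' are kept, and their minimum and maximum subject coordinates delimit the
#' candidate range.
#'
#' @param hsps Normalised HSP tibble (see [read_hsps()]).
#' @param genome Genome tibble (`scaffold`, `seq`), for frame arithmetic.
#' @param cfg A [gene_model_config()].
#' @return Tibble with one candidate range per query-target pair: `qseqid`,
#'   `scaffold`, `strand`, `frame` (0-2 in sense space), `min_coord`,
#'   `max_coord`, `n_hsps`, `qstart_min`, `qend_max`, `qlen`.
#' @export
merge_hsps <- function(hsps, genome, cfg = gene_model_config()) {
  if (!nrow(hsps)) {
    return(tibble(qseqid = character(0), sseqid = character(0)))
  }
  slen <- stats::setNames(nchar(genome$seq), genome$scaffold)
  kept <- hsps %>%
    filter(.data$evalue <= cfg$tblastn_evalue_max) %>%
    mutate(frame = hsp_frame(., slen))
  if (!nrow(kept)) {
    return(tibble(qseqid = character(0), scaffold = character(0),
                  strand = character(0), frame = integer(0),
                  min_coord = integer(0), max_coord = integer(0),
                  n_hsps = integer(0), qstart_min = integer(0),
                  qend_max = integer(0), qlen = integer(0)))
  }
  kept %>%
    group_by(.data$qseqid, .data$sseqid) %>%
    group_modify(function(g, key) {
      best <- g[which.max(g$bitscore), ]
      g <- g %>% filter(.data$strand == best$strand, .data$frame == best$frame)
      tibble(
        strand = best$strand, frame = best$frame,
        min_coord = min(g$sstart), max_coord = max(g$send),
        n_hsps = nrow(g),
        qstart_min = min(g$qstart), qend_max = max(g$qend),
        qlen = g$qlen[1]
      )
    }) %>%
    ungroup() %>%
    rename(scaffold = "sseqid")
}

# Sense-space view of a scaffold: for minus-strand models all searches run on
# the reverse complement, with [a, b) mapped to [L - b, L - a).
sense_cache <- function(genome) {
  seqs <- stats::setNames(genome$seq, genome$scaffold)
  rc <- new.env(parent = emptyenv())
  list(
    plus = seqs,
    len = stats::setNames(nchar(genome$seq), genome$scaffold),
    minus = function(scf) {
      if (is.null(rc[[scf]])) rc[[scf]] <- revcomp(seqs[[scf]])
      rc[[scf]]
    }
  )
}

codon_at <- function(s, pos) substring(s, pos + 1L, pos + 3L)

#' Extend candidate ranges to in-frame start and stop codons
#'
#' For each range the start is the in-frame ATG nearest to the 5' homology
#' boundary, searched upstream first and never across an in-frame terminator
#' (which marks the upstream ORF limit); failing that, the first in-frame ATG
#' downstream within the homology region. The stop is the first in-frame
#' triplet from the code's terminal-stop set at or after the 3' boundary
#' (solely TAA under the reassigned code). Models without a reachable ATG or
#' terminator are flagged incomplete, not dropped.
#'
#' @param ranges Output of [merge_hsps()].
#' @param genome Genome tibble.
#' @param code A `genetic_code`.
#' @param cfg A [gene_model_config()].
#' @return Gene-model tibble: `id`, `scaffold`, `strand`, `start`, `end`
#'   (genomic, 0-based half-open, terminator included), `complete5`,
#'   `complete3`, `sl_supported`, `protein_aa`, plus homology bookkeeping
#'   (`hom_start`, `hom_end`, `orf_limit` in sense space).
#' @export
extend_to_boundaries <- function(ranges, genome, code, cfg = gene_model_config()) {
  if (!nrow(ranges)) return(empty_models())
  sc <- sense_cache(genome)
  out <- purrr::pmap_dfr(ranges, function(qseqid, scaffold, strand, frame,
                                          min_coord, max_coord, ...) {
    L <- sc$len[[scaffold]]
    if (strand == "+") {
      s <- sc$plus[[scaffold]]; lo <- min_coord; hi <- max_coord
    } else {
      s <- sc$minus(scaffold); lo <- L - max_coord; hi <- L - min_coord
    }
    # upstream ATG search, stopping at an in-frame terminator
    start <- NA_integer_; orf_limit <- max(0L, lo - cfg$start_search_limit)
    orf_limit <- orf_limit + (lo - orf_limit) %% 3L
    p <- lo
    barrier <- orf_limit
    found <- NA_integer_
    while (p >= orf_limit) {
      cod <- codon_at(s, p)
      if (p < lo && cod %in% code$terminal_stops) { barrier <- p + 3L; break }
      if (is.na(found) && cod == "ATG") found <- p
      p <- p - 3L
    }
    start <- found
    complete5 <- !is.na(start)
    if (!complete5) {
      q <- lo
      while (q + 3L <= hi) {
        if (codon_at(s, q) == "ATG") { start <- q; complete5 <- TRUE; break }
        q <- q + 3L
      }
    }
    if (is.na(start)) start <- lo
    # first in-frame terminator at or after the 3' boundary
    stop_end <- NA_integer_
    q <- hi
    lim <- min(L - 3L, hi + cfg$stop_search_limit)
    while (q <= lim) {
      if (codon_at(s, q) %in% code$terminal_stops) { stop_end <- q + 3L; break }
      q <- q + 3L
    }
    complete3 <- !is.na(stop_end)
    if (!complete3) stop_end <- hi - (hi - start) %% 3L
    prot_aa <- max(0L, (stop_end - start) %/% 3L - as.integer(complete3))
    if (strand == "+") {
      g_start <- start; g_end <- stop_end
    } else {
      g_start <- L - stop_end; g_end <- L - start
    }
    tibble(id = qseqid, scaffold = scaffold, strand = strand,
           start = as.integer(g_start), end = as.integer(g_end),
           complete5 = complete5, complete3 = complete3,
           sl_supported = FALSE, protein_aa = as.integer(prot_aa),
           hom_start = as.integer(lo), hom_end = as.integer(hi),
           orf_limit = as.integer(barrier))
  })
  out
}

empty_models <- function() {
  tibble(id = character(0), scaffold = character(0), strand = character(0),
         start = integer(0), end = integer(0), complete5 = logical(0),
         complete3 = logical(0), sl_supported = logical(0),
         protein_aa = integer(0), hom_start = integer(0),
         hom_end = integer(0), orf_limit = integer(0))
}

#' Correct gene starts with spliced-leader sites
#'
#' Trans-splicing places the mature mRNA start at the SL addition site, so a
#' start codon upstream of an SL site cannot be the gene start. For every
#' model whose candidate 5' region (up to `sl_search_window` nt upstream of
#' the homology boundary; the mature leader may contain in-frame stops, so
#' the ORF limit does not apply here) contains an SL site on the model's
#' strand, the start is relocated to the first in-frame ATG downstream of
#' the most 3' such site and the model is flagged `sl_supported`. SL sites
#' falling inside the model or just downstream of its stop are anomalous for
#' that model and are ignored with a warning.
#'
#' @param models Output of [extend_to_boundaries()].
#' @param sl_sites Tibble with `scaffold`, `pos` (0-based genomic), `strand`.
#' @param genome Genome tibble.
#' @param code A `genetic_code`.
#' @param cfg A [gene_model_config()].
#' @return The models tibble with corrected starts.
#' @export
apply_sl_start_rule <- function(models, sl_sites, genome, code,
                                cfg = gene_model_config()) {
  if (!nrow(models) || is.null(sl_sites) || !nrow(sl_sites)) return(models)
  sc <- sense_cache(genome)
  warned <- FALSE
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    L <- sc$len[[m$scaffold]]
    sl <- sl_sites %>% filter(.data$scaffold == m$scaffold, .data$strand == m$strand)
    if (!nrow(sl)) next
    sense_pos <- if (m$strand == "+") sl$pos else L - 1L - sl$pos
    if (m$strand == "+") {
      s <- sc$plus[[m$scaffold]]
      cur_start <- m$start; stop_end <- m$end
    } else {
      s <- sc$minus(m$scaffold)
      cur_start <- L - m$end; stop_end <- L - m$start
    }
    anomalous <- sense_pos >= m$hom_start & sense_pos < stop_end + 100L
    if (any(anomalous) && !warned) {
      warn("SL site(s) at or downstream of a model's coding region ignored.")
      warned <- TRUE
    }
    in_region <- sense_pos >= max(0L, m$hom_start - cfg$sl_search_window) &
      sense_pos < m$hom_start
    if (!any(in_region)) next
    sl_at <- max(sense_pos[in_region])
    frame_anchor <- m$hom_start %% 3L
    q <- sl_at + (frame_anchor - sl_at) %% 3L
    new_start <- NA_integer_
    while (q + 3L <= stop_end) {
      if (codon_at(s, q) == "ATG") { new_start <- q; break }
      q <- q + 3L
    }
    if (is.na(new_start)) next
    models$sl_supported[i] <- TRUE
    models$complete5[i] <- TRUE
    if (m$strand == "+") {
      models$start[i] <- as.integer(new_start)
    } else {
      models$end[i] <- as.integer(L - new_start)
    }
    models$protein_aa[i] <- as.integer(
      (models$end[i] - models$start[i]) %/% 3L - as.integer(models$complete3[i])
    )
  }
  models
}

#' Reduce overlapping gene models to the longest
#'
#' Among models whose genomic overlap exceeds the tolerated `max_overlap`
#' nucleotides (strand-agnostic), only the longest survives; ties break to
#' the leftmost start, then lexicographic id. Idempotent.
#'
#' @param models Gene-model tibble.
#' @param cfg A [gene_model_config()].
#' @return The surviving models, with an `exclusions` attribute logging the
#'   dropped ids.
#' @export
reduce_overlaps <- function(models, cfg = gene_model_config()) {
  if (nrow(models) <= 1) {
    return(structure(models, exclusions = tibble(id = character(0), reason = character(0))))
  }
  ord <- order(-(models$end - models$start), models$start, models$id)
  keep <- logical(nrow(models))
  dropped <- character(0)
  for (j in ord) {
    k <- which(keep & models$scaffold == models$scaffold[j])
    ov <- if (length(k)) {
      pmin(models$end[k], models$end[j]) - pmax(models$start[k], models$start[j])
    } else numeric(0)
    if (any(ov > cfg$max_overlap)) {
      dropped <- c(dropped, models$id[j])
    } else {
      keep[j] <- TRUE
    }
  }
  structure(
    models[keep, ],
    exclusions = tibble(id = dropped,
                        reason = rep("overlap_reduced", length(dropped)))
  )
}

#' Rescue expressed, homology-supported regions as query proteins
#'
#' Maximal runs of read coverage at or above the transcript threshold that
#' also carry a qualifying BLASTX-style hit are translated (in the hit's
#' frame, under the active code) and returned as additional query proteins.
#' Regions failing either condition are not rescued.
#'
#' @param coverage Tibble `scaffold`, `start`, `end`, `depth` (per-base or
#'   windowed intervals).
#' @param hits Tibble `scaffold`, `start`, `end`, `strand`, `frame`
#'   (sense-space anchor, 0-2), `evalue`.
#' @param genome Genome tibble.
#' @param code A `genetic_code`.
#' @param cfg A [gene_model_config()].
#' @return Tibble `id`, `scaffold`, `start`, `end`, `strand`, `protein`.
#' @export
rescue_expressed_regions <- function(coverage, hits, genome, code,
                                     cfg = gene_model_config()) {
  empty_rescue <- tibble(id = character(0), scaffold = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), protein = character(0))
  covered <- coverage %>% filter(.data$depth >= cfg$min_transcript_cov)
  good_hits <- hits %>% filter(.data$evalue <= cfg$blastx_evalue_max)
  if (!nrow(covered) || !nrow(good_hits)) return(empty_rescue)
  runs <- covered %>%
    arrange(.data$scaffold, .data$start) %>%
    group_by(.data$scaffold) %>%
    group_modify(function(g, key) {
      grp <- cumsum(c(TRUE, g$start[-1] > g$end[-nrow(g)]))
      g %>% mutate(run = grp) %>% group_by(.data$run) %>%
        summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
    }) %>%
    ungroup()
  sc <- sense_cache(genome)
  out <- list()
  n <- 0
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    h <- good_hits %>%
      filter(.data$scaffold == r$scaffold,
             .data$start < r$end, .data$end > r$start)
    if (!nrow(h)) next
    h <- h[1, ]
    a <- max(r$start, h$start); b <- min(r$end, h$end)
    L <- sc$len[[r$scaffold]]
    if (h$strand == "+") {
      s <- sc$plus[[r$scaffold]]; lo <- a; hi <- b
    } else {
      s <- sc$minus(r$scaffold); lo <- L - b; hi <- L - a
    }
    lo <- lo + (h$frame - lo) %% 3L
    len <- ((hi - lo) %/% 3L) * 3L
    if (len < 3L) next
    prot <- translate_cds(substring(s, lo + 1L, lo + len), code, complete3 = FALSE)
    n <- n + 1
    out[[n]] <- tibble(id = sprintf("rescue_%04d", n), scaffold = r$scaffold,
                       start = as.integer(if (h$strand == "+") lo else L - (lo + len)),
                       end = as.integer(if (h$strand == "+") lo + len else L - lo),
                       strand = h$strand, protein = prot)
  }
  if (!n) return(empty_rescue)
  bind_rows(out)
}

#' Remove short predicted proteins
#'
#' @param models Gene-model tibble.
#' @param cfg A [gene_model_config()].
#' @return Models of at least `min_protein_aa` amino acids, with dropped ids
#'   in the `exclusions` attribute.
#' @export
filter_models <- function(models, cfg = gene_model_config()) {
  short <- models$protein_aa < cfg$min_protein_aa
  structure(
    models[!short, ],
    exclusions = tibble(id = models$id[short],
                        reason = rep(sprintf("protein_shorter_than_%daa", cfg$min_protein_aa),
                                     sum(short)))
  )
}

#' Build gene models from HSPs end to end
#'
#' Runs [merge_hsps()], [extend_to_boundaries()], [apply_sl_start_rule()],
#' [reduce_overlaps()] and [filter_models()] in order.
#'
#' @param genome Genome tibble.
#' @param hsps Normalised HSP tibble.
#' @param code A `genetic_code`.
#' @param sl_sites Optional SL site tibble.
#' @param cfg A [gene_model_config()].
#' @return Gene-model tibble of class `gene_models` with an `exclusions`
#'   attribute accumulating all dropped ids.
#' @export
annotate_genome <- function(genome, hsps, code, sl_sites = NULL,
                            cfg = gene_model_config()) {
  ranges <- merge_hsps(hsps, genome, cfg)
  models <- extend_to_boundaries(ranges, genome, code, cfg)
  if (!is.null(sl_sites)) {
    models <- apply_sl_start_rule(models, sl_sites, genome, code, cfg)
  }
  models <- reduce_overlaps(models, cfg)
  excl <- exclusions(models)
  models <- filter_models(models, cfg)
  excl <- bind_rows(excl, exclusions(models))
  structure(as_tibble(models), class = c("gene_models", class(tibble())),
            exclusions = excl)
}

#' Extract the CDS set of gene models
#'
#' @param models Gene-model tibble.
#' @param genome Genome tibble.
#' @param code A `genetic_code`.
#' @return A [cds_set()] with the models' sense-strand sequences.
#' @export
models_to_cds <- function(models, genome, code) {
  seqs <- stats::setNames(genome$seq, genome$scaffold)
  seq <- substring(seqs[models$scaffold], models$start + 1L, models$end)
  minus <- models$strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  cds_set(
    tibble(id = models$id, scaffold = models$scaffold,
           start = models$start, end = models$end, strand = models$strand,
           seq = unname(seq), complete5 = models$complete5,
           complete3 = models$complete3),
    code
  )
}

#' Scan read 5' ends for spliced-leader suffix matches
#'
#' Convenience helper replacing read-level SL mapping: a read is SL-supported
#' when a suffix of the SL sequence of at least `sl_min_match` nt prefixes
#' the read; the reported site is the read's genomic start position.
#'
#' @param reads Tibble with `scaffold`, `pos` (0-based genomic 5' position),
#'   `strand`, `seq` (read sequence, sense of the transcript).
#' @param cfg A [gene_model_config()].
#' @return SL-site tibble (`scaffold`, `pos`, `strand`) of supported reads.
#' @export
scan_sl_reads <- function(reads, cfg = gene_model_config()) {
  sl <- cfg$sl_seq
  hit <- vapply(reads$seq, function(s) {
    for (k in nchar(sl):cfg$sl_min_match) {
      suf <- substring(sl, nchar(sl) - k + 1, nchar(sl))
      if (startsWith(s, suf)) return(TRUE)
    }
    FALSE
  }, logical(1))
  reads[hit, c("scaffold", "pos", "strand")]
}
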