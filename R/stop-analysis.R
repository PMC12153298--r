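# Genuine-stop identification, terminator usage, and the stop-context
# profiles downstream and upstream of the terminator.

#' Configuration for genuine-stop identification
#'
#' @param evalue_max Maximum HSP e-value (default 1e-20).
#' @param max_targets Maximum targets per query (default 1).
#' @param require_complete_3prime Only use alignments covering the query's
#'   final residue.
#' @return List of class `stop_finder_config`.
#' @export
stop_finder_config <- function(evalue_max = 1e-20, max_targets = 1,
                               require_complete_3prime = TRUE) {
  stopifnot(evalue_max > 0, max_targets > 0)
  structure(list(evalue_max = evalue_max, max_targets = max_targets,
                 require_complete_3prime = require_complete_3prime),
            class = "stop_finder_config")
}

#' Identify the genuine stop codon after complete-3' alignments
#'
#' For each qualifying HSP (e-value at most the threshold and, by default,
#' aligned through the query's final residue) returns the in-frame triplet
#' immediately 3' of the alignment end on the subject strand -- the codon
#' that terminates translation. Alignments ending within 3 nt of the
#' scaffold end are flagged with no call.
#'
#' @param hsps Normalised HSP tibble (see [read_hsps()]).
#' @param genome Genome tibble.
#' @param cfg A [stop_finder_config()].
#' @return Tibble `qseqid`, `scaffold`, `strand`, `triplet`, `no_call`.
#' @export
find_genuine_stop <- function(hsps, genome, cfg = stop_finder_config()) {
  h <- hsps %>% filter(.data$evalue <= cfg$evalue_max)
  if (cfg$require_complete_3prime) h <- h %>% filter(.data$qend == .data$qlen)
  if (!nrow(h)) {
    return(tibble(qseqid = character(0), scaffold = character(0),
                  strand = character(0), triplet = character(0),
                  no_call = logical(0)))
  }
  sc <- sense_cache(genome)
  purrr::pmap_dfr(h, function(qseqid, sseqid, strand, sstart, send, ...) {
    L <- sc$len[[sseqid]]
    if (strand == "+") {
      pos <- send; s <- sc$plus[[sseqid]]
    } else {
      pos <- L - sstart; s <- sc$minus(sseqid)
    }
    if (pos + 3L > L) {
      return(tibble(qseqid = qseqid, scaffold = sseqid, strand = strand,
                    triplet = NA_character_, no_call = TRUE))
    }
    tibble(qseqid = qseqid, scaffold = sseqid, strand = strand,
           triplet = codon_at(s, pos), no_call = FALSE)
  })
}

#' Terminator usage over 3'-complete CDSs
#'
#' Counts UAA/UAG/UGA (DNA: TAA/TAG/TGA) as the final triplet of every
#' 3'-complete record. Under the reassigned code any non-UAA terminator is
#' an anomaly and is reported in the `anomalies` attribute.
#'
#' @param cds A `cds_set` (records lacking `complete3` are excluded).
#' @param code A `genetic_code`; defaults to the set's code.
#' @return Tibble `triplet`, `n`, `fraction` with attribute `anomalies`.
#' @export
stop_usage_table <- function(cds, code = cds_code(cds)) {
  rec <- cds %>% filter(.data$complete3)
  term <- substring(rec$seq, nchar(rec$seq) - 2L, nchar(rec$seq))
  stops <- c("TAA", "TAG", "TGA")
  n <- vapply(stops, function(tr) sum(term == tr), integer(1))
  anomalies <- tibble(id = rec$id, triplet = term) %>%
    filter(!.data$triplet %in% code$terminal_stops)
  structure(
    tibble(triplet = stops, n = unname(n),
           fraction = unname(n) / max(1L, nrow(rec))),
    anomalies = anomalies, n_records = nrow(rec)
  )
}

#' Cut flanking sequence around gene models
#'
#' Returns the sense-strand flank immediately 3' of the terminator (or 5' of
#' the start), clipped at scaffold bounds.
#'
#' @param genes Tibble with `id`, `scaffold`, `strand`, `start`, `end`.
#' @param genome Genome tibble.
#' @param width Flank width in nt.
#' @param side `"3p"` (after the terminator) or `"5p"` (before the start).
#' @return Tibble `id`, `seq`, `width_available`.
#' @export
cut_flanks <- function(genes, genome, width = 75, side = c("3p", "5p")) {
  side <- match.arg(side)
  seqs <- stats::setNames(genome$seq, genome$scaffold)
  lens <- stats::setNames(nchar(genome$seq), genome$scaffold)
  L <- lens[genes$scaffold]
  plus <- genes$strand == "+"
  right <- xor(!plus, side == "3p")  # TRUE: genomic interval right of gene
  a <- ifelse(right, genes$end, pmax(0L, genes$start - width))
  b <- ifelse(right, pmin(L, genes$end + width), genes$start)
  seq <- substring(seqs[genes$scaffold], a + 1L, b)
  flip <- !plus
  if (any(flip)) seq[flip] <- revcomp(seq[flip])
  tibble(id = genes$id, seq = unname(seq),
         width_available = as.integer(b - a))
}

#' Downstream stop-codon profile in three frames
#'
#' For each coding frame (1 = the protein-coding frame, 2 and 3 its +1 and
#' +2 nt shifts) and each triplet position 1..`n_triplets` after the
#' terminator, counts the genes whose triplet at that slot belongs to the
#' code's "true stop" set (UAA only under the reassigned code; all three
#' canonical stops otherwise). Genes with short flanks contribute only to
#' the positions they cover; per-cell denominators are reported.
#'
#' @param flanks Tibble `id`, `seq` of 3' flanks (from [cut_flanks()]).
#' @param code A `genetic_code`.
#' @param n_triplets Number of triplet positions (default 25).
#' @return Tibble `frame`, `position`, `count`, `denominator` of class
#'   `stop_context_profile`.
#' @export
downstream_stop_profile <- function(flanks, code, n_triplets = 25) {
  stop_set <- code$terminal_stops
  w <- nchar(flanks$seq)
  grid <- tidyr::expand_grid(frame = 1:3, position = seq_len(n_triplets))
  res <- purrr::pmap_dfr(grid, function(frame, position) {
    off <- (position - 1L) * 3L + (frame - 1L)
    ok <- w >= off + 3L
    tri <- substring(flanks$seq[ok], off + 1L, off + 3L)
    tibble(frame = frame, position = position,
           count = sum(tri %in% stop_set), denominator = sum(ok))
  })
  structure(res, class = c("stop_context_profile", class(tibble())),
            stop_set = stop_set, code = code$name, n_genes = nrow(flanks))
}

#' Upstream stop-triplet profile inside the CDS
#'
#' Counts each of UAA/UAG/UGA among in-frame codons at positions
#' -`n_codons`..-1 before the terminator (position -1 is the last amino-acid
#' codon). Shorter CDSs contribute only to the positions they cover.
#'
#' @param cds A `cds_set` of 3'-complete records.
#' @param code A `genetic_code`; defaults to the set's code.
#' @param n_codons Number of upstream positions (default 25).
#' @return Tibble `position`, `triplet`, `count`, `denominator`.
#' @export
upstream_stop_profile <- function(cds, code = cds_code(cds), n_codons = 25) {
  rec <- cds %>% filter(.data$complete3)
  n_int <- nchar(rec$seq) %/% 3L - 1L   # internal codons
  stops <- c("TAA", "TAG", "TGA")
  purrr::map_dfr(seq_len(n_codons), function(k) {
    ok <- n_int >= k
    idx <- n_int[ok] - k + 1L
    cod <- substring(rec$seq[ok], 3L * idx - 2L, 3L * idx)
    purrr::map_dfr(stops, function(tr) {
      tibble(position = -k, triplet = tr, count = sum(cod == tr),
             denominator = sum(ok))
    })
  }) %>% arrange(.data$position, .data$triplet)
}

#' The filtered 3'UTR set: genes with an early additional stop
#'
#' Flags genes with at least one additional in-frame putative stop codon
#' within `window` codons downstream of the genuine stop, and reports the GC
#' content over the first `gc_span` downstream nucleotides.
#'
#' @param flanks Tibble `id`, `seq` of 3' flanks (>= `gc_span` nt wide for
#'   unflagged GC values).
#' @param code A `genetic_code` (its terminal-stop set defines the putative
#'   stops).
#' @param window Codon window for membership (default 30).
#' @param gc_span Downstream span (nt) for the GC average (default 120).
#' @return Tibble `id`, `member`, `gc_downstream`, `gc_nt_used`,
#'   `short_flank` of class `filtered_utr_set`; the member fraction is in
#'   the `fraction` attribute and via [glance.filtered_utr_set()].
#' @export
filtered_3utr_set <- function(flanks, code, window = 30, gc_span = 120) {
  stop_set <- code$terminal_stops
  member <- vapply(flanks$seq, function(s) {
    n3 <- min(window, nchar(s) %/% 3L)
    if (n3 < 1) return(FALSE)
    any(substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3)) %in% stop_set)
  }, logical(1), USE.NAMES = FALSE)
  span <- pmin(gc_span, nchar(flanks$seq))
  gc <- vapply(seq_len(nrow(flanks)), function(i) {
    if (span[i] == 0) return(NA_real_)
    s <- substring(flanks$seq[i], 1, span[i])
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
    sum(f) / span[i]
  }, numeric(1))
  structure(
    tibble(id = flanks$id, member = member, gc_downstream = gc,
           gc_nt_used = as.integer(span), short_flank = span < gc_span),
    class = c("filtered_utr_set", class(tibble())),
    fraction = mean(member)
  )
}

#' Positional A/U zig-zag profile of UTRs
#'
#' Per-position nucleotide frequencies relative to the terminator, with an
#' alternation score quantifying the zig-zag: the mean over interior
#' positions p of |f(p) - (f(p-1) + f(p+1))/2|, averaged over A and T (U).
#'
#' @param flank3 Tibble `id`, `seq` of 3' flanks.
#' @param flank5 Optional tibble of 5' flanks for comparison.
#' @param max_pos Number of positions profiled (default 60).
#' @return Tibble `side`, `position`, `nt`, `freq`, `denominator` of class
#'   `zigzag_profile`; alternation scores per side in the `scores`
#'   attribute.
#' @export
zigzag_au_profile <- function(flank3, flank5 = NULL, max_pos = 60) {
  one_side <- function(fl, side) {
    P <- min(max_pos, max(nchar(fl$seq)))
    purrr::map_dfr(seq_len(P), function(p) {
      ok <- nchar(fl$seq) >= p
      b <- substring(fl$seq[ok], p, p)
      purrr::map_dfr(c("A", "C", "G", "T"), function(nt) {
        tibble(side = side, position = p, nt = nt,
               freq = mean(b == nt), denominator = sum(ok))
      })
    })
  }
  prof <- one_side(flank3, "3p")
  if (!is.null(flank5)) prof <- bind_rows(prof, one_side(flank5, "5p"))
  scores <- prof %>%
    filter(.data$nt %in% c("A", "T")) %>%
    group_by(.data$side, .data$nt) %>%
    arrange(.data$position, .by_group = TRUE) %>%
    summarise(score = {
      f <- .data$freq
      if (length(f) < 3) NA_real_ else {
        p <- 2:(length(f) - 1)
        mean(abs(f[p] - (f[p - 1] + f[p + 1]) / 2))
      }
    }, .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "nt", values_from = "score",
                       names_prefix = "score_") %>%
    mutate(score = (.data$score_A + .data$score_T) / 2)
  structure(prof, class = c("zigzag_profile", class(tibble())),
            scores = scores)
}

#' Alternation scores of a zig-zag profile
#'
#' @param profile A `zigzag_profile`.
#' @return Tibble `side`, `score_A`, `score_T`, `score`.
#' @export
zigzag_scores <- function(profile) attr(profile, "scores")
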