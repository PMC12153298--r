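# Synthetic genomes, HSP tables, coverage tracks, ortholog alignments and
# abundance tables with the statistical structure the analysis stages
# estimate, so the whole pipeline is exercisable without external data.

with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default planted codon-usage vector
#'
#' A 64-codon frequency vector over the sense codons of the active code.
#' Codon weights follow an AT-biased independent-base model at the given ORF
#' GC content; under the reassigned code the three in-frame reassigned codons
#' (ifRCs) are then pinned to the supplied fractions, echoing the observed
#' usage (UAA ~2.2%, UAG ~1.5%, UGA ~0.8% of all codons). Under the
#' canonical code the stop triplets carry zero in-frame mass.
#'
#' @param code A `genetic_code`.
#' @param gc ORF GC content of the base model.
#' @param ifrc Named fractions for TAA, TAG, TGA (reassigned code only).
#' @return Named numeric vector over the 64 codons summing to 1.
#' @export
default_codon_freqs <- function(code, gc = 0.38,
                                ifrc = c(TAA = 0.022, TAG = 0.015, TGA = 0.008)) {
  p <- base_probs(gc)
  w <- vapply(strsplit(all_codons(), ""), function(b) prod(p[b]), numeric(1))
  names(w) <- all_codons()
  stops <- c("TAA", "TAG", "TGA")
  if (code$name == "canonical") {
    w[stops] <- 0
    w / sum(w)
  } else {
    w[stops] <- 0
    w <- w / sum(w) * (1 - sum(ifrc))
    w[names(ifrc)] <- ifrc
    w
  }
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

nt_marginal <- function(codon_freqs) {
  bases <- strsplit(names(codon_freqs), "")
  out <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(codon_freqs)) {
    for (b in bases[[i]]) out[b] <- out[b] + codon_freqs[i] / 3
  }
  out
}

#' Specification for a synthetic genome
#'
#' Defines the study conditions the generator plants: per-codon usage
#' (including ifRC fractions), AT-rich intergenic sequence, a 3'UTR with
#' tandem in-frame UAA enrichment decaying after `utr3_uaa_decay` codons plus
#' alternating A/U (zig-zag) patterning, a fold-boost of G at the -1 position
#' before the terminator, spliced-leader sites for a fraction of genes, and
#' the terminator distribution of the active code.
#'
#' @param n_genes Number of genes.
#' @param mean_cds_len Mean CDS length in codons (including start and stop).
#' @param code A `genetic_code`.
#' @param codon_freqs 64-codon sense-usage vector (sums to 1).
#' @param intergenic_gc GC fraction of intergenic and UTR sequence.
#' @param utr3_uaa_fold Fold-enrichment of in-frame UAA in 3'UTR codons
#'   1..`utr3_uaa_decay`; 1 = no enrichment.
#' @param utr3_uaa_decay Codon distance K after which UAA reverts to
#'   background.
#' @param utr3_zigzag_amp Amplitude of the alternating A/U bias in the 3'UTR
#'   (added to/subtracted from the A and T probabilities on alternating
#'   positions).
#' @param minus1_g_boost Fold-enrichment of G at the -1 position before the
#'   terminator, measured against the overall CDS nucleotide background.
#' @param sl_fraction Fraction of genes given a spliced-leader site.
#' @param stop_probs Terminator distribution; defaults to `c(TAA = 1)` for
#'   the reassigned code and `c(TAA = .2, TAG = .5, TGA = .3)` for the
#'   canonical code (UAG most frequent, as in *Obscuromonas*).
#' @param utr3_len Length (nt) of the structured 3'UTR region.
#' @param intergenic_len Range (nt) of intergenic gaps between loci.
#' @param sl_offset Range (nt) of the SL site's distance upstream of the ATG.
#' @param genes_per_scaffold Genes placed per scaffold.
#' @param minus_fraction Fraction of genes on the minus strand.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_genes = 2000,
                            mean_cds_len = 400,
                            code = build_genetic_code("blastocrithidia"),
                            codon_freqs = default_codon_freqs(code),
                            intergenic_gc = 0.25,
                            utr3_uaa_fold = 3,
                            utr3_uaa_decay = 14,
                            utr3_zigzag_amp = 0.1,
                            minus1_g_boost = 2,
                            sl_fraction = 0.8,
                            stop_probs = NULL,
                            utr3_len = 90,
                            intergenic_len = c(250, 450),
                            sl_offset = c(15, 60),
                            genes_per_scaffold = 100,
                            minus_fraction = 0.5,
                            seed = 1) {
  if (is.null(stop_probs)) {
    stop_probs <- if (code$name == "blastocrithidia") c(TAA = 1) else c(TAA = 0.2, TAG = 0.5, TGA = 0.3)
  }
  stopifnot(inherits(code, "genetic_code"))
  if (abs(sum(codon_freqs) - 1) > 1e-8) abort("codon_freqs must sum to 1.")
  if (any(codon_freqs < 0)) abort("codon_freqs must be non-negative.")
  if (!all(names(stop_probs) %in% code$terminal_stops)) {
    abort("stop_probs includes a triplet outside the code's terminal stop set.")
  }
  frac_ok <- function(x) is.numeric(x) && x >= 0 && x <= 1
  stopifnot(frac_ok(intergenic_gc), frac_ok(sl_fraction), frac_ok(minus_fraction),
            utr3_uaa_decay >= 0, utr3_uaa_fold > 0, utr3_zigzag_amp >= 0,
            minus1_g_boost > 0, n_genes >= 1, mean_cds_len >= 35)
  p_bg_taa <- prod(base_probs(intergenic_gc)[c("T", "A", "A")])
  if (utr3_uaa_fold > 1 && p_bg_taa == 0) {
    abort("infeasible spec: UAA enrichment requested over a zero background.")
  }
  if (utr3_uaa_fold * p_bg_taa > 1) {
    abort("infeasible spec: enriched UAA probability exceeds 1.")
  }
  structure(
    list(n_genes = n_genes, mean_cds_len = mean_cds_len, code = code,
         codon_freqs = codon_freqs, intergenic_gc = intergenic_gc,
         utr3_uaa_fold = utr3_uaa_fold, utr3_uaa_decay = utr3_uaa_decay,
         utr3_zigzag_amp = utr3_zigzag_amp, minus1_g_boost = minus1_g_boost,
         sl_fraction = sl_fraction, stop_probs = stop_probs,
         utr3_len = utr3_len, intergenic_len = intergenic_len,
         sl_offset = sl_offset, genes_per_scaffold = genes_per_scaffold,
         minus_fraction = minus_fraction, seed = seed),
    class = "genome_sim_spec"
  )
}

# Draw n nucleotides, optionally with an alternating A/T (zig-zag) bias whose
# parity is anchored to absolute positions pos0 + 1..n.
random_nt <- function(n, gc, zigzag_amp = 0, pos0 = 0) {
  if (n <= 0) return(character(0))
  p <- base_probs(gc)
  if (zigzag_amp == 0) {
    return(paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""))
  }
  pos <- pos0 + seq_len(n)
  odd <- pos %% 2 == 1
  amp <- pmin(zigzag_amp, min(p["A"], p["T"]))
  draw_one <- function(is_odd) {
    q <- p
    s <- if (is_odd) amp else -amp
    q["A"] <- q["A"] + s
    q["T"] <- q["T"] - s
    sample(names(q), 1, prob = q)
  }
  paste(vapply(odd, draw_one, character(1)), collapse = "")
}

make_utr3 <- function(spec) {
  n3 <- floor(spec$utr3_len / 3)
  p <- base_probs(spec$intergenic_gc)
  p_taa <- prod(p[c("T", "A", "A")])
  q <- if (spec$utr3_uaa_fold > 1) (spec$utr3_uaa_fold - 1) * p_taa / (1 - p_taa) else 0
  triplets <- character(n3)
  for (k in seq_len(n3)) {
    if (k <= spec$utr3_uaa_decay && q > 0 && stats::runif(1) < q) {
      triplets[k] <- "TAA"
    } else {
      triplets[k] <- random_nt(3, spec$intergenic_gc, spec$utr3_zigzag_amp,
                               pos0 = (k - 1) * 3)
    }
  }
  paste(triplets, collapse = "")
}

#' Simulate a genome with planted gene models
#'
#' Genes are drawn i.i.d. from the spec's codon usage, started with ATG,
#' terminated by a triplet from the code's terminal-stop set, and placed on
#' scaffolds separated by AT-rich intergenic sequence. Each gene's 3'UTR
#' carries the planted in-frame UAA enrichment, zig-zag A/U patterning, and
#' the -1 G boost before the terminator; a fraction of genes receives a
#' spliced-leader site upstream of the start. Deterministic under the spec's
#' seed.
#'
#' @param spec A [genome_sim_spec()].
#' @return Object of class `sim_genome`: list with `genome` (tibble
#'   `scaffold`, `seq`), `genes` (truth table with coordinates, CDS and 3'UTR
#'   sequences, SL positions), `sl_sites`, and the `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed_(spec$seed, {
    freqs <- spec$codon_freqs[spec$codon_freqs > 0]
    # -1 boost: pin the third base of the final body codon so that
    # P(G at -1) = minus1_g_boost * overall CDS G frequency.
    p0 <- nt_marginal(spec$codon_freqs)
    third <- substring(names(freqs), 3, 3)
    p3 <- vapply(c(A = "A", C = "C", G = "G", T = "T"),
                 function(b) sum(freqs[third == b]), numeric(1))
    pG_target <- min(0.95, spec$minus1_g_boost * p0[["G"]])
    adj3 <- p3 * (1 - pG_target) / (1 - p3[["G"]])
    adj3[["G"]] <- pG_target
    final_freqs <- freqs * unname(adj3[third] / p3[third])
    names(final_freqs) <- names(freqs)
    final_freqs <- final_freqs / sum(final_freqs)

    n <- spec$n_genes
    n_body <- pmax(30L, stats::rpois(n, spec$mean_cds_len - 2))
    has_sl <- stats::runif(n) < spec$sl_fraction
    minus <- stats::runif(n) < spec$minus_fraction
    stops <- sample(names(spec$stop_probs), n, replace = TRUE,
                    prob = spec$stop_probs)
    total_body <- sum(n_body - 1L)
    pool <- sample(names(freqs), total_body, replace = TRUE, prob = freqs)
    pool_at <- c(0L, cumsum(n_body - 1L))
    finals <- sample(names(final_freqs), n, replace = TRUE, prob = final_freqs)

    scaffold_of <- ceiling(seq_len(n) / spec$genes_per_scaffold)
    scaff_names <- sprintf("scf%03d", seq_len(max(scaffold_of)))
    genes <- vector("list", n)
    sl_rows <- vector("list", n)
    scaff_seqs <- character(max(scaffold_of))

    for (s in seq_len(max(scaffold_of))) {
      idx <- which(scaffold_of == s)
      pieces <- character(0)
      cursor <- 0L
      for (i in idx) {
        gap <- sample(spec$intergenic_len[1]:spec$intergenic_len[2], 1)
        body <- c(pool[(pool_at[i] + 1L):(pool_at[i] + n_body[i] - 1L)], finals[i])
        cds <- paste0("ATG", paste(body, collapse = ""), stops[i])
        utr3 <- make_utr3(spec)
        sl_d <- if (has_sl[i]) sample(spec$sl_offset[1]:spec$sl_offset[2], 1) else NA_integer_
        gap_seq <- random_nt(gap, spec$intergenic_gc)
        if (!is.na(sl_d)) {
          # the mature 5' leader (SL site to ATG) carries no in-frame ATG: a
          # scanning ribosome would otherwise initiate there
          p <- gap - 3L
          while (p >= gap - sl_d && p >= 0L) {
            while (substring(gap_seq, p + 1L, p + 3L) == "ATG") {
              substring(gap_seq, p + 1L, p + 3L) <- random_nt(3, spec$intergenic_gc)
            }
            p <- p - 3L
          }
        }
        locus <- paste0(gap_seq, cds, utr3)
        llen <- nchar(locus)
        cds_lo <- gap           # local 0-based
        cds_hi <- gap + nchar(cds)
        sl_local <- if (!is.na(sl_d)) gap - sl_d else NA_integer_
        if (minus[i]) {
          locus_out <- revcomp(locus)
          g_start <- cursor + llen - cds_hi
          g_end <- cursor + llen - cds_lo
          sl_pos <- if (!is.na(sl_local)) cursor + llen - 1L - sl_local else NA_integer_
          strand <- "-"
        } else {
          locus_out <- locus
          g_start <- cursor + cds_lo
          g_end <- cursor + cds_hi
          sl_pos <- if (!is.na(sl_local)) cursor + sl_local else NA_integer_
          strand <- "+"
        }
        genes[[i]] <- tibble(
          id = sprintf("g%05d", i), scaffold = scaff_names[s],
          strand = strand, start = as.integer(g_start), end = as.integer(g_end),
          cds = cds, utr3 = utr3, stop_codon = stops[i],
          sl_pos = as.integer(sl_pos)
        )
        if (!is.na(sl_pos)) {
          sl_rows[[i]] <- tibble(scaffold = scaff_names[s],
                                 pos = as.integer(sl_pos), strand = strand)
        }
        pieces <- c(pieces, locus_out)
        cursor <- cursor + llen
      }
      tail_gap <- random_nt(sample(spec$intergenic_len[1]:spec$intergenic_len[2], 1),
                            spec$intergenic_gc)
      scaff_seqs[s] <- paste0(paste(pieces, collapse = ""), tail_gap)
    }
    structure(
      list(
        genome = tibble(scaffold = scaff_names, seq = scaff_seqs),
        genes = bind_rows(genes),
        sl_sites = bind_rows(sl_rows[!vapply(sl_rows, is.null, logical(1))]),
        spec = spec
      ),
      class = "sim_genome"
    )
  })
}

#' Truth annotation of a simulated genome as a GFF3-style tibble
#'
#' @param sim A `sim_genome`.
#' @return Tibble accepted by [write_gff3()] and [extract_cds()].
#' @export
sim_truth_annotation <- function(sim) {
  sim$genes %>%
    transmute(
      scaffold = .data$scaffold, source = "sim", type = "CDS",
      start = .data$start, end = .data$end, strand = .data$strand,
      id = .data$id, parent = NA_character_, pseudo = FALSE
    )
}

#' CDS set of the planted truth genes
#'
#' @param sim A `sim_genome`.
#' @return A [cds_set()] of the planted genes (sense-strand sequences).
#' @export
sim_truth_cds <- function(sim) {
  cds_set(
    sim$genes %>%
      transmute(.data$id, .data$scaffold, .data$start, .data$end,
                .data$strand, seq = .data$cds,
                complete5 = TRUE, complete3 = TRUE),
    sim$spec$code
  )
}

#' Write a simulated genome to disk
#'
#' Emits genome FASTA, truth GFF3, SL BED and a YAML run manifest recording
#' the seed and resolved parameters.
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "truth.gff3"),
    sl = file.path(dir, "sl_sites.bed"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_genome_fasta(sim$genome, paths$genome)
  write_gff3(sim_truth_annotation(sim), paths$gff)
  write_sl_bed(sim$sl_sites, paths$sl)
  sp <- sim$spec
  manifest <- list(
    seed = sp$seed, n_genes = sp$n_genes, code = sp$code$name,
    mean_cds_len = sp$mean_cds_len, intergenic_gc = sp$intergenic_gc,
    utr3_uaa_fold = sp$utr3_uaa_fold, utr3_uaa_decay = sp$utr3_uaa_decay,
    utr3_zigzag_amp = sp$utr3_zigzag_amp, minus1_g_boost = sp$minus1_g_boost,
    sl_fraction = sp$sl_fraction,
    files = lapply(paths[1:3], basename)
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Simulate a TBLASTN-like HSP table from planted genes
#'
#' Each gene yields one or two HSPs on its true strand and frame. Boundaries
#' are eroded inward by a capped geometric number of codons (local alignments
#' lose at most a residue or two at their edges); a fraction of genes is
#' split into two HSPs separated by a short unaligned gap. Decoy rows with
#' above-threshold e-values are spiked in so that e-value filtering is
#' exercised downstream. E-values of genuine rows are placeholders far below
#' all thresholds.
#'
#' @param sim A `sim_genome`.
#' @param frag_rate Fraction of genes split into two HSPs.
#' @param trim_max Maximum boundary erosion (codons) at each end.
#' @param trim_p Success probability of the geometric erosion (mean erosion
#'   `(1-p)/p` codons before capping).
#' @param decoy_rate Decoy rows per gene (expected).
#' @param seed Integer seed.
#' @return Normalised HSP tibble (see [read_hsps()]) with truth ids as
#'   `qseqid`.
#' @export
simulate_hsp_table <- function(sim, frag_rate = 0, trim_max = 0,
                               trim_p = 0.6, decoy_rate = 0.05, seed = 1) {
  genes <- sim$genes
  with_seed_(seed, {
    n <- nrow(genes)
    qlen <- (genes$end - genes$start) / 3 - 1L   # protein length, aa
    rgeom_cap <- function(n) pmin(stats::rgeom(n, trim_p), trim_max)
    t5 <- if (trim_max > 0) rgeom_cap(n) else rep(0L, n)
    t3 <- if (trim_max > 0) rgeom_cap(n) else rep(0L, n)
    frag <- stats::runif(n) < frag_rate & (qlen - t5 - t3) >= 60

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      q1 <- 1L + t5[i]
      q2 <- qlen[i] - t3[i]
      segs <- if (frag[i]) {
        cut_at <- sample(seq(q1 + 20L, q2 - 20L), 1)
        gap <- sample(3:10, 1)
        list(c(q1, cut_at), c(min(cut_at + gap, q2), q2))
      } else {
        list(c(q1, q2))
      }
      rows[[i]] <- purrr::map_dfr(segs, function(sg) {
        hsp_from_query_range(genes[i, ], qlen[i], sg[1], sg[2])
      })
    }
    hsps <- bind_rows(rows)
    n_decoy <- stats::rpois(1, decoy_rate * n)
    if (n_decoy > 0) {
      scf <- sample(sim$genome$scaffold, n_decoy, replace = TRUE)
      slen <- stats::setNames(nchar(sim$genome$seq), sim$genome$scaffold)
      st <- vapply(slen[scf], function(L) sample.int(max(L - 400L, 1L), 1), integer(1))
      decoys <- tibble(
        qseqid = sprintf("decoy%04d", seq_len(n_decoy)),
        sseqid = scf, pident = 35, length = 100L, mismatch = 60L, gapopen = 2L,
        qstart = 1L, qend = 100L,
        sstart = as.integer(st), send = as.integer(st + 300L),
        evalue = 1e-3, bitscore = 40, sframe = 1L, qlen = 100L,
        strand = "+"
      )
      hsps <- bind_rows(hsps, decoys)
    }
    hsps
  })
}

hsp_from_query_range <- function(gene, qlen, q1, q2) {
  naa <- q2 - q1 + 1L
  if (gene$strand == "+") {
    s_lo <- gene$start + 3L * (q1 - 1L)
    s_hi <- gene$start + 3L * q2
  } else {
    s_lo <- gene$end - 3L * q2
    s_hi <- gene$end - 3L * (q1 - 1L)
  }
  tibble(
    qseqid = gene$id, sseqid = gene$scaffold,
    pident = 98, length = naa, mismatch = round(0.02 * naa), gapopen = 0L,
    qstart = as.integer(q1), qend = as.integer(q2),
    sstart = as.integer(s_lo), send = as.integer(s_hi),
    evalue = 1e-50, bitscore = 2 * naa, sframe = NA_integer_,
    qlen = as.integer(qlen), strand = gene$strand
  )
}

#' Simulate a window read-depth track with planted somies
#'
#' Window means are drawn from Normal(median_cov * somy / 2, cv * mean),
#' truncated at zero, in successive non-overlapping windows.
#'
#' @param somies Tibble with `scaffold`, `length`, `somy`.
#' @param median_cov Depth of the disomic state.
#' @param cv Coefficient of variation of window means.
#' @param window Window size in nt.
#' @param seed Integer seed.
#' @return Tibble with `scaffold`, `start`, `end`, `depth`.
#' @export
simulate_coverage_track <- function(somies, median_cov = 50, cv = 0.1,
                                    window = 1000, seed = 1) {
  with_seed_(seed, {
    purrr::pmap_dfr(somies, function(scaffold, length, somy, ...) {
      starts <- seq(0L, max(0L, length - 1L), by = window)
      ends <- pmin(starts + window, length)
      mu <- median_cov * somy / 2
      depth <- pmax(0, stats::rnorm(length(starts), mu, cv * mu))
      tibble(scaffold = scaffold, start = as.integer(starts),
             end = as.integer(ends), depth = depth)
    })
  })
}

#' Simulate a multi-species protein alignment with CDS back-maps
#'
#' Plants gap-free alignment columns with glutamate or tryptophan conserved
#' across all taxa; at conserved Glu columns each taxon uses a UAR codon with
#' its planted probability `p_uar` (GAR otherwise), and at conserved Trp
#' columns UGA with probability `p_uga` (UGG otherwise). Remaining columns
#' hold other amino acids with synonymous-codon choice biased by each taxon's
#' GC, plus occasional gaps.
#'
#' @param n_taxa Number of rows.
#' @param n_glu_cols,n_trp_cols Numbers of conserved Glu / Trp columns.
#' @param n_other_cols Background columns.
#' @param p_uar,p_uga Per-taxon ifRC probabilities (recycled to `n_taxa`).
#' @param taxon_gc Per-taxon GC bias for synonymous choice (recycled).
#' @param gap_rate Per-taxon gap probability in background columns.
#' @param seed Integer seed.
#' @return Object of class `sim_alignment`: list with `alignment` (tibble
#'   `taxon`, `aligned_seq`), `cds_map` (tibble `taxon`, `cds`), and `truth`.
#' @export
simulate_ortholog_alignment <- function(n_taxa = 9, n_glu_cols = 1066,
                                        n_trp_cols = 202, n_other_cols = 1500,
                                        p_uar = 0.3, p_uga = 0.45,
                                        taxon_gc = 0.4, gap_rate = 0.03,
                                        seed = 1) {
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  p_uar <- rep_len(p_uar, n_taxa)
  p_uga <- rep_len(p_uga, n_taxa)
  taxon_gc <- rep_len(taxon_gc, n_taxa)
  with_seed_(seed, {
    canon <- codon_families(build_genetic_code("canonical"))
    other_fams <- canon %>% filter(!.data$aa %in% c("E", "W", "M"))
    other_aas <- unique(other_fams$aa)

    n_cols <- n_glu_cols + n_trp_cols + n_other_cols
    classes <- sample(c(rep("E", n_glu_cols), rep("W", n_trp_cols),
                        rep("other", n_other_cols)))
    aln <- matrix("", nrow = n_taxa, ncol = n_cols)
    cod <- matrix(NA_character_, nrow = n_taxa, ncol = n_cols)
    syn_pick <- function(aa, gc) {
      cands <- other_fams$codon[other_fams$aa == aa]
      w <- vapply(strsplit(cands, ""), function(b) prod(base_probs(gc)[b]), numeric(1))
      sample(cands, 1, prob = w)
    }
    for (j in seq_len(n_cols)) {
      if (classes[j] == "E") {
        for (t in seq_len(n_taxa)) {
          aln[t, j] <- "E"
          cod[t, j] <- if (stats::runif(1) < p_uar[t]) {
            sample(c("TAA", "TAG"), 1, prob = c(0.6, 0.4))
          } else sample(c("GAA", "GAG"), 1, prob = c(0.6, 0.4))
        }
      } else if (classes[j] == "W") {
        for (t in seq_len(n_taxa)) {
          aln[t, j] <- "W"
          cod[t, j] <- if (stats::runif(1) < p_uga[t]) "TGA" else "TGG"
        }
      } else {
        for (t in seq_len(n_taxa)) {
          if (stats::runif(1) < gap_rate) {
            aln[t, j] <- "-"
          } else {
            aa <- sample(other_aas, 1)
            aln[t, j] <- aa
            cod[t, j] <- syn_pick(aa, taxon_gc[t])
          }
        }
      }
    }
    structure(
      list(
        alignment = tibble(
          taxon = taxa,
          aligned_seq = apply(aln, 1, paste, collapse = "")
        ),
        cds_map = tibble(
          taxon = taxa,
          cds = vapply(seq_len(n_taxa), function(t) {
            paste(cod[t, !is.na(cod[t, ])], collapse = "")
          }, character(1))
        ),
        truth = tibble(taxon = taxa, p_uar = p_uar, p_uga = p_uga,
                       gc = taxon_gc),
        col_class = classes
      ),
      class = "sim_alignment"
    )
  })
}

#' Simulate a protein-abundance table coupled to ifRC frequency
#'
#' Abundance is `exp(intercept - slope * ifrc_freq + e)` with Gaussian noise
#' `e`, giving the monotone-decreasing expectation in ifRC frequency that the
#' regression stage estimates.
#'
#' @param profile An `ifrc_profile` (from [ifrc_summary()]) or a `cds_set`.
#' @param slope Coupling slope (>= 0; 0 = no coupling).
#' @param intercept Log-scale intercept.
#' @param noise SD of the log-scale noise.
#' @param seed Integer seed.
#' @return Tibble with `id`, `abundance` (arbitrary units).
#' @export
simulate_abundance_table <- function(profile, slope = 5, intercept = 0,
                                     noise = 0.3, seed = 1) {
  if (inherits(profile, "cds_set")) profile <- ifrc_summary(profile)
  with_seed_(seed, {
    eps <- if (noise > 0) stats::rnorm(nrow(profile), 0, noise) else 0
    tibble(
      id = profile$id,
      abundance = exp(intercept - slope * dplyr::coalesce(profile$ifrc_freq, 0) + eps)
    )
  })
}

#' Simulate anchored motif windows with optional positional boosts
#'
#' Flanking positions are drawn i.i.d. from the background; the anchor codon
#' occupies the centre. A boost multiplies one nucleotide's probability at a
#' named position (e.g. G at -1), with the other nucleotides rescaled.
#'
#' @param n_sites Number of windows.
#' @param background Named probabilities over A, C, G, T.
#' @param flank Flank width (nt) on each side of the anchor codon.
#' @param anchor Anchor triplet placed at the centre; `NULL` draws the three
#'   centre positions from the background too (pure-null windows).
#' @param boosts Named list: position label (e.g. `"-1"`, `"+2"`) to a named
#'   fold vector (e.g. `c(G = 2)`).
#' @param seed Integer seed.
#' @return Character vector of windows with attributes `flank` and `anchor`.
#' @export
simulate_motifs <- function(n_sites, background, flank = 6, anchor = "TAA",
                            boosts = NULL, seed = 1) {
  stopifnot(abs(sum(background) - 1) < 1e-8)
  labels <- motif_position_labels(flank)
  with_seed_(seed, {
    probs <- lapply(labels, function(lab) {
      p <- background[c("A", "C", "G", "T")]
      if (!is.null(boosts) && lab %in% names(boosts)) {
        b <- boosts[[lab]]
        for (nt in names(b)) {
          target <- min(0.95, b[[nt]] * p[[nt]])
          others <- setdiff(names(p), nt)
          p[others] <- p[others] * (1 - target) / sum(p[others])
          p[nt] <- target
        }
      }
      p
    })
    cols <- vapply(seq_along(labels), function(k) {
      if (!is.null(anchor) && grepl("^S", labels[k])) {
        rep(substring(anchor, as.integer(sub("S", "", labels[k])),
                      as.integer(sub("S", "", labels[k]))), n_sites)
      } else {
        sample(names(probs[[k]]), n_sites, replace = TRUE, prob = probs[[k]])
      }
    }, character(n_sites))
    if (n_sites == 1) cols <- matrix(cols, nrow = 1)
    structure(apply(cols, 1, paste, collapse = ""),
              flank = flank, anchor = anchor)
  })
}

motif_position_labels <- function(flank) {
  c(as.character(-(flank:1)), paste0("S", 1:3), paste0("+", seq_len(flank)))
}
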