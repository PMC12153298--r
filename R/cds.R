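# CDS containers and codon counting.

#' Construct a CDS set
#'
#' A CDS set is a tibble of CDS records (one row per coding sequence, sense
#' strand) carrying the active genetic code and an exclusion log as
#' attributes.
#'
#' @param records Tibble with columns `id`, `scaffold`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `seq`, `complete5`, `complete3`.
#' @param code A `genetic_code`.
#' @param exclusions Tibble with `id`, `reason` for records removed upstream.
#' @return The records tibble with class `cds_set` and attributes `code`,
#'   `exclusions`.
#' @export
cds_set <- function(records, code, exclusions = tibble(id = character(0), reason = character(0))) {
  stopifnot(inherits(code, "genetic_code"))
  records <- as_tibble(records)
  needed <- c("id", "scaffold", "start", "end", "strand", "seq", "complete5", "complete3")
  missing <- setdiff(needed, names(records))
  if (length(missing)) abort(paste("cds_set records lack columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(records$id)) abort("cds_set record ids must be unique.")
  if (any(exclusions$id %in% records$id)) {
    abort("exclusion ids overlap retained record ids.")
  }
  bad <- records$complete5 & records$complete3 & nchar(records$seq) %% 3 != 0
  if (any(bad)) {
    abort(paste("complete CDS length not divisible by 3 for:",
                paste(utils::head(records$id[bad], 5), collapse = ", ")))
  }
  structure(records, class = c("cds_set", class(tibble())),
            code = code, exclusions = as_tibble(exclusions))
}

#' Exclusion log of a CDS set or gene-model table
#'
#' @param x An object with an `exclusions` attribute.
#' @return Tibble with `id`, `reason`.
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble(id = character(0), reason = character(0))
}

#' Genetic code attached to a CDS set
#'
#' @param x A `cds_set`.
#' @return The `genetic_code` object.
#' @export
cds_code <- function(x) attr(x, "code")

#' Extract CDS sequences from a genome and GFF3 annotation
#'
#' Minus-strand features are reverse-complemented to the sense strand.
#' Pseudogenes and CDSs split into two or more parts (several CDS features
#' sharing one `Parent` or `id`) are excluded and logged rather than kept, as
#' are features with out-of-range coordinates on a known scaffold raising an
#' error.
#'
#' @param genome Tibble with `scaffold`, `seq` (as from [read_genome_fasta()]).
#' @param annotations Tibble as from [read_gff3()]; rows with `type == "CDS"`
#'   are used.
#' @param code A `genetic_code` attached to the resulting set.
#' @param drop_split Exclude CDSs split into >= 2 parts (default TRUE).
#' @return A [cds_set()].
#' @export
extract_cds <- function(genome, annotations, code, drop_split = TRUE) {
  feats <- annotations %>% filter(.data$type %in% c("CDS", "cds"))
  if (!nrow(feats)) {
    return(cds_set(tibble(id = character(0), scaffold = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), seq = character(0),
                          complete5 = logical(0), complete3 = logical(0)),
                   code))
  }
  unknown <- setdiff(unique(feats$scaffold), genome$scaffold)
  if (length(unknown)) {
    abort(paste("annotation references unknown scaffold(s):",
                paste(unknown, collapse = ", ")))
  }
  lens <- stats::setNames(nchar(genome$seq), genome$scaffold)
  oob <- feats$start < 0 | feats$end > lens[feats$scaffold] | feats$start >= feats$end
  if (any(oob)) {
    abort(paste("out-of-bounds CDS feature(s):",
                paste(utils::head(feats$id[oob], 5), collapse = ", ")))
  }
  feats <- feats %>% mutate(gene = dplyr::coalesce(.data$parent, .data$id))

  excl <- tibble(id = character(0), reason = character(0))
  pseudo_ids <- unique(feats$gene[feats$pseudo])
  if (length(pseudo_ids)) {
    excl <- bind_rows(excl, tibble(id = pseudo_ids, reason = "pseudogene"))
    feats <- feats %>% filter(!.data$gene %in% pseudo_ids)
  }
  if (drop_split) {
    split_ids <- feats %>% count(.data$gene) %>% filter(.data$n >= 2) %>% pull(.data$gene)
    if (length(split_ids)) {
      excl <- bind_rows(excl, tibble(id = split_ids, reason = "split_cds"))
      feats <- feats %>% filter(!.data$gene %in% split_ids)
    }
  }
  seqs <- stats::setNames(genome$seq, genome$scaffold)
  seq <- substring(seqs[feats$scaffold], feats$start + 1L, feats$end)
  minus <- feats$strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  records <- tibble(
    id = feats$gene,
    scaffold = feats$scaffold,
    start = as.integer(feats$start),
    end = as.integer(feats$end),
    strand = feats$strand,
    seq = unname(seq),
    complete5 = TRUE,
    complete3 = TRUE
  )
  cds_set(records, code, excl)
}

#' Count in-frame codons per CDS
#'
#' Each 5'-complete CDS is split into consecutive triplets from its first
#' base. The terminal triplet of a 3'-complete CDS is dropped when
#' `drop_terminal` is set, so the counts cover in-frame (internal) codons
#' only. Triplets containing any non-ACGT symbol are excluded from the counts
#' and tallied in the `ambiguous` attribute.
#'
#' @param cds A `cds_set` or tibble with `id`, `seq`, `complete5`, `complete3`.
#' @param drop_terminal Drop the terminator triplet of 3'-complete records.
#' @return Tibble with `id`, `codon`, `count` (observed codons only), carrying
#'   attribute `ambiguous` (tibble `id`, `n_ambiguous`).
#' @export
count_codons <- function(cds, drop_terminal = TRUE) {
  if (!nrow(cds)) abort("count_codons: empty CDS set.")
  if (!all(cds$complete5)) {
    abort("count_codons requires 5'-complete records; filter or exclude others.")
  }
  n_cod <- floor(nchar(cds$seq) / 3)
  drop <- drop_terminal & cds$complete3 & n_cod > 0
  n_keep <- n_cod - as.integer(drop)
  ids <- rep(cds$id, n_keep)
  offs <- unlist(lapply(n_keep, seq_len), use.names = FALSE)
  codons <- substring(rep(cds$seq, n_keep), 3 * offs - 2, 3 * offs)
  clean <- codons %in% all_codons()
  counts <- tibble(id = ids[clean], codon = codons[clean]) %>%
    count(.data$id, .data$codon, name = "count")
  amb <- tibble(id = ids[!clean]) %>% count(.data$id, name = "n_ambiguous")
  structure(counts, ambiguous = amb)
}

#' Aggregate per-CDS codon counts over the whole set
#'
#' @param counts Output of [count_codons()].
#' @return Tibble with `codon`, `count` over all 64 codons (zeros included).
#' @export
aggregate_codon_counts <- function(counts) {
  agg <- counts %>%
    group_by(.data$codon) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  tibble(codon = all_codons()) %>%
    left_join(agg, by = "codon") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Nucleotide background of a CDS set
#'
#' Per-nucleotide probabilities over all counted CDS positions, the
#' background used for enrichment logos ("average nucleotide content of all
#' coding sequences").
#'
#' @param cds A `cds_set` or tibble with a `seq` column.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
cds_nucleotide_background <- function(cds) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(cds$seq),
                                   letters = c("A", "C", "G", "T"))
  tot <- colSums(f)
  tot / sum(tot)
}
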