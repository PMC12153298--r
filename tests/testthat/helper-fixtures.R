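# Small fixture builders and independent oracles shared across tests.

blasto <- build_genetic_code("blastocrithidia")
canon <- build_genetic_code("canonical")

# one-record CDS set from a raw sequence
one_cds <- function(seq, id = "c1", complete3 = TRUE, code = blasto,
                    strand = "+") {
  cds_set(
    tibble::tibble(id = id, scaffold = "s", start = 0L,
                   end = nchar(seq), strand = strand, seq = seq,
                   complete5 = TRUE, complete3 = complete3),
    code
  )
}

# CDS set of several sequences
cds_from_seqs <- function(seqs, code = blasto, complete3 = TRUE) {
  cds_set(
    tibble::tibble(id = sprintf("c%03d", seq_along(seqs)), scaffold = "s",
                   start = 0L, end = nchar(seqs), strand = "+", seq = seqs,
                   complete5 = TRUE, complete3 = complete3),
    code
  )
}

# random CDS built codon-by-codon from a sense-codon pool
random_cds_seq <- function(n_codons, code = blasto, terminator = "TAA") {
  sense <- setdiff(all_codons(), c("TAA", "TAG", "TGA"))
  if (code$name == "blastocrithidia") sense <- c(sense, "TAA", "TAG", "TGA")
  body <- sample(sense, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), terminator)
}

# --- independent oracles ------------------------------------------------

# sliding-triplet codon tally by index arithmetic (no package code)
oracle_count_codons <- function(seq, drop_terminal = TRUE) {
  n <- floor(nchar(seq) / 3)
  idx <- seq_len(if (drop_terminal) n - 1 else n)
  cods <- vapply(idx, function(i) substr(seq, 3 * i - 2, 3 * i), character(1))
  table(cods[grepl("^[ACGT]{3}$", cods)])
}

# standard-code translation through Biostrings' own table
oracle_translate_canonical <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     genetic.code = Biostrings::GENETIC_CODE))
}

# brute-force GC over a string
oracle_gc <- function(s) {
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("G", "C"))
}

# brute-force recomputation of the ifRC statistics from raw sequences
oracle_ifrc <- function(seqs) {
  cods <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) %/% 3
    vapply(seq_len(n - 1), function(i) substr(s, 3 * i - 2, 3 * i), character(1))
  }))
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  cnt <- function(x) sum(cods %in% x)
  denom <- cnt(c("GAA", "TAA", "GAG", "TAG", "TGG", "TGA"))
  list(glu1 = cnt(c("GAA", "TAA")) / length(cods),
       glu2 = cnt(c("GAG", "TAG")) / length(cods),
       trp = cnt(c("TGG", "TGA")) / length(cods),
       ifrc = if (denom > 0) cnt(c("TAA", "TAG", "TGA")) / denom else 0)
}

# small genome with one planted gene and explicit flanks, for boundary tests
planted_locus <- function(utr5, cds, utr3, strand = "+",
                          scaffold = "chr1") {
  locus <- paste0(utr5, cds, utr3)
  if (strand == "-") {
    genome_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
    start <- nchar(utr3); end <- nchar(utr3) + nchar(cds)
  } else {
    genome_seq <- locus
    start <- nchar(utr5); end <- nchar(utr5) + nchar(cds)
  }
  list(
    genome = tibble::tibble(scaffold = scaffold, seq = genome_seq),
    start = as.integer(start), end = as.integer(end), strand = strand
  )
}

# HSP row in normalised coordinates
hsp_row <- function(qseqid, sseqid, sstart, send, strand = "+",
                    qstart = 1L, qend = NULL, qlen = NULL,
                    evalue = 1e-50, bitscore = 500) {
  naa <- (send - sstart) / 3
  if (is.null(qend)) qend <- as.integer(qstart + naa - 1)
  if (is.null(qlen)) qlen <- qend
  tibble::tibble(
    qseqid = qseqid, sseqid = sseqid, pident = 99, length = naa,
    mismatch = 0L, gapopen = 0L, qstart = as.integer(qstart),
    qend = as.integer(qend), sstart = as.integer(sstart),
    send = as.integer(send), evalue = evalue, bitscore = bitscore,
    sframe = NA_integer_, qlen = as.integer(qlen), strand = strand
  )
}
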