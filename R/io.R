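# Readers and writers for the standard formats the pipeline consumes.
# All genomic coordinates are 0-based half-open internally; GFF3/BED I/O
# converts to and from the conventions of each format.

#' Read a genome FASTA into a tibble
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return Tibble with columns `scaffold`, `seq`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    scaffold = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x))
  )
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `scaffold`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$scaffold))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read GFF3 features into a tibble
#'
#' Coordinates are converted from the 1-based closed GFF3 convention to
#' 0-based half-open. Pseudogene status is taken from a `pseudo=true` or a
#' `biotype`/`gene_biotype` attribute containing "pseudogene".
#'
#' @param path GFF3 file.
#' @return Tibble with `scaffold`, `source`, `type`, `start`, `end`, `strand`,
#'   `id`, `parent`, `pseudo`.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(S4Vectors::mcols(g))
  get_col <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else rep(NA_character_, length(g))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else rep(NA_character_, length(g))
  pseudo_attr <- tolower(get_col("pseudo"))
  biotype <- tolower(paste0(get_col("biotype"), get_col("gene_biotype")))
  tibble(
    scaffold = as.character(GenomicRanges::seqnames(g)),
    source = get_col("source"),
    type = as.character(g$type),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    id = get_col("ID"),
    parent = parent,
    pseudo = !is.na(pseudo_attr) & pseudo_attr %in% c("true", "1") |
      grepl("pseudogene", biotype)
  )
}

#' Write gene models or features as GFF3
#'
#' @param features Tibble with `scaffold`, `start`, `end` (0-based half-open),
#'   `strand`, `id`, and optionally `type` (default `"CDS"`) and `pseudo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  type <- if ("type" %in% names(features)) features$type else rep("CDS", nrow(features))
  attrs <- paste0("ID=", features$id)
  if ("pseudo" %in% names(features)) {
    attrs <- ifelse(features$pseudo, paste0(attrs, ";pseudo=true"), attrs)
  }
  lines <- paste(
    features$scaffold, "stopshift", type,
    features$start + 1L, features$end, ".",
    features$strand, "0", attrs,
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a BED-like table of spliced-leader addition sites
#'
#' @param path BED file (chrom, start, end, optional name/score/strand).
#' @return Tibble with `scaffold`, `pos` (0-based site position), `strand`.
#' @export
read_sl_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b) <- c("scaffold", "start", "end", "name", "score",
                "strand")[seq_len(ncol(b))]
  tibble(
    scaffold = as.character(b$scaffold),
    pos = as.integer(b$start),
    strand = if ("strand" %in% names(b)) as.character(b$strand) else "+"
  )
}

#' Write spliced-leader sites as BED
#'
#' @param sl Tibble with `scaffold`, `pos`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sl_bed <- function(sl, path) {
  lines <- paste(sl$scaffold, sl$pos, sl$pos + 1L, "SL", 0L, sl$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

HSP_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore",
              "sframe", "qlen")

#' Read a BLAST outfmt-6-like HSP table
#'
#' Expects the 12 standard tabular columns plus `sframe` and `qlen`. Subject
#' coordinates follow the BLAST convention (1-based, `sstart > send` on the
#' minus strand) and are normalised to 0-based half-open sense coordinates
#' with an explicit `strand` column.
#'
#' @param path TSV path (no header).
#' @return Tibble of HSP rows with normalised `sstart`, `send`, `strand`.
#' @export
read_hsps <- function(path) {
  h <- readr::read_tsv(path, col_names = HSP_COLS, show_col_types = FALSE)
  normalise_hsps(h)
}

#' Normalise BLAST-convention HSP coordinates
#'
#' @param h Tibble with the columns of [read_hsps()].
#' @return Tibble with `sstart` < `send` 0-based half-open and `strand`.
#' @export
normalise_hsps <- function(h) {
  minus <- h$sstart > h$send
  lo <- ifelse(minus, h$send, h$sstart)
  hi <- ifelse(minus, h$sstart, h$send)
  h %>%
    mutate(
      strand = ifelse(minus, "-", "+"),
      sstart = as.integer(lo - 1L),
      send = as.integer(hi)
    )
}

#' Write an HSP table in BLAST outfmt-6-like convention
#'
#' @param h Normalised HSP tibble (as from [simulate_hsp_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hsps <- function(h, path) {
  minus <- h$strand == "-"
  out <- h %>%
    mutate(
      sstart_out = ifelse(minus, .data$send, .data$sstart + 1L),
      send_out = ifelse(minus, .data$sstart + 1L, .data$send)
    ) %>%
    transmute(
      .data$qseqid, .data$sseqid, .data$pident, .data$length,
      .data$mismatch, .data$gapopen, .data$qstart, .data$qend,
      sstart = .data$sstart_out, send = .data$send_out,
      .data$evalue, .data$bitscore, .data$sframe, .data$qlen
    )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph-like window coverage table
#'
#' @param path TSV with columns scaffold, start, end, mean depth.
#' @return Tibble with `scaffold`, `start`, `end`, `depth`.
#' @export
read_coverage_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("scaffold", "start", "end", "depth"),
                  show_col_types = FALSE)
}

#' Write a window coverage table as bedGraph
#'
#' @param cov Tibble with `scaffold`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(cov, path) {
  readr::write_tsv(cov[, c("scaffold", "start", "end", "depth")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a two-column abundance table
#'
#' @param path TSV with a header line `id<TAB>abundance` (arbitrary units).
#' @return Tibble with `id`, `abundance`.
#' @export
read_abundance_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    rlang::set_names(c("id", "abundance"))
}
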