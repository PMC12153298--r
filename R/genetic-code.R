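#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_BASES <- c("T", "C", "A", "G")

#' All 64 DNA codons in TCAG order
#'
#' @return Character vector of the 64 triplets, first base cycling slowest.
#' @export
all_codons <- function() {
  paste0(rep(DNA_BASES, each = 16),
         rep(rep(DNA_BASES, each = 4), times = 4),
         rep(DNA_BASES, times = 16))
}

# Standard nuclear code, one letter per codon in TCAG order ("*" = stop).
STANDARD_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]

#' Build a genetic-code model
#'
#' Two variants are supported. `"canonical"` is the standard nuclear code
#' with three terminators. `"blastocrithidia"` is the reassigned code of
#' *Blastocrithidia*: in-frame UGA is read as tryptophan, in-frame UAG as
#' glutamate, and UAA has a dual meaning -- glutamate in-frame but the sole
#' translation terminator when it is the final triplet of a complete CDS.
#'
#' @param variant `"canonical"` or `"blastocrithidia"`.
#' @return An object of class `genetic_code`: a list with the 64-triplet
#'   `table` (amino acid or `"*"`), the `terminal_stops` set, and the
#'   `internal_reassignments` map applied to in-frame occurrences.
#' @examples
#' code <- build_genetic_code("blastocrithidia")
#' code$terminal_stops
#' @export
build_genetic_code <- function(variant = c("canonical", "blastocrithidia")) {
  if (!is.character(variant) || !variant[1] %in% c("canonical", "blastocrithidia")) {
    abort(paste0(
      "Unknown genetic-code variant ", deparse(variant[1]),
      "; valid variants are \"canonical\" and \"blastocrithidia\"."
    ))
  }
  variant <- variant[1]
  tab <- stats::setNames(STANDARD_AA, all_codons())
  if (variant == "canonical") {
    code <- list(
      name = "canonical",
      table = tab,
      terminal_stops = c("TAA", "TAG", "TGA"),
      internal_reassignments = character(0)
    )
  } else {
    code <- list(
      name = "blastocrithidia",
      table = tab,
      terminal_stops = "TAA",
      internal_reassignments = c(TAA = "E", TAG = "E", TGA = "W")
    )
  }
  structure(code, class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", x$name, "\n", sep = "")
  cat("  terminal stop(s): ", paste(x$terminal_stops, collapse = ", "), "\n", sep = "")
  if (length(x$internal_reassignments)) {
    cat("  in-frame reassignments: ",
        paste(names(x$internal_reassignments), "->",
              x$internal_reassignments, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Effective in-frame translation table for a code
#'
#' The 64-triplet table with internal reassignments applied, i.e. the meaning
#' of each triplet when it occurs inside a CDS (not as the terminator).
#'
#' @param code A `genetic_code`.
#' @return Named character vector over the 64 codons.
#' @export
internal_table <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  tab <- code$table
  if (length(code$internal_reassignments)) {
    tab[names(code$internal_reassignments)] <- code$internal_reassignments
  }
  tab
}

#' Amino-acid family of every sense codon under a code
#'
#' Triplets whose only in-frame meaning is termination (canonical stops) are
#' excluded; under the reassigned code all 64 triplets are sense in-frame, so
#' UAA/UAG fall in the Glu family and UGA in the Trp family.
#'
#' @param code A `genetic_code`.
#' @return Tibble with columns `codon`, `aa`.
#' @export
codon_families <- function(code) {
  tab <- internal_table(code)
  tibble(codon = names(tab), aa = unname(tab)) %>%
    filter(.data$aa != "*")
}

#' Split a nucleotide string into consecutive triplets
#'
#' Trailing bases that do not fill a triplet are dropped.
#'
#' @param seq Single nucleotide string.
#' @return Character vector of triplets (possibly empty).
#' @export
codon_split <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- floor(nchar(seq) / 3)
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Translate a CDS under a genetic code
#'
#' In-frame triplets are translated through the code's table with internal
#' reassignments applied; the final triplet of a 3'-complete CDS is treated
#' as the terminator if it belongs to the code's terminal-stop set and is not
#' rendered as an amino acid. Codons containing non-ACGT symbols translate to
#' `"X"`; an in-frame canonical stop inside a CDS translates to `"*"` under
#' the canonical code.
#'
#' @param seq CDS nucleotide string (sense strand), 5'-complete.
#' @param code A `genetic_code`.
#' @param complete3 Is the CDS 3'-complete (ends in its terminator)?
#' @return Amino-acid string.
#' @examples
#' code <- build_genetic_code("blastocrithidia")
#' translate_cds("ATGTGATAA", code)  # "MW"
#' @export
translate_cds <- function(seq, code, complete3 = TRUE) {
  stopifnot(inherits(code, "genetic_code"))
  if (nchar(seq) < 3) abort("CDS shorter than one codon cannot be translated.")
  if (complete3 && nchar(seq) %% 3 != 0) {
    abort("3'-complete CDS length is not divisible by 3.")
  }
  codons <- codon_split(seq)
  if (complete3 && codons[length(codons)] %in% code$terminal_stops) {
    codons <- codons[-length(codons)]
  }
  if (!length(codons)) return("")
  tab <- internal_table(code)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
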