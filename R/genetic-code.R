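#' Genetic code tables
#'
#' Returns a genetic code object mapping the 64 codons to amino-acid letters,
#' with start and stop codon sets. The `"ciliate"` code (NCBI translation
#' table 6, used by *Tetrahymena* and other ciliate nuclear genomes)
#' reassigns TAA and TAG to glutamine (Q), leaving TGA as the sole stop.
#' The `"standard"` code is NCBI table 1.
#'
#' @param name `"ciliate"` (default) or `"standard"`.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codon_to_aa` (named character vector of length 64, stop marker `"*"`),
#'   `start_codons`, `alt_start_codons` (the alternative initiators
#'   GTG/CTG/TTG considered during novel-gene calling), and `stop_codons`.
#' @examples
#' code <- genetic_code("ciliate")
#' code$codon_to_aa[["TAA"]]  # "Q"
#' code$stop_codons           # "TGA"
#' @export
genetic_code <- function(name = c("ciliate", "standard")) {
  name <- match.arg(name)
  tab <- Biostrings::GENETIC_CODE  # standard table, named by codon
  if (name == "ciliate") {
    tab[["TAA"]] <- "Q"
    tab[["TAG"]] <- "Q"
  }
  stops <- names(tab)[tab == "*"]
  structure(
    list(
      table_id = if (name == "ciliate") "6" else "1",
      codon_to_aa = tab,
      start_codons = "ATG",
      alt_start_codons = c("GTG", "CTG", "TTG"),
      stop_codons = stops
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> table", x$table_id,
      "| stops:", paste(x$stop_codons, collapse = ","),
      "| starts:", paste(x$start_codons, collapse = ","), "\n")
  invisible(x)
}

.check_dna <- function(dna) {
  if (length(dna) != 1L || is.na(dna) || !nzchar(dna)) {
    stop("`dna` must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", dna)) {
    stop("`dna` contains characters other than A/C/G/T/N", call. = FALSE)
  }
  dna
}

#' Reverse-complement a DNA string
#'
#' @param dna DNA string over A/C/G/T/N (uppercase).
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(dna) {
  .check_dna(dna)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Translate a DNA string in one reading frame
#'
#' Translates complete codons starting at the chosen frame offset. Stop
#' codons are rendered as `"*"`; codons containing `N` are rendered as
#' `"X"`; a trailing partial codon is dropped.
#'
#' @param dna DNA string over A/C/G/T/N (uppercase).
#' @param code A [genetic_code()] object.
#' @param frame Reading frame 1, 2 or 3 (offset 0/1/2 nucleotides).
#' @return Amino-acid string, one letter per complete codon.
#' @examples
#' translate_dna("ATGAAATAA", genetic_code("ciliate"))  # "MKQ"
#' translate_dna("ATGAAATGA", genetic_code("ciliate"))  # "MK*"
#' @export
translate_dna <- function(dna, code = genetic_code(), frame = 1) {
  .check_dna(dna)
  stopifnot(frame %in% 1:3)
  n <- nchar(dna)
  if (n < frame + 2) {
    stop("`dna` too short for a complete codon in frame ", frame, call. = FALSE)
  }
  starts <- seq.int(frame, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}
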