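#' @useDynLib protegap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Split a translated frame into maximal stop-free stretches and return
# their aa-coordinates (0-based within the translated string).
.stop_free_stretches <- function(aa, min_len) {
  m <- gregexpr("[^*]+", aa)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  keep <- len >= min_len
  if (!any(keep)) return(NULL)
  data.frame(aa_start = as.integer(m[keep]) - 1L, aa_len = len[keep])
}

.entry_df <- function(entry_id = character(), sequence = character(),
                      origin = character(), contig = character(),
                      strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      source_id = character()) {
  data.frame(entry_id = entry_id, sequence = sequence, origin = origin,
             contig = contig, strand = strand, frame = frame,
             start = start, end = end, source_id = source_id,
             stringsAsFactors = FALSE)
}

#' Six-frame translation entries of a genome
#'
#' Translates every contig in all six frames (three forward, three on the
#' reverse complement) and emits each maximal stop-free stretch of at least
#' `min_len` residues as a database entry, recording contig, strand, frame
#' and the genomic interval (0-based half-open, forward-strand coordinates)
#' that encodes it. Stretches are inter-stop stretches, not start-to-stop
#' ORFs: peptide evidence may lie upstream of any start codon, and start
#' inference is deferred to novel-gene calling.
#'
#' @param genome Named character vector of contig sequences (uppercase
#'   A/C/G/T/N).
#' @param code A [genetic_code()] object.
#' @param min_len Minimum stretch length in residues (default 20).
#' @return A data frame of entries with columns `entry_id`, `sequence`,
#'   `origin` (`"six_frame"`), `contig`, `strand`, `frame` (+1..+3, -1..-3),
#'   `start`, `end`, `source_id`.
#' @export
six_frame_entries <- function(genome, code = genetic_code(), min_len = 20) {
  stopifnot(min_len >= 1, length(genome) > 0 || is.character(genome))
  if (is.null(names(genome)) && length(genome) > 0) {
    stop("`genome` must be a named character vector of contigs", call. = FALSE)
  }
  out <- vector("list", length(genome) * 6L)
  k <- 0L
  for (ctg in names(genome)) {
    fwd <- genome[[ctg]]
    rev <- reverse_complement(fwd)
    lc <- nchar(fwd)
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") fwd else rev
      for (fr in 1:3) {
        if (nchar(seq) < fr + 2L) next
        aa <- translate_dna(seq, code, frame = fr)
        st <- .stop_free_stretches(aa, min_len)
        if (is.null(st)) next
        # oriented nt interval of the stretch
        os <- (fr - 1L) + 3L * st$aa_start
        oe <- os + 3L * st$aa_len
        if (strand == "+") {
          gs <- os; ge <- oe
        } else {
          gs <- lc - oe; ge <- lc - os
        }
        frame_signed <- if (strand == "+") fr else -fr
        k <- k + 1L
        out[[k]] <- .entry_df(
          entry_id = sprintf("sf|%s|%s%d|%d-%d", ctg, strand, fr, gs, ge),
          sequence = substring(aa, st$aa_start + 1L, st$aa_start + st$aa_len),
          origin = "six_frame", contig = ctg, strand = strand,
          frame = rep.int(frame_signed, nrow(st)),
          start = gs, end = ge, source_id = NA_character_
        )
      }
    }
  }
  if (k == 0L) return(.entry_df())
  do.call(rbind, out[seq_len(k)])
}

#' Three-frame translation entries of sense-oriented transcripts
#'
#' @param transcripts Named character vector of transcript sequences
#'   (sense orientation).
#' @inheritParams six_frame_entries
#' @return Entry data frame with origin `"transcript_frame"`; `start`/`end`
#'   are coordinates on the transcript.
#' @export
transcript_entries <- function(transcripts, code = genetic_code(),
                               min_len = 20) {
  stopifnot(min_len >= 1)
  if (length(transcripts) == 0) return(.entry_df())
  ids <- names(transcripts)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("transcripts must have unique names", call. = FALSE)
  }
  out <- list()
  for (tid in ids) {
    seq <- transcripts[[tid]]
    for (fr in 1:3) {
      if (nchar(seq) < fr + 2L) next
      aa <- translate_dna(seq, code, frame = fr)
      st <- .stop_free_stretches(aa, min_len)
      if (is.null(st)) next
      os <- (fr - 1L) + 3L * st$aa_start
      oe <- os + 3L * st$aa_len
      out[[length(out) + 1L]] <- .entry_df(
        entry_id = sprintf("tx|%s|%d|%d-%d", tid, fr, os, oe),
        sequence = substring(aa, st$aa_start + 1L, st$aa_start + st$aa_len),
        origin = "transcript_frame", contig = NA_character_,
        strand = "+", frame = rep.int(fr, nrow(st)),
        start = os, end = oe, source_id = tid
      )
    }
  }
  if (length(out) == 0) return(.entry_df())
  do.call(rbind, out)
}

#' Wrap plain protein sequences as database entries
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param origin `"reference"` or `"contaminant"`.
#' @return Entry data frame.
#' @export
protein_entries <- function(proteins, origin = c("reference", "contaminant")) {
  origin <- match.arg(origin)
  if (length(proteins) == 0) return(.entry_df())
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("proteins must have unique names", call. = FALSE)
  }
  .entry_df(entry_id = ids, sequence = unname(proteins),
            origin = origin, contig = NA_character_, strand = NA_character_,
            frame = NA_integer_, start = NA_integer_, end = NA_integer_,
            source_id = NA_character_)
}

.reverse_strings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Assemble the combined target-decoy search database
#'
#' Concatenates reference, genomic six-frame, transcript three-frame and
#' contaminant entries. With `with_decoys = TRUE` one reversed-sequence
#' decoy (`DECOY_` prefix, origin `"decoy"`) is appended per target entry.
#'
#' @param reference,genomic,transcript,contaminants Entry data frames as
#'   produced by [protein_entries()], [six_frame_entries()],
#'   [transcript_entries()]; any may be `NULL`.
#' @param with_decoys Append reversed decoys (default `TRUE`).
#' @return An object of class `protegap_db`: list with `entries` (data
#'   frame) and `counts` (entries per origin).
#' @export
build_database <- function(reference = NULL, genomic = NULL,
                           transcript = NULL, contaminants = NULL,
                           with_decoys = TRUE) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                  list(reference, genomic, transcript, contaminants))
  entries <- if (length(parts)) do.call(rbind, parts) else .entry_df()
  if (anyDuplicated(entries$entry_id)) {
    stop("duplicate entry ids in combined database", call. = FALSE)
  }
  if (with_decoys && nrow(entries) > 0) {
    dec <- entries
    dec$source_id <- dec$entry_id
    dec$entry_id <- paste0("DECOY_", dec$entry_id)
    dec$sequence <- .reverse_strings(dec$sequence)
    dec$origin <- "decoy"
    entries <- rbind(entries, dec)
  }
  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         counts = if (nrow(entries)) table(entries$origin) else table(character())),
    class = "protegap_db"
  )
}

#' @export
print.protegap_db <- function(x, ...) {
  cat("<protegap_db>", nrow(x$entries), "entries\n")
  if (nrow(x$entries)) print(x$counts)
  invisible(x)
}

#' Read and write database FASTA
#'
#' Headers follow `entry_id origin|contig|strand|frame|start|end`.
#'
#' @param db A `protegap_db`.
#' @param path Output/input file path.
#' @return `write_database_fasta` returns `path` invisibly;
#'   `read_database_fasta` returns a `protegap_db` (without regenerating
#'   decoys: the file is taken as-is).
#' @export
write_database_fasta <- function(db, path) {
  e <- db$entries
  aa <- Biostrings::AAStringSet(e$sequence)
  names(aa) <- sprintf("%s %s|%s|%s|%s|%s|%s", e$entry_id, e$origin,
                       e$contig, e$strand, e$frame, e$start, e$end)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_database_fasta
#' @export
read_database_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- sub(" .*", "", hdr)
  meta <- sub("^[^ ]+ ", "", hdr)
  f <- strsplit(meta, "|", fixed = TRUE)
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_, character(1))
  num <- function(x) suppressWarnings(as.integer(x))
  entries <- .entry_df(entry_id = id, sequence = as.character(aa),
                       origin = get(1), contig = get(2), strand = get(3),
                       frame = num(get(4)), start = num(get(5)),
                       end = num(get(6)), source_id = NA_character_)
  entries$contig[entries$contig == "NA"] <- NA_character_
  entries$strand[entries$strand == "NA"] <- NA_character_
  structure(list(entries = entries, counts = table(entries$origin)),
            class = "protegap_db")
}
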