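#' Monoisotopic mass constants
#'
#' Standard monoisotopic residue masses for the 20 amino acids, plus water
#' and proton masses. With `fixed_carbamidomethyl = TRUE` (default), the
#' cysteine residue mass includes the +57.02146 Da carbamidomethyl group
#' from iodoacetamide alkylation, applied as a fixed modification.
#'
#' @param fixed_carbamidomethyl Apply fixed Cys carbamidomethylation.
#' @return List with `residues` (named numeric vector), `water`, `proton`.
#' @export
mass_constants <- function(fixed_carbamidomethyl = TRUE) {
  res <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  if (fixed_carbamidomethyl) res[["C"]] <- res[["C"]] + 57.02146
  list(residues = res, water = 18.010565, proton = 1.007276)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (Keil rule) and
#' enumerates all peptides with 0..`max_missed` internal missed cleavage
#' sites whose length lies in `[min_len, max_len]`. Peptides containing
#' `X` (ambiguous translation) are emitted but flagged non-matchable.
#'
#' @param sequence Protein sequence (single string).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param min_len,max_len Peptide length bounds (defaults 6 and 60).
#' @return Data frame with `peptide`, `start` (0-based offset in the
#'   parent), `missed`, `matchable` (no `X` or other non-standard residue).
#' @examples
#' digest("AKRPGKR", max_missed = 0, min_len = 1)$peptide  # AK, RPGK, R
#' @export
digest <- function(sequence, max_missed = 2, min_len = 6, max_len = 60) {
  stopifnot(length(sequence) == 1L, nzchar(sequence), max_missed >= 0)
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # cleavage boundaries: 0, after each K/R not followed by P, n
  cut <- which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
  bounds <- c(0L, cut, n)
  nb <- length(bounds)
  out <- list()
  for (m in 0:max_missed) {
    if (nb - 1L - m < 1L) break
    s <- bounds[seq_len(nb - 1L - m)]
    e <- bounds[seq.int(2L + m, nb)]
    len <- e - s
    keep <- len >= min_len & len <= max_len
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      peptide = substring(sequence, s[keep] + 1L, e[keep]),
      start = s[keep], missed = m, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer(), matchable = logical()))
  }
  res <- do.call(rbind, out)
  res$matchable <- !grepl("[^GASPVTCLINDQKEMHFRYW]", res$peptide)
  res
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any modification mass shifts.
#'
#' @param sequence Peptide sequence (no `X` or other unknown residues).
#' @param mod_mass Total modification mass shift in Da (default 0).
#' @param constants [mass_constants()] list.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.3599
#' @export
peptide_mass <- function(sequence, mod_mass = 0,
                         constants = mass_constants()) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- constants$residues[ch]
  if (anyNA(m)) {
    stop("unknown residue(s): ",
         paste(unique(ch[is.na(m)]), collapse = ","), call. = FALSE)
  }
  sum(m) + constants$water + mod_mass
}

#' Mass-to-charge ratio of a charged peptide ion
#'
#' @param mass Neutral mass in Da.
#' @param charge Positive integer charge.
#' @param constants [mass_constants()] list.
#' @return m/z value `(mass + charge * proton) / charge`.
#' @export
mz <- function(mass, charge, constants = mass_constants()) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  (mass + charge * constants$proton) / charge
}

#' Symmetric ppm tolerance window around a mass
#'
#' @param mass Mass in Da (> 0).
#' @param tol_ppm Tolerance in parts per million (default 20).
#' @return Numeric vector `c(low, high)` = `mass * (1 -/+ tol_ppm * 1e-6)`.
#' @export
ppm_window <- function(mass, tol_ppm = 20) {
  stopifnot(all(mass > 0))
  c(low = mass * (1 - tol_ppm * 1e-6), high = mass * (1 + tol_ppm * 1e-6))
}

#' Build the searchable peptide index over a database
#'
#' Digests every database entry (targets and decoys) and collapses peptides
#' by sequence. A peptide is a decoy peptide only if every parent entry is
#' a decoy (target-decoy competition). Peptides containing non-standard
#' residues are excluded from the matchable index.
#'
#' @param db A `protegap_db` from [build_database()].
#' @inheritParams digest
#' @param constants [mass_constants()] list.
#' @return Object of class `peptide_index`: list with `peptides` (data
#'   frame: `peptide`, `mass`, `is_decoy`, sorted by mass), `parents`
#'   (data frame: `peptide`, `entry_id`, `start`, `missed`, `origin`) and
#'   `params`.
#' @export
build_peptide_index <- function(db, max_missed = 2, min_len = 6,
                                max_len = 60,
                                constants = mass_constants()) {
  e <- db$entries
  digs <- lapply(seq_len(nrow(e)), function(i) {
    d <- digest(e$sequence[i], max_missed, min_len, max_len)
    if (nrow(d) == 0) return(NULL)
    d$entry_id <- e$entry_id[i]
    d$origin <- e$origin[i]
    d
  })
  parents <- do.call(rbind, digs)
  if (is.null(parents) || nrow(parents) == 0) {
    return(structure(list(
      peptides = data.frame(peptide = character(), mass = numeric(),
                            is_decoy = logical()),
      parents = data.frame(peptide = character(), entry_id = character(),
                           start = integer(), missed = integer(),
                           origin = character()),
      params = list(max_missed = max_missed, min_len = min_len,
                    max_len = max_len, constants = constants)),
      class = "peptide_index"))
  }
  parents <- parents[parents$matchable, , drop = FALSE]
  parents <- parents[, c("peptide", "entry_id", "start", "missed", "origin")]
  seqs <- unique(parents$peptide)
  # decoy-only peptides
  tgt <- unique(parents$peptide[parents$origin != "decoy"])
  is_decoy <- !(seqs %in% tgt)
  resm <- constants$residues
  masses <- vapply(strsplit(seqs, "", fixed = TRUE),
                   function(ch) sum(resm[ch]), numeric(1)) + constants$water
  o <- order(masses, seqs)
  structure(list(
    peptides = data.frame(peptide = seqs[o], mass = masses[o],
                          is_decoy = is_decoy[o], stringsAsFactors = FALSE),
    parents = parents,
    params = list(max_missed = max_missed, min_len = min_len,
                  max_len = max_len, constants = constants)),
    class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("<peptide_index>", nrow(x$peptides), "unique peptides (",
      sum(x$peptides$is_decoy), "decoy-only )\n")
  invisible(x)
}

#' Serialize a peptide index as TSV
#'
#' @param index A `peptide_index`.
#' @param path Output path.
#' @export
write_peptide_index <- function(index, path) {
  p <- index$peptides
  par <- split(paste0(index$parents$entry_id, ":", index$parents$start),
               index$parents$peptide)
  p$parents <- vapply(p$peptide, function(s) paste(par[[s]], collapse = ";"),
                      character(1))
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
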