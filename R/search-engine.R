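.residue_masses <- function(sequence, constants) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- unname(constants$residues[ch])
  if (anyNA(m)) stop("unknown residue in ", sequence, call. = FALSE)
  m
}

#' Theoretical b/y fragment ion ladders
#'
#' Singly-charged b and y ion m/z values for a peptide, the HCD
#' fragmentation convention. A modification mass shift at a given residue
#' position is included in every ion that contains that residue (prefix
#' ions b_i with i > position; suffix ions y_j with j >= length -
#' position).
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param mod_mass Modification mass shift in Da (default 0).
#' @param mod_pos 0-based residue position of the modification (required
#'   when `mod_mass != 0`).
#' @param frag_charge Fragment charge (default 1).
#' @param constants [mass_constants()] list.
#' @return Data frame with `ion` (e.g. `"b1"`), `series`, `index`, `mz`.
#' @examples
#' theoretical_ions("AG")  # b1 = 72.0444, y1 = 76.0393, y2 = 147.0764
#' @export
theoretical_ions <- function(sequence, mod_mass = 0, mod_pos = NA,
                             frag_charge = 1,
                             constants = mass_constants()) {
  L <- nchar(sequence)
  if (L < 2) stop("peptide must have length >= 2 to fragment", call. = FALSE)
  if (mod_mass != 0 && is.na(mod_pos)) {
    stop("`mod_pos` required for a modified peptide", call. = FALSE)
  }
  res <- .residue_masses(sequence, constants)
  pre <- cumsum(res)
  i <- seq_len(L - 1L)
  b_neutral <- pre[i]
  y_neutral <- sum(res) - pre[L - i] + constants$water
  if (mod_mass != 0) {
    b_neutral <- b_neutral + ifelse(i > mod_pos, mod_mass, 0)
    y_neutral <- y_neutral + ifelse(i >= L - mod_pos, mod_mass, 0)
  }
  z <- frag_charge
  data.frame(
    ion = c(paste0("b", i), paste0("y", i)),
    series = rep(c("b", "y"), each = L - 1L),
    index = c(i, i),
    mz = c((b_neutral + z * constants$proton) / z,
           (y_neutral + z * constants$proton) / z),
    stringsAsFactors = FALSE
  )
}

#' Score one spectrum against one peptide
#'
#' Score = number of matched fragment ions plus the fraction of total peak
#' intensity carried by matched peaks. A fragment matches when a peak lies
#' within `frag_tol_ppm` of the theoretical ion either unshifted or shifted
#' by `delta`; the shift is attributed to the single residue position that
#' maximizes the matched-ion count (ties: lowest position). Deterministic
#' for fixed inputs.
#'
#' @param spectrum A spectrum list (`peaks` matrix with columns mz,
#'   intensity).
#' @param sequence Candidate peptide.
#' @param delta Precursor mass delta in Da (0 for unmodified matching).
#' @param frag_tol_ppm Fragment tolerance in ppm (default 20).
#' @param constants [mass_constants()] list.
#' @return List with `score`, `n_matched_ions`, `intensity_fraction`,
#'   `position` (0-based best shift position, `NA` when `delta == 0`).
#' @export
score_match <- function(spectrum, sequence, delta = 0, frag_tol_ppm = 20,
                        constants = mass_constants()) {
  res <- .residue_masses(sequence, constants)
  if (length(res) < 2) stop("peptide must have length >= 2", call. = FALSE)
  pk <- spectrum$peaks
  if (is.null(pk) || nrow(pk) == 0) {
    return(list(score = 0, n_matched_ions = 0L, intensity_fraction = 0,
                position = NA_integer_))
  }
  unshifted <- identical(delta, 0) || abs(delta) < 1e-12
  sc <- cpp_score_positions(pk[, 1], pk[, 2], res, delta, frag_tol_ppm,
                            constants$proton, constants$water, unshifted)
  best <- which.max(sc$nmatch)
  list(score = sc$nmatch[best] + sc$int_frac[best],
       n_matched_ions = sc$nmatch[best],
       intensity_fraction = sc$int_frac[best],
       position = if (unshifted) NA_integer_ else best - 1L)
}

#' Open search: best peptide-spectrum match per spectrum
#'
#' For each spectrum, candidate peptides are those whose unmodified mass
#' lies within `precursor_window` of the spectrum's neutral mass, or within
#' `precursor_tol_ppm` of it (the unmodified branch). The top-scoring
#' candidate is reported with its precursor mass delta. Ties are broken by
#' smaller absolute delta, then lexicographically smaller peptide. Spectra
#' with charge outside `[2, 6]` are skipped with a warning.
#'
#' @param spectra List of spectra (see [read_mgf()]).
#' @param index A [build_peptide_index()] object over targets and decoys.
#' @param precursor_window Open-search delta window in Da (default
#'   `c(-500, 500)`).
#' @param frag_tol_ppm Fragment ion tolerance in ppm (default 20).
#' @param precursor_tol_ppm Precursor tolerance in ppm for the unmodified
#'   branch (default 20).
#' @param min_matched_peaks Minimum distinct matched peaks for a PSM to
#'   be reported (default 4): spectra whose best candidate explains fewer
#'   peaks yield no PSM, the usual minimal-evidence rule of database
#'   search engines.
#' @return PSM data frame: `spectrum_id`, `peptide`, `charge`,
#'   `neutral_precursor_mass`, `delta_mass`, `score`, `n_matched_ions`,
#'   `intensity_fraction`, `is_decoy`.
#' @export
open_search <- function(spectra, index, precursor_window = c(-500, 500),
                        frag_tol_ppm = 20, precursor_tol_ppm = 20,
                        min_matched_peaks = 4) {
  constants <- index$params$constants
  charges <- vapply(spectra, function(s) as.integer(s$charge), integer(1))
  ok <- charges >= 2L & charges <= 6L
  if (any(!ok)) {
    warning(sum(!ok), " spectra with charge outside [2,6] skipped")
    spectra <- spectra[ok]
  }
  if (length(spectra) == 0 || nrow(index$peptides) == 0) {
    return(data.frame(spectrum_id = character(), peptide = character(),
                      charge = integer(), neutral_precursor_mass = numeric(),
                      delta_mass = numeric(), score = numeric(),
                      n_matched_ions = integer(),
                      intensity_fraction = numeric(), is_decoy = logical()))
  }
  smass <- vapply(spectra, neutral_mass, numeric(1), constants = constants)
  npk <- vapply(spectra, function(s) nrow(s$peaks), integer(1))
  spec_off <- c(0L, cumsum(npk))
  peak_mz <- unlist(lapply(spectra, function(s) s$peaks[, 1]), use.names = FALSE)
  peak_int <- unlist(lapply(spectra, function(s) s$peaks[, 2]), use.names = FALSE)
  if (is.null(peak_mz)) peak_mz <- peak_int <- numeric()

  pep <- index$peptides  # sorted by mass
  res_list <- strsplit(pep$peptide, "", fixed = TRUE)
  lens <- lengths(res_list)
  pep_off <- c(0L, cumsum(lens))
  res_mass <- unname(constants$residues[unlist(res_list, use.names = FALSE)])

  hits <- cpp_open_search(smass, peak_mz, peak_int, spec_off,
                          pep$mass, res_mass, pep_off, pep$peptide,
                          precursor_window[1], precursor_window[2],
                          frag_tol_ppm, precursor_tol_ppm,
                          constants$proton, constants$water,
                          as.integer(min_matched_peaks))
  data.frame(
    spectrum_id = vapply(spectra[hits$spec], `[[`, character(1), "spectrum_id"),
    peptide = pep$peptide[hits$pep],
    charge = charges[ok][hits$spec],
    neutral_precursor_mass = smass[hits$spec],
    delta_mass = hits$delta_mass,
    score = hits$score,
    n_matched_ions = hits$n_matched_ions,
    intensity_fraction = hits$intensity_fraction,
    is_decoy = pep$is_decoy[hits$pep],
    stringsAsFactors = FALSE
  )
}

.rank_psms <- function(psms) {
  order(-psms$score, abs(psms$delta_mass), psms$peptide, psms$spectrum_id)
}

#' Target-decoy FDR filtering of PSMs
#'
#' Ranks PSMs by decreasing score, estimates the FDR at each depth from
#' the decoy/target ratio above it, converts to q-values by a running
#' minimum from the bottom of the list, and accepts PSMs with q-value at
#' or below the threshold. Decoys are removed from the accepted set after
#' estimation.
#'
#' By default the +1-corrected estimator `(#decoys + 1) / #targets` is
#' used: the running-minimum step of the q-value computation otherwise
#' selects depths where the decoy count is momentarily lucky, which makes
#' the plain ratio anticonservative on small lists. `plus_one = FALSE`
#' gives the plain `#decoys / #targets` ratio.
#'
#' @param psms PSM data frame from [open_search()].
#' @param threshold Maximum q-value (default 0.01, i.e. 1% FDR).
#' @param plus_one Use the +1-corrected decoy count (default `TRUE`).
#' @param keep_all Return the full annotated list instead of the accepted
#'   subset.
#' @return PSM data frame with a `q_value` column; by default only the
#'   accepted target PSMs.
#' @export
peptide_fdr <- function(psms, threshold = 0.01, plus_one = TRUE,
                        keep_all = FALSE) {
  if (nrow(psms) == 0) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  o <- .rank_psms(psms)
  psms <- psms[o, , drop = FALSE]
  n_dec <- cumsum(psms$is_decoy) + as.integer(plus_one)
  n_tgt <- cumsum(!psms$is_decoy)
  fdr <- ifelse(n_tgt > 0, n_dec / n_tgt, Inf)
  psms$q_value <- rev(cummin(rev(fdr)))
  rownames(psms) <- NULL
  if (keep_all) return(psms)
  psms[psms$q_value <= threshold & !psms$is_decoy, , drop = FALSE]
}

#' Target-decoy FDR filtering at the protein-group level
#'
#' Applies the decoy-ratio estimator to scored groups (target and decoy
#' groups competing), where each group carries its best peptide score.
#'
#' @param groups Data frame with columns `score` and `is_decoy` (one row
#'   per group; other columns are carried through).
#' @param threshold Maximum group q-value (default 0.01).
#' @param plus_one Use the +1-corrected decoy count (default `TRUE`; see
#'   [peptide_fdr()]).
#' @return Accepted target groups with a `q_value` column.
#' @export
protein_fdr <- function(groups, threshold = 0.01, plus_one = TRUE) {
  if (nrow(groups) == 0) {
    groups$q_value <- numeric(0)
    return(groups)
  }
  o <- order(-groups$score)
  groups <- groups[o, , drop = FALSE]
  n_dec <- cumsum(groups$is_decoy) + as.integer(plus_one)
  n_tgt <- cumsum(!groups$is_decoy)
  fdr <- ifelse(n_tgt > 0, n_dec / n_tgt, Inf)
  groups$q_value <- rev(cummin(rev(fdr)))
  rownames(groups) <- NULL
  groups[groups$q_value <= threshold & !groups$is_decoy, , drop = FALSE]
}

#' Write a PSM table as TSV
#'
#' @param psms PSM data frame.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
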