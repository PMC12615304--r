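#' The modification catalog
#'
#' Loads a catalog of modification types (name, monoisotopic mass shift,
#' residue specificity, position rule). The packaged default holds 30
#' common eukaryotic modifications with Unimod monoisotopic masses
#' (acetylation, mono/di/tri-methylation, phosphorylation, the GlyGly
#' ubiquitination remnant, acylations, glycosylations, lipidations, ...).
#' Pairs whose masses differ by less than `2 * near_tol` are flagged
#' near-isobaric (e.g. GlyGly 114.0429 vs glutaryl 114.0317).
#'
#' @param path TSV file with columns `name`, `mass`, `residues`,
#'   `position`; defaults to the packaged catalog.
#' @param near_tol Da half-window used only to set the `near_isobaric`
#'   flag (default 0.02, the 20 ppm window at 1000 Da).
#' @return Data frame with `name`, `mass`, `residues`, `position`,
#'   `near_isobaric`.
#' @export
ptm_catalog <- function(path = system.file("extdata", "ptm_catalog.tsv",
                                           package = "protegap"),
                        near_tol = 0.02) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(cat$name))
  d <- abs(outer(cat$mass, cat$mass, "-"))
  diag(d) <- Inf
  cat$near_isobaric <- apply(d < 2 * near_tol, 1, any)
  cat
}

#' Assign a precursor mass delta to a modification type
#'
#' The catalog entry minimizing `|delta - mass|` within the ppm tolerance
#' (applied on the precursor scale: `tol_ppm * 1e-6 * peptide_mass`) is
#' returned. A delta within tolerance of zero is unmodified. When more
#' than one entry lies within tolerance the assignment is ambiguous: all
#' qualifying entries are reported and the assignment is deferred.
#'
#' @param delta Observed precursor mass delta in Da.
#' @param catalog A [ptm_catalog()] data frame.
#' @param peptide_mass Unmodified peptide mass in Da (sets the absolute
#'   tolerance).
#' @param tol_ppm Tolerance in ppm (default 20).
#' @return List with `status` (`"unmodified"`, `"assigned"`,
#'   `"ambiguous"` or `"none"`) and `matches` (catalog rows within
#'   tolerance, closest first).
#' @export
match_delta <- function(delta, catalog, peptide_mass, tol_ppm = 20) {
  tol <- tol_ppm * 1e-6 * peptide_mass
  if (abs(delta) <= tol) {
    return(list(status = "unmodified", matches = catalog[0, ]))
  }
  d <- abs(delta - catalog$mass)
  hit <- which(d <= tol)
  if (length(hit) == 0) return(list(status = "none", matches = catalog[0, ]))
  hit <- hit[order(d[hit])]
  list(status = if (length(hit) > 1) "ambiguous" else "assigned",
       matches = catalog[hit, , drop = FALSE])
}

#' Localize a modification site within a peptide
#'
#' Scores the spectrum with the mass shift placed at every
#' specificity-compatible residue position and returns the argmax. The
#' call is confident when the argmax is unique with a margin of at least
#' one matched ion over the runner-up; ties return the lowest compatible
#' position, not confident.
#'
#' @param spectrum Spectrum list (see [read_mgf()]).
#' @param sequence Peptide sequence.
#' @param mod_mass Modification mass shift in Da.
#' @param residues Specificity string, e.g. `"STY"`.
#' @param frag_tol_ppm Fragment tolerance in ppm (default 20).
#' @param constants [mass_constants()] list.
#' @return List with `site` (0-based position, `NA` when no compatible
#'   residue), `confident`, `position_scores`.
#' @export
localize_site <- function(spectrum, sequence, mod_mass, residues,
                          frag_tol_ppm = 20,
                          constants = mass_constants()) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  compat <- which(ch %in% strsplit(residues, "", fixed = TRUE)[[1]]) - 1L
  if (length(compat) == 0) {
    return(list(site = NA_integer_, confident = FALSE,
                position_scores = numeric(0)))
  }
  res <- .residue_masses(sequence, constants)
  sc <- cpp_score_positions(spectrum$peaks[, 1], spectrum$peaks[, 2], res,
                            mod_mass, frag_tol_ppm, constants$proton,
                            constants$water, FALSE)
  nm <- sc$nmatch[compat + 1L]
  best <- which.max(nm)  # first maximum = lowest position on ties
  margin <- if (length(nm) > 1) nm[best] - max(nm[-best]) else Inf
  list(site = compat[best], confident = margin >= 1,
       position_scores = stats::setNames(nm, compat))
}

#' Annotate accepted PSMs with modification type and site
#'
#' Runs [match_delta()] on every accepted PSM with a non-zero delta,
#' localizes unambiguous assignments with [localize_site()], and resolves
#' the peptide site to a protein coordinate on the anchor entry of the
#' peptide's protein group (first parent entry when no grouping is
#' supplied). One modification per PSM.
#'
#' @param accepted_psms Accepted PSMs from [peptide_fdr()].
#' @param spectra The spectra list searched (ids must match).
#' @param index The [build_peptide_index()].
#' @param catalog A [ptm_catalog()].
#' @param tol_ppm Precursor-scale matching tolerance in ppm (default 20).
#' @param constants [mass_constants()] list.
#' @return Data frame: `spectrum_id`, `peptide`, `type`, `mass`,
#'   `delta_mass`, `site` (0-based in peptide), `residue`, `protein`,
#'   `protein_pos` (1-based), `confident`, `ambiguous`.
#' @export
annotate_ptms <- function(accepted_psms, spectra, index, catalog,
                          tol_ppm = 20, constants = mass_constants()) {
  empty <- data.frame(spectrum_id = character(), peptide = character(),
                      type = character(), mass = numeric(),
                      delta_mass = numeric(), site = integer(),
                      residue = character(), protein = character(),
                      protein_pos = integer(), confident = logical(),
                      ambiguous = logical())
  if (nrow(accepted_psms) == 0) return(empty)
  spec_by_id <- stats::setNames(spectra,
                                vapply(spectra, `[[`, character(1),
                                       "spectrum_id"))
  par <- index$parents[index$parents$origin != "decoy", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(accepted_psms))) {
    psm <- accepted_psms[i, ]
    pmass <- psm$neutral_precursor_mass - psm$delta_mass
    md <- match_delta(psm$delta_mass, catalog, pmass, tol_ppm)
    if (md$status %in% c("unmodified", "none")) next
    ambiguous <- md$status == "ambiguous"
    mod <- md$matches[1, ]
    loc <- list(site = NA_integer_, confident = FALSE)
    if (!ambiguous) {
      loc <- localize_site(spec_by_id[[psm$spectrum_id]], psm$peptide,
                           mod$mass, mod$residues,
                           frag_tol_ppm = tol_ppm, constants = constants)
      if (is.na(loc$site)) next  # no compatible residue: dropped
    }
    pp <- par[par$peptide == psm$peptide, , drop = FALSE]
    pp <- pp[order(pp$entry_id, pp$start), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      spectrum_id = psm$spectrum_id, peptide = psm$peptide,
      type = mod$name, mass = mod$mass, delta_mass = psm$delta_mass,
      site = loc$site,
      residue = if (is.na(loc$site)) NA_character_ else
        substring(psm$peptide, loc$site + 1L, loc$site + 1L),
      protein = pp$entry_id[1],
      protein_pos = if (is.na(loc$site)) NA_integer_ else
        pp$start[1] + loc$site + 1L,
      confident = isTRUE(loc$confident) && !ambiguous,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize PTM assignments per modification type
#'
#' Sites are deduplicated by (protein, coordinate, type); proteins by id;
#' spectra are PSM counts. Ambiguous assignments are excluded, so each
#' PSM contributes to exactly one type.
#'
#' @param assignments Output of [annotate_ptms()].
#' @return Data frame: `type`, `n_proteins`, `n_sites`, `n_spectra`.
#' @export
summarize_ptms <- function(assignments) {
  a <- assignments[!assignments$ambiguous & !is.na(assignments$site), ,
                   drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(type = character(), n_proteins = integer(),
                      n_sites = integer(), n_spectra = integer()))
  }
  res <- do.call(rbind, lapply(split(a, a$type), function(d) {
    data.frame(type = d$type[1],
               n_proteins = length(unique(d$protein)),
               n_sites = nrow(unique(d[, c("protein", "protein_pos")])),
               n_spectra = nrow(d), stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$n_spectra, res$type), ]
  rownames(res) <- NULL
  res
}
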