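#' Run the full proteogenomic pipeline on a simulated (or assembled) study
#'
#' Convenience orchestration used by the examples and the acceptance
#' study: builds the combined reference + six-frame + transcript +
#' contaminant target-decoy database, digests it into the peptide index,
#' runs the open search, filters PSMs at the peptide-level FDR threshold,
#' classifies GSSPs, maps evidence to the genome, clusters GSSP loci into
#' novel-gene calls, audits annotated gene models, and groups reference
#' proteins.
#'
#' @param sim A `protegap_sim` with spectra (see
#'   [simulate_proteogenome()]), or any list providing `genome`,
#'   `annotation`, `transcripts`, `spectra`, `code`.
#' @param fdr Peptide/protein FDR threshold (default 0.01).
#' @param precursor_window Open-search window in Da (default
#'   `c(-500, 500)`).
#' @param min_entry_len Minimum translated entry length (default 20).
#' @param use_transcripts Include three-frame transcript entries
#'   (default `TRUE`).
#' @return List with `db`, `index`, `psms`, `accepted`, `evidence`,
#'   `mappings`, `loci`, `novel_calls`, `errors`, `groups`.
#' @export
run_proteogenomics <- function(sim, fdr = 0.01,
                               precursor_window = c(-500, 500),
                               min_entry_len = 20, use_transcripts = TRUE) {
  code <- sim$code
  ref <- annotated_proteins(sim$annotation, sim$genome, code)
  db <- build_database(
    reference = protein_entries(ref, "reference"),
    genomic = six_frame_entries(sim$genome, code, min_len = min_entry_len),
    transcript = if (use_transcripts)
      transcript_entries(sim$transcripts, code, min_len = min_entry_len),
    contaminants = protein_entries(contaminant_proteins(), "contaminant"),
    with_decoys = TRUE)
  index <- build_peptide_index(db)
  psms <- open_search(sim$spectra, index,
                      precursor_window = precursor_window)
  accepted <- peptide_fdr(psms, threshold = fdr)
  accepted$state <- sub("\\|.*$", "", accepted$spectrum_id)
  evidence <- assign_peptides(accepted, index)
  mappings <- map_peptide_to_genome(evidence, index, db, sim$annotation,
                                    sim$genome)
  cl <- cluster_gssps(mappings, sim$annotation, sim$genome)
  novel_calls <- call_novel_genes(cl$loci, sim$genome, code)
  errors <- detect_gene_model_errors(cl$audit, sim$annotation, sim$genome,
                                     code)
  groups <- group_proteins(evidence, db)
  list(db = db, index = index, psms = psms, accepted = accepted,
       evidence = evidence, mappings = mappings, loci = cl$loci,
       audit = cl$audit, novel_calls = novel_calls, errors = errors,
       groups = groups)
}
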