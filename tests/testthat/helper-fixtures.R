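# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# small study: quick, used by module-level tests
small_config <- function(seed = 7) {
  sim_config(seed = seed, n_annotated_genes = 20, n_hidden_genes = 3,
             n_error_genes = c(start = 1, stop = 1, intron_boundary = 1,
                               intron_coding = 1),
             peptide_sampling_depth = 60, n_noise_spectra = 150)
}

small_sim <- function() {
  .memo("small_sim", function() simulate_spectra(generate_genome(small_config())))
}

small_result <- function() {
  .memo("small_result", function() run_proteogenomics(small_sim()))
}

# default study conditions (50 genes), used by the acceptance suite
default_sim <- function() {
  .memo("default_sim", function()
    simulate_spectra(generate_genome(sim_config(seed = 1))))
}

default_result <- function() {
  .memo("default_result", function() run_proteogenomics(default_sim()))
}

# default-size study at noise-free settings (exact masses, no noise peaks)
noisefree_sim <- function() {
  .memo("noisefree_sim", function()
    simulate_spectra(generate_genome(
      sim_config(seed = 1, noise_peaks = 0, mass_error_ppm = 0))))
}

noisefree_result <- function() {
  .memo("noisefree_result", function() run_proteogenomics(noisefree_sim()))
}

# large gene set for quantification recovery (no spectra needed)
big_quant_sim <- function() {
  .memo("big_quant_sim", function() {
    sim <- generate_genome(sim_config(seed = 11, n_annotated_genes = 540,
                                      n_hidden_genes = 10,
                                      intergenic_range = c(80, 150)))
    simulate_spectral_counts(simulate_rnaseq(sim))
  })
}

# brute-force six-frame oracle: translate every codon independently with
# the Biostrings table, split on stops, keep stretches >= min_len
oracle_six_frame <- function(genome, min_len = 20) {
  tab <- Biostrings::getGeneticCode("6")
  out <- character(0)
  for (ctg in names(genome)) {
    for (seqs in c(genome[[ctg]], reverse_complement(genome[[ctg]]))) {
      for (fr in 1:3) {
        n <- nchar(seqs)
        if (n < fr + 2) next
        starts <- seq.int(fr, n - 2, by = 3)
        codons <- substring(seqs, starts, starts + 2)
        aa <- unname(tab[codons])
        aa[is.na(aa)] <- "X"
        runs <- strsplit(paste(aa, collapse = ""), "*", fixed = TRUE)[[1]]
        out <- c(out, runs[nchar(runs) >= min_len])
      }
    }
  }
  sort(out)
}

# brute-force digestion oracle: every substring bounded by valid cleavage
# boundaries with <= max_missed internal cleavage sites
oracle_digest <- function(sequence, max_missed = 2, min_len = 6,
                          max_len = 60) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  is_site <- function(i) i > 0 && i < n && ch[i] %in% c("K", "R") &&
    ch[i + 1] != "P"
  bounds <- c(0, Filter(is_site, seq_len(n)), n)
  out <- character(0)
  for (a in bounds) for (b in bounds) {
    if (b <= a) next
    internal <- sum(bounds > a & bounds < b)
    len <- b - a
    if (internal <= max_missed && len >= min_len && len <= max_len) {
      out <- c(out, substring(sequence, a + 1, b))
    }
  }
  sort(out)
}

# random protein sequence (standard alphabet)
random_protein <- function(n) {
  paste(sample(strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# spectrum built from a peptide's exact b/y ladder (+ optional shift)
ladder_spectrum <- function(peptide, id = "sp1", mod_mass = 0, mod_pos = NA,
                            charge = 2, intensity = 1) {
  ions <- theoretical_ions(peptide, mod_mass, mod_pos)
  pk <- cbind(mz = sort(ions$mz),
              intensity = rep_len(intensity, nrow(ions)))
  list(spectrum_id = id,
       precursor_mz = mz(peptide_mass(peptide, mod_mass), charge),
       charge = charge, peaks = pk)
}

# observed-GSSP detectability of hidden genes, from the ledger alone
hidden_detectability <- function(sim) {
  ref <- c(annotated_proteins(sim$annotation, sim$genome, sim$code),
           contaminant_proteins())
  hid <- sim$truth$genes[sim$truth$genes$type == "hidden", ]
  tr <- sim$truth$spectra
  data.frame(
    gene_id = hid$gene_id, contig = hid$contig,
    cds_start = hid$cds_start, cds_end = hid$cds_end,
    n_gssp = vapply(hid$gene_id, function(g) {
      peps <- unique(tr$peptide[!is.na(tr$gene) & tr$gene == g])
      sum(vapply(peps, function(p)
        !any(grepl(p, ref, fixed = TRUE)), logical(1)))
    }, numeric(1)), stringsAsFactors = FALSE)
}

# For each injected error, decide from the ledger whether any observed
# GSSP peptide qualifies as evidence for its category (error genes are
# single-exon in truth, so true peptide intervals are direct offsets).
error_evidence_covered <- function(sim) {
  tg <- sim$truth$genes
  gm <- sim$annotation
  ref <- c(annotated_proteins(gm, sim$genome, sim$code),
           contaminant_proteins())
  tr <- sim$truth$spectra
  errs <- sim$truth$errors
  covered <- logical(nrow(errs))
  for (i in seq_len(nrow(errs))) {
    g <- tg[tg$gene_id == errs$gene_id[i], ]
    lc <- nchar(sim$genome[[g$contig]])
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    orient <- function(s, e) if (g$strand == "+") c(s, e) else c(lc - e, lc - s)
    tiv <- orient(g$cds_start, g$cds_end)
    peps <- unique(tr$peptide[!is.na(tr$gene) & tr$gene == g$gene_id])
    peps <- peps[vapply(peps, function(p)
      !any(grepl(p, ref, fixed = TRUE)), logical(1))]
    hit <- FALSE
    for (p in peps) {
      off <- as.integer(regexpr(p, g$protein, fixed = TRUE)) - 1L
      if (off < 0) next
      ps <- tiv[1] + 3L * off
      pe <- ps + 3L * nchar(p)
      # a fully tryptic genome search only maps peptides whose upstream
      # in-frame neighbour is a cleavage site or a stop; internal tryptic
      # peptides (off > 0) always qualify, the protein N-terminal peptide
      # only when the codon before the CDS is a stop or encodes K/R
      if (off == 0L) {
        oseq <- if (g$strand == "+") sim$genome[[g$contig]] else
          reverse_complement(sim$genome[[g$contig]])
        upstream <- substring(oseq, tiv[1] - 2L, tiv[1])
        up_aa <- sim$code$codon_to_aa[upstream]
        if (is.na(up_aa) || !(up_aa %in% c("K", "R", "*"))) next
      }
      if (errs$category[i] == "start") {
        b <- orient(ex$start[1], ex$end[nrow(ex)])[1]
        if (ps < b && pe > b) hit <- TRUE
      } else if (errs$category[i] == "stop") {
        b <- orient(ex$start[1], ex$end[nrow(ex)])[2]
        if (ps < b && pe > b) hit <- TRUE
      } else {
        oex <- apply(ex[, c("start", "end")], 1, function(r)
          orient(r[1], r[2]))
        oex <- oex[, order(oex[1, ]), drop = FALSE]
        donor <- oex[2, 1]; acceptor <- oex[1, 2]
        if (errs$category[i] == "intron_boundary") {
          if ((ps < donor && pe > donor) || (ps < acceptor && pe > acceptor))
            hit <- TRUE
        } else {
          if (ps >= donor && pe <= acceptor) hit <- TRUE
        }
      }
      if (hit) break
    }
    covered[i] <- hit
  }
  cbind(errs, covered = covered)
}

# random stop-free CDS (ATG ... TGA) for constructed cases
.random_cds_for_test <- function(n_codons, code = genetic_code("ciliate")) {
  pool <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  paste0("ATG", paste(sample(pool, n_codons - 1, TRUE), collapse = ""), "TGA")
}
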