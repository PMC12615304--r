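test_that("b/y ladders reproduce hand-computed m/z values", {
  ions <- theoretical_ions("AG")
  expect_equal(ions$mz[ions$ion == "b1"], 72.0444, tolerance = 1e-3)
  expect_equal(ions$mz[ions$ion == "y1"], 76.0393, tolerance = 1e-3)
  # ladders run to length-1 per series; the intact-peptide y ion mass is
  # still the peptide [M+H]+
  expect_equal(nrow(ions), 2)
  expect_equal(mz(peptide_mass("AG"), 1), 147.0764, tolerance = 1e-3)
  ions3 <- theoretical_ions("AGA")
  # an N-terminal shift moves every prefix ion and no suffix ion
  m <- theoretical_ions("AGA", mod_mass = 42.010565, mod_pos = 0)
  expect_equal(m$mz[m$series == "b"] - ions3$mz[ions3$series == "b"],
               rep(42.010565, 2))
  expect_equal(m$mz[m$series == "y"], ions3$mz[ions3$series == "y"])
  # a C-terminal shift moves every suffix ion and no prefix ion
  mc <- theoretical_ions("AGA", mod_mass = 42.010565, mod_pos = 2)
  expect_equal(mc$mz[mc$series == "y"] - ions3$mz[ions3$series == "y"],
               rep(42.010565, 2))
  expect_equal(mc$mz[mc$series == "b"], ions3$mz[ions3$series == "b"])
  expect_error(theoretical_ions("A"), "length >= 2")
})

test_that("a complete ladder scores all peaks plus full intensity", {
  sp <- ladder_spectrum("PEPTIDEK")
  s <- score_match(sp, "PEPTIDEK")
  expect_equal(s$score, 14 + 1.0)
  expect_equal(s$n_matched_ions, 14L)
  empty <- list(spectrum_id = "e", precursor_mz = 500, charge = 2,
                peaks = matrix(numeric(), ncol = 2))
  expect_equal(score_match(empty, "PEPTIDEK")$score, 0)
  expect_lt(score_match(sp, "GGGGGGK")$score, 2)
})

test_that("open search recovers unmodified and shifted peptides", {
  db <- build_database(
    reference = protein_entries(c(p = "MAAPEPTIDEKLSSSGYEQRVVVNDDKTTTR"),
                                "reference"), with_decoys = TRUE)
  idx <- build_peptide_index(db)
  sp_plain <- ladder_spectrum("LSSSGYEQR", id = "plain")
  sp_phos <- ladder_spectrum("LSSSGYEQR", id = "phos",
                             mod_mass = 79.96633, mod_pos = 2)
  psms <- open_search(list(sp_plain, sp_phos), idx)
  expect_equal(nrow(psms), 2)
  expect_equal(psms$peptide, c("LSSSGYEQR", "LSSSGYEQR"))
  expect_lt(abs(psms$delta_mass[psms$spectrum_id == "plain"]), 0.02)
  expect_equal(psms$delta_mass[psms$spectrum_id == "phos"], 79.966,
               tolerance = 1e-3)
  # a spectrum matching nothing yields no PSM
  far <- list(spectrum_id = "far", precursor_mz = 4000, charge = 2,
              peaks = cbind(mz = c(200.1, 300.2), intensity = c(1, 1)))
  expect_equal(nrow(open_search(list(far), idx)), 0)
})

test_that("spectra with out-of-range charge are skipped with a warning", {
  db <- build_database(reference = protein_entries(c(p = "AAAPEPTIDEKR"),
                                                   "reference"))
  idx <- build_peptide_index(db)
  sp <- ladder_spectrum("AAAPEPTIDEK", charge = 8)
  expect_warning(res <- open_search(list(sp), idx), "charge")
  expect_equal(nrow(res), 0)
})

test_that("open search is deterministic", {
  sim <- small_sim()
  res <- small_result()
  again <- open_search(sim$spectra[1:80], res$index)
  expect_identical(open_search(sim$spectra[1:80], res$index), again)
})

test_that("self-recovery is near-perfect on noise-free spectra", {
  cfg <- sim_config(seed = 21, n_annotated_genes = 10, n_hidden_genes = 1,
                    n_error_genes = c(start = 0, stop = 0,
                                      intron_boundary = 0, intron_coding = 0),
                    peptide_sampling_depth = 30, n_noise_spectra = 0,
                    noise_peaks = 0, mass_error_ppm = 0, ptm_rates = numeric(0))
  sim <- simulate_spectra(generate_genome(cfg))
  res <- run_proteogenomics(sim)
  m <- merge(res$psms, sim$truth$spectra[, c("spectrum_id", "peptide")],
             by = "spectrum_id", suffixes = c("", ".true"))
  expect_gte(mean(m$peptide == m$peptide.true), 0.99)
})

test_that("the decoy-ratio estimator reproduces the worked 1% example", {
  psms <- data.frame(
    spectrum_id = sprintf("s%03d", 1:120),
    peptide = sprintf("PEP%03dK", 1:120),
    delta_mass = 0, score = seq(120, 1),
    is_decoy = c(rep(FALSE, 100), TRUE, rep(c(FALSE, TRUE), length.out = 19)))
  all <- peptide_fdr(psms, plus_one = FALSE, keep_all = TRUE)
  # at depth 101: 100 targets, 1 decoy -> estimated FDR 1%
  expect_equal(sum(all$is_decoy[1:101]), 1L)
  expect_equal(sum(all$is_decoy[1:101]) / sum(!all$is_decoy[1:101]), 0.01)
  expect_lte(all$q_value[101], 0.01)
  acc <- peptide_fdr(psms, threshold = 0.01, plus_one = FALSE)
  expect_gte(nrow(acc), 100)
  expect_false(any(acc$is_decoy))
  # threshold 0: only PSMs ranked above every decoy survive
  acc0 <- peptide_fdr(psms, threshold = 0, plus_one = FALSE)
  expect_equal(acc0$spectrum_id, sprintf("s%03d", 1:100))
  # degenerate inputs
  expect_equal(nrow(peptide_fdr(psms[0, ])), 0)
  alldec <- psms; alldec$is_decoy <- TRUE
  expect_equal(nrow(peptide_fdr(alldec)), 0)
})

test_that("q-values are monotone non-increasing in score", {
  all <- peptide_fdr(small_result()$psms, keep_all = TRUE)
  expect_false(is.unsorted(all$q_value))  # ranked by decreasing score
})

test_that("protein-level filtering applies the same estimator to groups", {
  g <- data.frame(group_id = c(sprintf("t%03d", 1:200), "d1", "d2"),
                  score = c(seq(300, 101), 150.5, 120.5),
                  is_decoy = c(rep(FALSE, 200), TRUE, TRUE))
  all_in <- protein_fdr(g, threshold = 2 / 200 + 1e-9, plus_one = FALSE)
  expect_equal(nrow(all_in), 200)
  single <- data.frame(group_id = "t1", score = 10, is_decoy = FALSE)
  acc <- protein_fdr(single, plus_one = FALSE)
  expect_equal(acc$q_value, 0)
  dec_only <- data.frame(group_id = "d", score = 10, is_decoy = TRUE)
  expect_equal(nrow(protein_fdr(dec_only)), 0)
})

test_that("MGF files round-trip through the reader and writer", {
  sim <- small_sim()
  path <- tempfile(fileext = ".mgf")
  write_mgf(sim$spectra[1:5], path)
  back <- read_mgf(path)
  expect_equal(length(back), 5)
  expect_equal(back[[3]]$spectrum_id, sim$spectra[[3]]$spectrum_id)
  expect_equal(back[[3]]$charge, sim$spectra[[3]]$charge)
  expect_equal(back[[3]]$precursor_mz, sim$spectra[[3]]$precursor_mz,
               tolerance = 1e-5)
  expect_equal(back[[3]]$peaks[, "mz"], sim$spectra[[3]]$peaks[, "mz"],
               tolerance = 1e-5, ignore_attr = TRUE)
})
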