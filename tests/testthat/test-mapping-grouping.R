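test_that("GSSP classification depends only on matched origins", {
  # shared tryptic peptide MSHAAAEDK in reference and six-frame entries;
  # GGGENFMICQNK only six-frame; MCQNTAMPEPK only contaminant
  ref <- protein_entries(c(refA = "MSHAAAEDKGSSVVQNLYKVVVDDDR"),
                         "reference")
  sfe <- protein_entries(c(sfB = "MSHAAAEDKGGGENFMICQNK"), "reference")
  sfe$origin <- "six_frame"
  cont <- protein_entries(c(ct = "MCQNTAMPEPKAAAAAAR"), "contaminant")
  db <- build_database(ref, sfe, NULL, cont, with_decoys = TRUE)
  idx <- build_peptide_index(db)
  psms <- data.frame(
    spectrum_id = c("s1", "s2", "s3", "s4"),
    peptide = c("MSHAAAEDK", "GGGENFMICQNK", "MCQNTAMPEPK", "MSHAAAEDK"),
    stringsAsFactors = FALSE)
  ev <- assign_peptides(psms, idx)
  expect_equal(ev$uniqueness[ev$peptide == "MSHAAAEDK"], "reference_matched")
  expect_equal(ev$psm_count[ev$peptide == "MSHAAAEDK"], 2L)
  expect_equal(ev$uniqueness[ev$peptide == "GGGENFMICQNK"], "gssp")
  expect_equal(ev$uniqueness[ev$peptide == "MCQNTAMPEPK"],
               "reference_matched")
  expect_true(ev$contaminant_only[ev$peptide == "MCQNTAMPEPK"])
  # invariance to database entry order
  db2 <- build_database(cont, sfe, NULL, ref, with_decoys = TRUE)
  ev2 <- assign_peptides(psms, build_peptide_index(db2))
  expect_equal(ev2[order(ev2$peptide), c("peptide", "uniqueness")],
               ev[order(ev$peptide), c("peptide", "uniqueness")],
               ignore_attr = TRUE)
})

test_that("parsimony grouping merges, subsumes and separates", {
  ev <- data.frame(peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK"),
                   psm_count = c(5L, 3L, 2L),
                   uniqueness = "reference_matched",
                   contaminant_only = FALSE, stringsAsFactors = FALSE)
  ev$matched_entries <- list(c("P1", "P2", "P3"), c("P1", "P2"), "P4")
  db <- build_database(reference = protein_entries(
    c(P1 = "XAAAAAAKXCCCCCCKX", P2 = "AAAAAAKCCCCCCK",
      P3 = "AAAAAAK", P4 = "DDDDDDK"), "reference"), with_decoys = FALSE)
  g <- group_proteins(ev, db)
  expect_equal(nrow(g), 2)
  big <- g[vapply(g$members, function(m) "P1" %in% m, logical(1)), ]
  expect_setequal(big$members[[1]], c("P1", "P2", "P3"))
  expect_setequal(big$peptides[[1]], c("AAAAAAK", "CCCCCCK"))
  expect_equal(big$spectral_count, 8L)
  sep <- g[g$anchor == "P4", ]
  expect_equal(sep$peptides[[1]], "DDDDDDK")
  # count conservation under anchor-only assignment
  expect_equal(sum(g$spectral_count), sum(ev$psm_count))
})

test_that("coverage is the interval-union fraction of the anchor", {
  # craft a 100-residue anchor with unique substrings
  set.seed(5)
  anchor <- random_protein(100)
  while (anyDuplicated(substring(anchor, 1:81, 20:100))) {
    anchor <- random_protein(100)
  }
  ev <- data.frame(peptide = c(substring(anchor, 1, 20),
                               substring(anchor, 11, 30)),
                   psm_count = c(1L, 1L), uniqueness = "reference_matched",
                   contaminant_only = FALSE, stringsAsFactors = FALSE)
  ev$matched_entries <- list("A1", "A1")
  db <- build_database(reference = protein_entries(c(A1 = anchor),
                                                   "reference"),
                       with_decoys = FALSE)
  g <- group_proteins(ev, db)
  cs <- coverage_stats(g, ev, db)
  expect_equal(cs$coverage, 0.30)
  expect_equal(cs$n_unique_peptides, 2L)
  expect_equal(cs$psm_count, 2L)
  # full tiling
  ev2 <- ev
  ev2$peptide <- c(substring(anchor, 1, 60), substring(anchor, 41, 100))
  ev2$matched_entries <- list("A1", "A1")
  cs2 <- coverage_stats(group_proteins(ev2, db), ev2, db)
  expect_equal(cs2$coverage, 1.0)
})

test_that("six-frame mappings offset by three nucleotides per residue", {
  res <- small_result()
  sim <- small_sim()
  maps <- res$mappings
  sf <- maps[maps$origin == "six_frame", ]
  db <- res$db$entries
  idx <- res$index$parents
  for (i in utils::head(seq_len(nrow(sf)), 50)) {
    ent <- db[db$entry_id == sf$entry_id[i], ]
    par <- idx[idx$peptide == sf$peptide[i] &
                 idx$entry_id == sf$entry_id[i], ][1, ]
    L <- nchar(sf$peptide[i])
    if (ent$strand == "+") {
      expect_equal(sf$start[i], ent$start + 3L * par$start)
    } else {
      expect_equal(sf$end[i], ent$end - 3L * par$start)
    }
    expect_equal(sf$end[i] - sf$start[i], 3L * L)
  }
})

test_that("every genomic mapping re-translates to its peptide", {
  res <- small_result()
  sim <- small_sim()
  maps <- res$mappings
  key <- paste(maps$peptide, maps$entry_id)
  for (k in unique(key)) {
    m <- maps[key == k, , drop = FALSE]
    m <- m[order(m$block), , drop = FALSE]
    aa <- translate_mapping(sim$genome, m$contig[1], m$strand[1],
                            m[, c("start", "end")], sim$code)
    expect_equal(aa, m$peptide[1])
  }
})

test_that("spliced reference mappings conserve coding length", {
  res <- small_result()
  maps <- res$mappings
  spliced <- maps[maps$origin == "reference" & maps$n_blocks > 1, ]
  if (nrow(spliced) > 0) {
    key <- paste(spliced$peptide, spliced$entry_id)
    for (k in unique(key)) {
      m <- spliced[key == k, ]
      expect_equal(sum(m$end - m$start), 3L * nchar(m$peptide[1]))
    }
  } else {
    succeed("no junction-spanning peptides in this draw")
  }
})

test_that("assigned spectral counts are conserved across groups", {
  res <- small_result()
  g <- res$groups
  grouped_peps <- unique(unlist(g$peptides))
  ev <- res$evidence
  expect_equal(sum(g$spectral_count),
               sum(ev$psm_count[ev$peptide %in% grouped_peps]))
  # every grouped peptide assigned to exactly one group
  assigned <- unlist(g$assigned_peptides)
  expect_false(anyDuplicated(assigned) > 0)
  expect_setequal(assigned, grouped_peps)
})
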