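.mapping_row <- function(peptide, contig, strand, frame, start, end) {
  data.frame(peptide = peptide, entry_id = "sf", origin = "six_frame",
             contig = contig, strand = strand, frame = frame,
             start = start, end = end, block = 1L, n_blocks = 1L,
             uniqueness = "gssp", stringsAsFactors = FALSE)
}

test_that("GC content excludes N and handles degenerate input", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("GCNN"), 1)
  expect_true(is.na(gc_content("NNNN")))
})

test_that("GSSP clustering merges by gap and separates strands/frames", {
  m <- rbind(.mapping_row("AAAAAAK", "c1", "+", 1, 100, 121),
             .mapping_row("CCCCCCK", "c1", "+", 1, 171, 192),
             .mapping_row("DDDDDDK", "c1", "-", -1, 130, 151),
             .mapping_row("EEEEEEK", "c1", "+", 1, 1000, 1021))
  cl <- cluster_gssps(m, gm = NULL, max_gap = 300)
  expect_equal(nrow(cl$loci), 3)
  first <- cl$loci[cl$loci$strand == "+" & cl$loci$start == 100, ]
  expect_equal(nrow(first$peptides[[1]]), 2)
  # within an annotated gene span on the same strand -> routed to audit
  gm <- gene_models(
    genes = data.frame(gene_id = "g1", contig = "c1", strand = "+"),
    exons = data.frame(gene_id = "g1", contig = "c1", strand = "+",
                       start = 80L, end = 300L))
  cl2 <- cluster_gssps(m, gm, max_gap = 300)
  expect_equal(nrow(cl2$audit), 2)   # the two plus-strand GSSPs inside g1
  expect_equal(nrow(cl2$loci), 2)    # minus-strand one + far one survive
})

test_that("novel-gene calling recovers a constructed ORF exactly", {
  set.seed(30)
  code <- genetic_code("ciliate")
  cds <- .random_cds_for_test(40, code)
  protein <- sub("\\*$", "", translate_dna(cds, code))
  up <- 90; down <- 60
  contig <- paste0(strrep("A", up), "TGA", cds, strrep("A", down))
  genome <- c(z = contig)
  gs <- up + 3L; ge <- gs + nchar(cds)
  # two unique peptides inside the CDS (in-frame intervals)
  p1 <- substring(protein, 3, 12); p2 <- substring(protein, 20, 30)
  m <- rbind(
    .mapping_row(p1, "z", "+", 1, gs + 3 * 2, gs + 3 * 12),
    .mapping_row(p2, "z", "+", 1, gs + 3 * 19, gs + 3 * 30))
  loci <- cluster_gssps(m, gm = NULL)$loci
  expect_equal(nrow(loci), 1)
  call <- call_novel_gene(loci[1, ], genome, code)
  expect_equal(c(call$orf_start, call$orf_end), c(gs, ge))
  expect_equal(call$start_class, "canonical_ATG")
  expect_equal(call$start_codon, "ATG")
  expect_equal(call$protein, protein)
  expect_true(all(vapply(call$peptides[[1]], grepl, logical(1),
                         x = call$protein, fixed = TRUE)))
  expect_equal(call$gc, gc_content(cds))
  # a single unique GSSP is rejected
  expect_null(call_novel_gene(
    within(loci[1, ], peptides <- list(m[1, ])), genome, code))
})

test_that("alternative and noncanonical starts are classified", {
  set.seed(31)
  code <- genetic_code("ciliate")
  body <- paste(replicate(30, "CAA"), collapse = "")  # Q-codons, stop-free
  # GTG start reachable before the evidence
  contig1 <- paste0(strrep("A", 60), "TGA", "GTG", body, "TGA",
                    strrep("A", 30))
  m1 <- .mapping_row(strrep("Q", 8), "w", "+", 1, 63 + 3 + 3 * 2,
                     63 + 3 + 3 * 10)
  m1 <- rbind(m1, .mapping_row(strrep("Q", 6), "w", "+", 1, 63 + 3 + 3 * 12,
                               63 + 3 + 3 * 18))
  loci1 <- cluster_gssps(m1, gm = NULL)$loci
  c1 <- call_novel_gene(loci1[1, ], c(w = contig1), code)
  expect_equal(c1$start_class, "alternative")
  expect_equal(c1$start_codon, "GTG")
  # stop immediately before the evidence, no candidate start at all
  contig2 <- paste0(strrep("A", 60), "TGA", "AAT", body, "TGA",
                    strrep("A", 30))
  m2 <- rbind(.mapping_row(strrep("Q", 8), "w", "+", 1, 63 + 3 + 3 * 2,
                           63 + 3 + 3 * 10),
              .mapping_row(strrep("Q", 6), "w", "+", 1, 63 + 3 + 3 * 12,
                           63 + 3 + 3 * 18))
  loci2 <- cluster_gssps(m2, gm = NULL)$loci
  c2 <- call_novel_gene(loci2[1, ], c(w = contig2), code)
  expect_equal(c2$start_class, "noncanonical")
  expect_equal(c2$start_codon, "AAT")
  expect_equal(c2$orf_start, 63)
})

test_that("gene-model audit classifies the four error categories", {
  # plus-strand single-exon gene [100, 400); codon grid: pos = 100 mod 3
  genome <- c(c1 = strrep("A", 600))
  gm1 <- gene_models(
    genes = data.frame(gene_id = "g1", contig = "c1", strand = "+"),
    exons = data.frame(gene_id = "g1", contig = "c1", strand = "+",
                       start = 100L, end = 400L))
  m_start <- .mapping_row("AAAAAAAAAAK", "c1", "+", 1, 70, 103)   # crosses 100
  m_stop <- .mapping_row("AAAAAAAAAAK", "c1", "+", 1, 370, 403)   # crosses 400
  m_off <- .mapping_row("AAAAAAAAAAK", "c1", "+", 1, 71, 104)     # off frame
  errs <- detect_gene_model_errors(rbind(m_start, m_stop, m_off), gm1, genome)
  expect_setequal(errs$category, c("start_error", "stop_error"))
  # two-exon gene with annotated intron [160, 220)
  gm2 <- gene_models(
    genes = data.frame(gene_id = "g2", contig = "c1", strand = "+"),
    exons = data.frame(gene_id = "g2", contig = "c1", strand = "+",
                       start = c(100L, 220L), end = c(160L, 400L)))
  m_donor <- .mapping_row("AAAAAAAAAAK", "c1", "+", 1, 145, 178)  # crosses 160
  m_inside <- .mapping_row("AAAAAAK", "c1", "+", 1, 169, 190)     # in intron
  errs2 <- detect_gene_model_errors(rbind(m_donor, m_inside), gm2, genome)
  expect_true(any(errs2$category == "intron_boundary_error" &
                    errs2$gene_id == "g2"))
  expect_true(any(errs2$category == "intron_coding" & errs2$gene_id == "g2"))
  # a clean mapping wholly inside an exon yields no record
  m_clean <- .mapping_row("AAAAAAK", "c1", "+", 1, 103, 124)
  expect_equal(nrow(detect_gene_model_errors(m_clean, gm1, genome)), 0)
})

test_that("novel-call GFF3 and FASTA outputs are written", {
  res <- small_result()
  calls <- res$novel_calls
  expect_gt(nrow(calls), 0)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_novel_calls(calls, gff, fa)
  gr <- rtracklayer::import(gff)
  expect_equal(length(gr), nrow(calls))
  expect_equal(sort(gr$ID), sort(calls$call_id))
  aa <- Biostrings::readAAStringSet(fa)
  expect_equal(sort(as.character(aa)), sort(calls$protein),
               ignore_attr = TRUE)
})
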