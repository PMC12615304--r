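test_that("ciliate code matches the canonical table 6 and reassigns TAA/TAG", {
  code <- genetic_code("ciliate")
  oracle <- Biostrings::getGeneticCode("6")
  expect_equal(code$codon_to_aa[names(oracle)], as.character(oracle),
               ignore_attr = TRUE)
  expect_equal(unname(code$codon_to_aa[c("TAA", "TAG")]), c("Q", "Q"))
  expect_equal(code$stop_codons, "TGA")
  std <- genetic_code("standard")
  expect_setequal(std$stop_codons, c("TAA", "TAG", "TGA"))
})

test_that("translation handles frames, stops, N codons and bad input", {
  code <- genetic_code("ciliate")
  expect_equal(translate_dna("ATGAAATAA", code), "MKQ")
  expect_equal(translate_dna("ATGAAATGA", code), "MK*")
  expect_equal(translate_dna("ATGAAA", code, frame = 2), "*")  # TGA AA(drop)
  expect_equal(translate_dna("ATNAAA", code), "XK")
  expect_equal(translate_dna("ATGAAAA", code), "MK")  # partial codon dropped
  expect_error(translate_dna("", code), "non-empty")
  expect_error(translate_dna("ATGU", code), "characters")
  expect_error(translate_dna("AT", code), "too short")
})

test_that("six-frame entries match the brute-force codon-scan oracle", {
  set.seed(42)
  code <- genetic_code("ciliate")
  for (rep in 1:25) {
    len <- sample(80:1200, 1)
    genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), len, TRUE,
                                  prob = c(.35, .15, .15, .35)),
                           collapse = ""))
    got <- six_frame_entries(genome, code, min_len = 10)
    expect_equal(sort(got$sequence), oracle_six_frame(genome, min_len = 10))
  }
})

test_that("six-frame output is symmetric under reverse complement", {
  set.seed(43)
  for (rep in 1:10) {
    genome <- c(x = paste(sample(c("A", "C", "G", "T"), 700, TRUE),
                          collapse = ""))
    rc <- c(x = reverse_complement(genome[["x"]]))
    a <- six_frame_entries(genome, min_len = 8)
    b <- six_frame_entries(rc, min_len = 8)
    expect_equal(sort(a$sequence), sort(b$sequence))
    # strands exchange
    expect_equal(sort(a$sequence[a$strand == "+"]),
                 sort(b$sequence[b$strand == "-"]))
  }
})

test_that("entries below the length floor are dropped, above kept", {
  code <- genetic_code("ciliate")
  # frame +1: 25 non-stop codons, stop, 19 codons, stop
  seg <- function(n) paste(rep("AAG", n), collapse = "")
  genome <- c(k = paste0(seg(25), "TGA", seg(19), "TGA"))
  got <- six_frame_entries(genome, code, min_len = 20)
  fwd1 <- got[got$frame == 1, ]
  expect_equal(nrow(fwd1), 1)
  expect_equal(fwd1$sequence, strrep("K", 25))
  expect_true(all(nchar(got$sequence) >= 20))
  expect_false(any(grepl("*", got$sequence, fixed = TRUE)))
})

test_that("an all-A contig yields the full-length polylysine stretch", {
  genome <- c(a = strrep("A", 120))
  got <- six_frame_entries(genome, min_len = 20)
  f1 <- got[got$frame == 1, ]
  expect_equal(f1$sequence, strrep("K", 40))
  expect_equal(c(f1$start, f1$end), c(0L, 120L))
})

test_that("minus-strand provenance round-trips through extraction", {
  set.seed(44)
  genome <- c(m = paste(sample(c("A", "C", "G", "T"), 600, TRUE,
                               prob = c(.35, .15, .15, .35)), collapse = ""))
  got <- six_frame_entries(genome, min_len = 10)
  minus <- got[got$strand == "-", ]
  expect_gt(nrow(minus), 0)
  for (i in seq_len(nrow(minus))) {
    aa <- translate_mapping(genome, "m", "-",
                            data.frame(start = minus$start[i],
                                       end = minus$end[i]))
    expect_equal(aa, minus$sequence[i])
  }
})

test_that("transcript entries translate three forward frames with the floor", {
  code <- genetic_code("ciliate")
  cds <- .random_cds_for_test(40, code)
  tx <- c(t1 = cds)
  got <- transcript_entries(tx, code, min_len = 20)
  prot <- sub("\\*$", "", translate_dna(cds, code))
  expect_true(prot %in% got$sequence[got$frame == 1])
  # 59 nt stop-free -> 19 aa -> filtered
  short <- c(s1 = paste(rep("AAG", 19), collapse = ""))
  expect_equal(nrow(transcript_entries(short, code, min_len = 20)), 0)
  expect_equal(nrow(transcript_entries(stats::setNames(character(0),
                                                       character(0)))), 0)
  expect_error(transcript_entries(c(a = "ATGAAA", a = "ATGAAA"), code),
               "unique")
})

test_that("database assembly appends one reversed decoy per target", {
  ref <- protein_entries(c(r1 = "PEPTIDEKAAAAAAAAAAAR",
                           r2 = "MSSSSSSSSSSKAAAAAAAR"), "reference")
  sf <- six_frame_entries(c(c1 = strrep("A", 200)), min_len = 20)[1:3, ]
  cont <- protein_entries(c(ct = "MKKKKKKKKKKKKKKKKKKR"), "contaminant")
  db <- build_database(ref, sf, NULL, cont, with_decoys = TRUE)
  expect_equal(nrow(db$entries), 12)
  expect_equal(unname(db$counts["decoy"]), 6L)
  dec <- db$entries[db$entries$origin == "decoy", ]
  expect_equal(dec$sequence[dec$source_id == "r1"],
               paste(rev(strsplit("PEPTIDEKAAAAAAAAAAAR", "")[[1]]),
                     collapse = ""))
  # reversal example
  expect_equal(protegap:::.reverse_strings("PEPTIDEK"), "KEDITPEP")
  empty <- build_database()
  expect_equal(nrow(empty$entries), 0)
  expect_error(build_database(ref, reference2 <- ref), "duplicate")
})

test_that("database FASTA round-trips entries and provenance", {
  sf <- six_frame_entries(c(c9 = strrep("A", 120)), min_len = 20)
  db <- build_database(genomic = sf, with_decoys = TRUE)
  path <- tempfile(fileext = ".fa")
  write_database_fasta(db, path)
  back <- read_database_fasta(path)
  expect_equal(back$entries$sequence, db$entries$sequence)
  expect_equal(back$entries$origin, db$entries$origin)
  expect_equal(back$entries$start, db$entries$start)
})
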