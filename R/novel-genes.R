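#' GC content of a DNA string
#'
#' `(#G + #C) / length`, with N excluded from numerator and denominator.
#'
#' @param dna DNA string over A/C/G/T/N.
#' @return Fraction in `[0, 1]`, or `NA` for an all-N (or empty after N
#'   removal) sequence.
#' @export
gc_content <- function(dna) {
  .check_dna(dna)
  ch <- strsplit(dna, "", fixed = TRUE)[[1]]
  ch <- ch[ch != "N"]
  if (length(ch) == 0) return(NA_real_)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Cluster GSSP genomic mappings into candidate loci
#'
#' GSSPs on the same contig, strand and reading frame whose intervals lie
#' within `max_gap` nucleotides of each other are merged into one locus.
#' GSSPs overlapping an annotated gene span on the same strand are routed
#' to gene-model auditing instead of novel-locus calling.
#'
#' @param mappings Genomic mappings from [map_peptide_to_genome()]
#'   (six-frame rows with `uniqueness == "gssp"` are used).
#' @param gm A [gene_models()] object (annotated genes), or `NULL` to skip
#'   routing.
#' @param genome Named contig vector (for span computation on `-` strand
#'   genes; only contig names are needed here).
#' @param max_gap Maximum nucleotide gap between GSSPs of one locus
#'   (default 300).
#' @return List with `loci` (data frame: `locus_id`, `contig`, `strand`,
#'   `frame`, `start`, `end`, `peptides` list column of mapping rows) and
#'   `audit` (mapping rows routed to error auditing).
#' @export
cluster_gssps <- function(mappings, gm = NULL, genome = NULL,
                          max_gap = 300) {
  g <- mappings[mappings$uniqueness == "gssp" &
                  mappings$origin == "six_frame", , drop = FALSE]
  empty_loci <- data.frame(locus_id = character(), contig = character(),
                           strand = character(), frame = integer(),
                           start = integer(), end = integer())
  if (nrow(g) == 0) return(list(loci = empty_loci, audit = g))
  # route gene-overlapping GSSPs (same strand) to the audit
  to_audit <- rep(FALSE, nrow(g))
  if (!is.null(gm) && nrow(gm$genes) > 0) {
    spans <- do.call(rbind, lapply(seq_len(nrow(gm$genes)), function(i) {
      e <- gm$exons[gm$exons$gene_id == gm$genes$gene_id[i], ]
      data.frame(contig = gm$genes$contig[i], strand = gm$genes$strand[i],
                 start = min(e$start), end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(g))) {
      to_audit[i] <- any(spans$contig == g$contig[i] &
                           spans$strand == g$strand[i] &
                           spans$start < g$end[i] & g$start[i] < spans$end)
    }
  }
  audit <- g[to_audit, , drop = FALSE]
  g <- g[!to_audit, , drop = FALSE]
  if (nrow(g) == 0) return(list(loci = empty_loci, audit = audit))
  key <- paste(g$contig, g$strand, g$frame, sep = "\r")
  loci <- list()
  for (k in unique(key)) {
    gg <- g[key == k, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(gg$start[-1] >
                                    cummax(gg$end[-nrow(gg)]) + max_gap)))
    for (cid in unique(cl)) {
      sub <- gg[cl == cid, , drop = FALSE]
      loci[[length(loci) + 1L]] <- list(
        contig = sub$contig[1], strand = sub$strand[1],
        frame = sub$frame[1], start = min(sub$start), end = max(sub$end),
        peptides = sub)
    }
  }
  df <- data.frame(
    locus_id = sprintf("locus_%03d", seq_along(loci)),
    contig = vapply(loci, `[[`, character(1), "contig"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    frame = as.integer(vapply(loci, `[[`, numeric(1), "frame")),
    start = as.integer(vapply(loci, function(x) min(x$peptides$start),
                              numeric(1))),
    end = as.integer(vapply(loci, function(x) max(x$peptides$end),
                            numeric(1))),
    stringsAsFactors = FALSE
  )
  df$peptides <- lapply(loci, `[[`, "peptides")
  list(loci = df, audit = audit)
}

#' Call a novel gene from a GSSP locus
#'
#' Rejects loci with fewer than `min_unique` unique supporting GSSPs.
#' Otherwise the ORF is inferred in the locus frame: extend upstream
#' in-frame to the nearest stop codon, then forward to the first candidate
#' start (ATG preferred over the alternative initiators GTG/CTG/TTG even
#' when an alternative lies further upstream); when no candidate start
#' exists upstream of the peptide evidence, the codon at the most upstream
#' evidence-consistent position (immediately after the bounding stop) is
#' reported with `start_class = "noncanonical"`. Downstream, the ORF runs
#' to the first in-frame stop (included in the interval). Calls truncated
#' by a contig boundary are flagged partial.
#'
#' @param locus One row of `cluster_gssps()$loci` (with its `peptides`).
#' @param genome Named contig vector.
#' @param code A [genetic_code()] object.
#' @param min_unique Minimum unique supporting GSSPs (default 2).
#' @return One-row data frame (`call_id`, `contig`, `strand`, `frame`,
#'   `orf_start`, `orf_end`, `protein`, `start_codon`, `start_class`,
#'   `gc`, `n_gssps`, `partial`, `peptides` list column) or `NULL` when
#'   rejected.
#' @export
call_novel_gene <- function(locus, genome, code = genetic_code(),
                            min_unique = 2) {
  peps <- locus$peptides[[1]]
  n_unique <- length(unique(peps$peptide))
  if (n_unique < min_unique) return(NULL)
  ctg <- genome[[locus$contig]]
  lc <- nchar(ctg)
  oseq <- if (locus$strand == "+") ctg else reverse_complement(ctg)
  # oriented coordinates of the evidence span
  if (locus$strand == "+") {
    span_s <- min(peps$start); span_e <- max(peps$end)
  } else {
    span_s <- lc - max(peps$end); span_e <- lc - min(peps$start)
  }
  codon_at <- function(p) substring(oseq, p + 1L, p + 3L)
  is_stop <- function(cd) cd %in% code$stop_codons
  partial <- FALSE
  # upstream: walk back in frame to the nearest stop
  p <- span_s - 3L
  while (p >= 0L && !is_stop(codon_at(p))) p <- p - 3L
  if (p < 0L) {
    partial <- TRUE
    from <- span_s %% 3L  # frame anchor at contig edge
  } else {
    from <- p + 3L
  }
  cand <- if (from <= span_s) seq.int(from, span_s, by = 3L) else integer(0)
  codons <- vapply(cand, codon_at, character(1))
  pick <- function(set) {
    hit <- which(codons %in% set)
    if (length(hit)) cand[hit[1]] else NA_integer_
  }
  orf_s <- pick(code$start_codons)
  start_class <- "canonical_ATG"
  if (is.na(orf_s)) {
    orf_s <- pick(code$alt_start_codons)
    start_class <- "alternative"
  }
  if (is.na(orf_s)) {
    orf_s <- from
    start_class <- "noncanonical"
  }
  # downstream: first in-frame stop (included in the CDS interval)
  q <- span_e
  while (q + 3L <= nchar(oseq) && !is_stop(codon_at(q))) q <- q + 3L
  if (q + 3L > nchar(oseq)) {
    partial <- TRUE
    orf_e <- q
  } else {
    orf_e <- q + 3L
  }
  protein <- translate_dna(substring(oseq, orf_s + 1L, orf_e), code)
  protein <- sub("\\*$", "", protein)
  if (locus$strand == "+") {
    gs <- orf_s; ge <- orf_e
  } else {
    gs <- lc - orf_e; ge <- lc - orf_s
  }
  dna <- substring(ctg, gs + 1L, ge)
  out <- data.frame(
    call_id = paste0("novel_", locus$locus_id), contig = locus$contig,
    strand = locus$strand, frame = locus$frame, orf_start = gs,
    orf_end = ge, protein = protein,
    start_codon = codon_at(orf_s), start_class = start_class,
    gc = gc_content(dna), n_gssps = n_unique, partial = partial,
    stringsAsFactors = FALSE
  )
  out$peptides <- list(unique(peps$peptide))
  out
}

#' @rdname call_novel_gene
#' @param loci The `loci` data frame from [cluster_gssps()].
#' @export
call_novel_genes <- function(loci, genome, code = genetic_code(),
                             min_unique = 2) {
  calls <- lapply(seq_len(nrow(loci)), function(i)
    call_novel_gene(loci[i, , drop = FALSE], genome, code, min_unique))
  calls <- Filter(Negate(is.null), calls)
  if (length(calls) == 0) {
    return(data.frame(call_id = character(), contig = character(),
                      strand = character(), frame = integer(),
                      orf_start = integer(), orf_end = integer(),
                      protein = character(), start_codon = character(),
                      start_class = character(), gc = numeric(),
                      n_gssps = integer(), partial = logical()))
  }
  do.call(rbind, calls)
}

# Oriented peptide interval + oriented exon table for one gene.
.orient_interval <- function(start, end, strand, lc) {
  if (strand == "+") c(start, end) else c(lc - end, lc - start)
}

#' Audit annotated gene models against contiguous peptide evidence
#'
#' Classifies genome-anchored six-frame peptide mappings that conflict
#' with an annotated gene model into four categories:
#' * `start_error`: peptide maps in-frame upstream of and crossing the
#'   annotated start (5' CDS boundary);
#' * `stop_error`: peptide maps in-frame downstream of and crossing the
#'   annotated stop (3' CDS boundary);
#' * `intron_boundary_error`: peptide translates contiguously across an
#'   annotated exon-intron boundary, in frame with the flanking exon;
#' * `intron_coding`: peptide maps entirely within an annotated intron,
#'   in frame with the upstream CDS continued through the intron.
#'
#' One record per (gene, category), with all evidence peptides attached.
#'
#' @param audit_mappings Six-frame mapping rows (e.g.
#'   `cluster_gssps()$audit`).
#' @param gm A [gene_models()] object.
#' @param genome Named contig vector.
#' @param code A [genetic_code()] object (unused in the decision rules but
#'   kept for interface symmetry with callers that re-translate evidence).
#' @return Data frame: `gene_id`, `category`, `n_peptides`, `peptides`
#'   (list column).
#' @export
detect_gene_model_errors <- function(audit_mappings, gm, genome,
                                     code = genetic_code()) {
  empty <- data.frame(gene_id = character(), category = character(),
                      n_peptides = integer())
  if (nrow(audit_mappings) == 0 || nrow(gm$genes) == 0) return(empty)
  recs <- list()
  for (gi in seq_len(nrow(gm$genes))) {
    gene <- gm$genes[gi, ]
    lc <- nchar(genome[[gene$contig]])
    oe <- .oriented_exons(gm, gene$gene_id, lc)
    gs <- oe$ostart[1]
    ge <- oe$oend[nrow(oe)]
    m <- audit_mappings[audit_mappings$contig == gene$contig &
                          audit_mappings$strand == gene$strand, ,
                        drop = FALSE]
    if (nrow(m) == 0) next
    for (k in seq_len(nrow(m))) {
      iv <- .orient_interval(m$start[k], m$end[k], gene$strand, lc)
      ps <- iv[1]; pe <- iv[2]
      pep <- m$peptide[k]
      add <- function(cat) {
        recs[[length(recs) + 1L]] <<- data.frame(
          gene_id = gene$gene_id, category = cat, peptide = pep,
          stringsAsFactors = FALSE)
      }
      # start: crosses 5' boundary, in frame with first exon's codon grid
      if (ps < gs && pe > gs && (gs - ps) %% 3L == 0L) add("start_error")
      # stop: crosses 3' boundary, in frame with last exon's grid
      last <- nrow(oe)
      anch3 <- (oe$ostart[last] - oe$cds_start[last]) %% 3L
      if (ps < ge && pe > ge && ps %% 3L == anch3) add("stop_error")
      if (last > 1) {
        for (x in seq_len(last - 1L)) {
          donor <- oe$oend[x]
          acceptor <- oe$ostart[x + 1L]
          anch_d <- (oe$ostart[x] - oe$cds_start[x]) %% 3L
          anch_a <- anch_d  # contiguous translation continues the same grid
          crosses <- (ps < donor && pe > donor) ||
            (ps < acceptor && pe > acceptor)
          if (crosses && ps %% 3L == anch_d) add("intron_boundary_error")
          inside <- ps >= donor && pe <= acceptor
          if (inside && ps %% 3L == anch_a) add("intron_coding")
        }
      }
    }
  }
  if (length(recs) == 0) return(empty)
  all <- do.call(rbind, recs)
  agg <- unique(all[, c("gene_id", "category")])
  agg$peptides <- lapply(seq_len(nrow(agg)), function(i)
    sort(unique(all$peptide[all$gene_id == agg$gene_id[i] &
                              all$category == agg$category[i]])))
  agg$n_peptides <- lengths(agg$peptides)
  rownames(agg) <- NULL
  agg[, c("gene_id", "category", "n_peptides", "peptides")]
}

#' Write novel-gene calls as GFF3 and protein FASTA
#'
#' @param calls Output of [call_novel_genes()].
#' @param gff_path,fasta_path Output paths (either may be `NULL`).
#' @export
write_novel_calls <- function(calls, gff_path = NULL, fasta_path = NULL) {
  if (!is.null(gff_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = calls$contig,
      ranges = IRanges::IRanges(start = calls$orf_start + 1L,
                                end = calls$orf_end),
      strand = calls$strand, type = "gene", ID = calls$call_id,
      gssp_count = calls$n_gssps, start_class = calls$start_class)
    rtracklayer::export(gr, gff_path, format = "gff3")
  }
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(calls$protein)
    names(aa) <- calls$call_id
    Biostrings::writeXStringSet(aa, fasta_path)
  }
  invisible(calls)
}
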