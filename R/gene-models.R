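#' Construct a gene-model set
#'
#' Gene models hold the annotation that peptide evidence is audited
#' against: one row per gene plus its ordered CDS segments ("exons" here
#' always means coding segments). All internal coordinates are 0-based
#' half-open on the forward strand; GFF3 I/O converts from/to 1-based
#' inclusive.
#'
#' @param genes Data frame with `gene_id`, `contig`, `strand`.
#' @param exons Data frame with `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open), non-overlapping within a gene.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "contig", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  bad <- unlist(lapply(split(exons, exons$gene_id), function(e) {
    nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])
  }))
  if (any(bad)) stop("overlapping exons within a gene", call. = FALSE)
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes,", nrow(x$exons),
      "CDS segments\n")
  invisible(x)
}

# Exons of one gene in 5'->3' order with oriented coordinates.
# opos(g) = g on "+"; on "-" the interval [s,e) maps to [Lc-e, Lc-s).
# cds_start = cumulative CDS nucleotides before each exon.
.oriented_exons <- function(gm, gene_id, contig_len) {
  g <- gm$genes[gm$genes$gene_id == gene_id, ]
  e <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  if (g$strand == "+") {
    e <- e[order(e$start), , drop = FALSE]
    os <- e$start; oe <- e$end
  } else {
    e <- e[order(-e$start), , drop = FALSE]
    os <- contig_len - e$end; oe <- contig_len - e$start
  }
  len <- oe - os
  data.frame(ostart = os, oend = oe,
             cds_start = cumsum(c(0L, len[-length(len)])),
             fstart = e$start, fend = e$end)
}

# Project a CDS-coordinate range [a, b) of a gene onto forward-strand
# genomic intervals (possibly split across junctions).
.cds_to_genomic <- function(gm, gene_id, a, b, contig_len) {
  oe <- .oriented_exons(gm, gene_id, contig_len)
  strand <- gm$genes$strand[gm$genes$gene_id == gene_id]
  out <- list()
  for (i in seq_len(nrow(oe))) {
    c0 <- oe$cds_start[i]
    c1 <- c0 + (oe$oend[i] - oe$ostart[i])
    lo <- max(a, c0); hi <- min(b, c1)
    if (lo >= hi) next
    qa <- lo - c0; qb <- hi - c0
    if (strand == "+") {
      out[[length(out) + 1L]] <- c(oe$fstart[i] + qa, oe$fstart[i] + qb)
    } else {
      out[[length(out) + 1L]] <- c(oe$fend[i] - qb, oe$fend[i] - qa)
    }
  }
  if (length(out) == 0) return(NULL)
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Spliced CDS and translated protein of annotated genes
#'
#' `spliced_cds` concatenates each gene's CDS segments 5'->3' (reverse
#' complemented on the minus strand); `annotated_proteins` translates them
#' under the given code, dropping a trailing stop if present.
#'
#' @param gm A [gene_models()] object.
#' @param genome Named character vector of contig sequences.
#' @param code A [genetic_code()] object.
#' @return Named character vector (by `gene_id`).
#' @export
spliced_cds <- function(gm, genome) {
  vapply(gm$genes$gene_id, function(gid) {
    g <- gm$genes[gm$genes$gene_id == gid, ]
    ctg <- genome[[g$contig]]
    e <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    s <- paste(substring(ctg, e$start + 1L, e$end), collapse = "")
    if (g$strand == "-") reverse_complement(s) else s
  }, character(1))
}

#' @rdname spliced_cds
#' @export
annotated_proteins <- function(gm, genome, code = genetic_code()) {
  cds <- spliced_cds(gm, genome)
  vapply(cds, function(s) sub("\\*+$", "", translate_dna(s, code)),
         character(1))
}

#' Read and write gene models as GFF3
#'
#' Writes `gene` and `CDS` features with `ID`/`Parent` attributes via
#' rtracklayer, converting between internal 0-based half-open and GFF3
#' 1-based inclusive coordinates.
#'
#' @param gm A [gene_models()] object.
#' @param path File path.
#' @export
write_gff3 <- function(gm, path) {
  g <- gm$genes
  spans <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    e <- gm$exons[gm$exons$gene_id == g$gene_id[i], ]
    c(min(e$start), max(e$end))
  }))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = spans[, 1] + 1L, end = spans[, 2]),
    strand = g$strand, type = "gene", ID = g$gene_id,
    Parent = as(rep(list(character(0)), nrow(g)), "CharacterList")
  )
  e <- gm$exons
  # GFF3 phase: offset to the next codon start within each CDS segment
  phase <- integer(nrow(e))
  for (gid in unique(e$gene_id)) {
    idx <- which(e$gene_id == gid)
    strand <- e$strand[idx[1]]
    ord <- idx[order(e$start[idx], decreasing = (strand == "-"))]
    cum <- cumsum(c(0L, (e$end - e$start)[ord][-length(ord)]))
    phase[ord] <- (3L - cum %% 3L) %% 3L
  }
  cds_gr <- GenomicRanges::GRanges(
    seqnames = e$contig,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand, type = "CDS",
    ID = paste0(e$gene_id, ".cds", seq_len(nrow(e))),
    Parent = as(as.list(e$gene_id), "CharacterList")
  )
  cds_gr$phase <- phase
  gene_gr$phase <- NA_integer_
  rtracklayer::export(c(gene_gr, cds_gr), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_cds <- tolower(as.character(gr$type)) == "cds"
  cds <- gr[is_cds]
  parent <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  exons <- data.frame(
    gene_id = parent,
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    stringsAsFactors = FALSE
  )
  genes <- unique(exons[, c("gene_id", "contig", "strand")])
  gene_models(genes, exons)
}
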