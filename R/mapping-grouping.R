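#' Aggregate accepted PSMs into peptide evidence and classify GSSPs
#'
#' Each distinct peptide sequence is aggregated over its PSMs and matched
#' against database entries through the digestion-derived parent map (so
#' matches always have tryptic termini). A peptide is a genome
#' search-specific peptide (GSSP) when none of its parents is a reference
#' or contaminant entry; peptides matching only contaminants are classed
#' `reference_matched` but flagged so they are excluded from genome
#' mapping. Decoy parents are ignored. I and L are treated as distinct
#' residues throughout.
#'
#' @param accepted_psms Accepted target PSMs from [peptide_fdr()].
#' @param index The [build_peptide_index()] used for the search.
#' @return Data frame with `peptide`, `psm_count`, `uniqueness`
#'   (`"gssp"` or `"reference_matched"`), `contaminant_only`, and
#'   `matched_entries` (list column of entry ids).
#' @export
assign_peptides <- function(accepted_psms, index) {
  if (nrow(accepted_psms) == 0) {
    return(data.frame(peptide = character(), psm_count = integer(),
                      uniqueness = character(), contaminant_only = logical()))
  }
  counts <- table(accepted_psms$peptide)
  seqs <- sort(names(counts))
  par <- index$parents[index$parents$origin != "decoy", , drop = FALSE]
  par <- par[par$peptide %in% seqs, , drop = FALSE]
  sp <- split(par, par$peptide)
  miss <- setdiff(seqs, names(sp))
  if (length(miss)) {
    stop("accepted peptide(s) match no target entry: ",
         paste(utils::head(miss, 3), collapse = ","), call. = FALSE)
  }
  origin_sets <- lapply(sp, function(d) unique(d$origin))
  has_ref <- vapply(origin_sets, function(o)
    any(o %in% c("reference", "contaminant")), logical(1))
  contam_only <- vapply(origin_sets, function(o)
    identical(o, "contaminant") || all(o == "contaminant"), logical(1))
  ev <- data.frame(
    peptide = seqs,
    psm_count = as.integer(counts[seqs]),
    uniqueness = ifelse(has_ref[seqs], "reference_matched", "gssp"),
    contaminant_only = contam_only[seqs],
    stringsAsFactors = FALSE
  )
  ev$matched_entries <- lapply(sp[seqs], function(d) unique(d$entry_id))
  rownames(ev) <- NULL
  ev
}

#' Parsimony protein grouping
#'
#' Entries with identical peptide sets are merged into one group; entries
#' whose peptide set is a strict subset of another's are subsumed into
#' that group; each peptide is then assigned to exactly one group by a
#' greedy pass over groups ordered by descending peptide count, then
#' lexicographic anchor id (shared peptides go to the anchor group only,
#' keeping spectral-count totals conserved).
#'
#' Grouping is restricted to origins in `origins`; by default six-frame
#' and transcript entries are excluded, mirroring grouping over the
#' annotated proteome (six-frame evidence is handled by the novel-gene
#' caller).
#'
#' @param evidence Peptide evidence from [assign_peptides()].
#' @param db The `protegap_db`.
#' @param origins Entry origins eligible for grouping.
#' @return Data frame: `group_id`, `anchor` (entry id), `members`,
#'   `peptides`, `assigned_peptides`, `unique_peptides` (list columns),
#'   `spectral_count`, `n_unique_peptides`.
#' @export
group_proteins <- function(evidence, db,
                           origins = c("reference", "contaminant")) {
  empty <- data.frame(group_id = character(), anchor = character(),
                      spectral_count = integer(),
                      n_unique_peptides = integer())
  if (nrow(evidence) == 0) return(empty)
  keep_entries <- db$entries$entry_id[db$entries$origin %in% origins]
  pairs <- do.call(rbind, lapply(seq_len(nrow(evidence)), function(i) {
    ids <- intersect(evidence$matched_entries[[i]], keep_entries)
    if (length(ids) == 0) return(NULL)
    data.frame(peptide = evidence$peptide[i], entry_id = ids,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  sets <- lapply(split(pairs$peptide, pairs$entry_id), function(x) sort(unique(x)))
  # merge identical peptide sets (anchor = lexicographically first member)
  sig <- vapply(sets, paste, character(1), collapse = "\r")
  merged <- split(names(sets), sig)
  mrep <- vapply(merged, function(m) sort(m)[1], character(1))
  rep_sets <- lapply(merged, function(m) sets[[m[1]]])
  ord <- order(-lengths(rep_sets), mrep)
  merged <- merged[ord]; mrep <- mrep[ord]; rep_sets <- rep_sets[ord]
  # subsume strict subsets into the first (largest) containing group
  host <- rep(NA_integer_, length(mrep))
  for (i in seq_along(mrep)) {
    for (j in seq_len(i - 1L)) {
      if (!is.na(host[j])) next
      if (all(rep_sets[[i]] %in% rep_sets[[j]])) { host[i] <- j; break }
    }
  }
  keep <- which(is.na(host))
  groups <- lapply(keep, function(j) {
    members <- unlist(merged[c(j, which(host == j))], use.names = FALSE)
    list(anchor = mrep[j], members = sort(unique(members)),
         peptides = rep_sets[[j]])
  })
  # greedy peptide assignment: groups already ordered by (-size, anchor)
  pep2grp <- integer(0)
  for (gi in seq_along(groups)) {
    new <- setdiff(groups[[gi]]$peptides, names(pep2grp))
    pep2grp[new] <- gi
  }
  counts <- stats::setNames(evidence$psm_count, evidence$peptide)
  out <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    assigned <- names(pep2grp)[pep2grp == gi]
    uniq <- g$peptides[vapply(g$peptides, function(p) {
      sum(vapply(groups, function(h) p %in% h$peptides, logical(1))) == 1L
    }, logical(1))]
    data.frame(group_id = paste0("PG", gi), anchor = g$anchor,
               spectral_count = sum(counts[assigned]),
               n_unique_peptides = length(uniq), stringsAsFactors = FALSE)
  }))
  out$members <- lapply(groups, `[[`, "members")
  out$peptides <- lapply(groups, `[[`, "peptides")
  out$assigned_peptides <- lapply(seq_along(groups), function(gi)
    names(pep2grp)[pep2grp == gi])
  out$unique_peptides <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    g$peptides[vapply(g$peptides, function(p)
      sum(vapply(groups, function(h) p %in% h$peptides, logical(1))) == 1L,
      logical(1))]
  })
  rownames(out) <- NULL
  out
}

#' Coverage and counting statistics per protein group
#'
#' Coverage is the fraction of the anchor sequence covered by the union of
#' its peptides' intervals (all occurrences of each peptide).
#'
#' @param groups Output of [group_proteins()].
#' @param evidence Output of [assign_peptides()].
#' @param db The `protegap_db`.
#' @return Data frame: `group_id`, `coverage`, `n_unique_peptides`,
#'   `psm_count`.
#' @export
coverage_stats <- function(groups, evidence, db) {
  counts <- stats::setNames(evidence$psm_count, evidence$peptide)
  res <- lapply(seq_len(nrow(groups)), function(gi) {
    anchor_seq <- db$entries$sequence[db$entries$entry_id == groups$anchor[gi]]
    peps <- groups$peptides[[gi]]
    ivs <- do.call(rbind, lapply(peps, function(p) {
      m <- gregexpr(p, anchor_seq, fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      cbind(as.integer(m), as.integer(m) + nchar(p) - 1L)
    }))
    cov <- if (is.null(ivs)) 0 else {
      r <- IRanges::reduce(IRanges::IRanges(start = ivs[, 1], end = ivs[, 2]))
      sum(IRanges::width(r)) / nchar(anchor_seq)
    }
    data.frame(group_id = groups$group_id[gi], coverage = cov,
               n_unique_peptides = length(groups$unique_peptides[[gi]]),
               psm_count = sum(counts[groups$assigned_peptides[[gi]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Map peptide evidence to genomic coordinates
#'
#' Six-frame parents map by offsetting the entry's genomic interval by 3
#' nucleotides per residue (strand-aware). Reference parents are projected
#' splice-aware through the gene model's CDS segments, possibly yielding
#' several intervals across junctions. Transcript-frame and
#' contaminant-only matches are skipped.
#'
#' @param evidence Output of [assign_peptides()].
#' @param index The [build_peptide_index()].
#' @param db The `protegap_db`.
#' @param gm Optional [gene_models()] (required for reference mapping).
#' @param genome Optional named contig vector (required for minus-strand
#'   reference projection; supplies contig lengths).
#' @return Data frame: `peptide`, `entry_id`, `origin`, `contig`,
#'   `strand`, `frame` (signed, `NA` for spliced reference), `start`,
#'   `end`, `block`, `n_blocks`, `uniqueness`.
#' @export
map_peptide_to_genome <- function(evidence, index, db, gm = NULL,
                                  genome = NULL) {
  empty <- data.frame(peptide = character(), entry_id = character(),
                      origin = character(), contig = character(),
                      strand = character(), frame = integer(),
                      start = integer(), end = integer(), block = integer(),
                      n_blocks = integer(), uniqueness = character())
  if (nrow(evidence) == 0) return(empty)
  ev <- evidence[!evidence$contaminant_only, , drop = FALSE]
  par <- index$parents
  e <- db$entries
  out <- list()
  for (i in seq_len(nrow(ev))) {
    p <- ev$peptide[i]
    plen <- nchar(p)
    pp <- par[par$peptide == p & par$origin %in% c("six_frame", "reference"), ,
              drop = FALSE]
    pp <- pp[!duplicated(paste(pp$entry_id, pp$start)), , drop = FALSE]
    for (k in seq_len(nrow(pp))) {
      ent <- e[e$entry_id == pp$entry_id[k], ]
      if (ent$origin == "six_frame") {
        off <- 3L * pp$start[k]
        if (ent$strand == "+") {
          gs <- ent$start + off; ge <- gs + 3L * plen
        } else {
          ge <- ent$end - off; gs <- ge - 3L * plen
        }
        out[[length(out) + 1L]] <- data.frame(
          peptide = p, entry_id = ent$entry_id, origin = "six_frame",
          contig = ent$contig, strand = ent$strand, frame = ent$frame,
          start = gs, end = ge, block = 1L, n_blocks = 1L,
          uniqueness = ev$uniqueness[i], stringsAsFactors = FALSE)
      } else if (ent$origin == "reference") {
        if (is.null(gm) || !(ent$entry_id %in% gm$genes$gene_id)) {
          warning("no gene model for reference entry ", ent$entry_id,
                  "; mapping skipped")
          next
        }
        gi <- gm$genes[gm$genes$gene_id == ent$entry_id, ]
        clen <- if (!is.null(genome)) nchar(genome[[gi$contig]]) else NA
        if (gi$strand == "-" && is.na(clen)) {
          warning("genome required for minus-strand projection; skipped")
          next
        }
        iv <- .cds_to_genomic(gm, ent$entry_id, 3L * pp$start[k],
                              3L * (pp$start[k] + plen),
                              if (is.na(clen)) 0L else clen)
        if (is.null(iv)) next
        iv <- iv[order(iv$start), , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          peptide = p, entry_id = ent$entry_id, origin = "reference",
          contig = gi$contig, strand = gi$strand, frame = NA_integer_,
          start = iv$start, end = iv$end, block = seq_len(nrow(iv)),
          n_blocks = nrow(iv), uniqueness = ev$uniqueness[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract and translate a genomic mapping (round-trip check)
#'
#' @param genome Named contig vector.
#' @param contig,strand Contig id and strand of the mapping.
#' @param intervals Data frame with `start`, `end` (forward coordinates,
#'   ascending).
#' @param code A [genetic_code()] object.
#' @return The translated peptide encoded by the mapping.
#' @export
translate_mapping <- function(genome, contig, strand, intervals,
                              code = genetic_code()) {
  s <- paste(substring(genome[[contig]], intervals$start + 1L,
                       intervals$end), collapse = "")
  if (strand == "-") s <- reverse_complement(s)
  translate_dna(s, code)
}

#' Write genomic mappings as BED (0-based half-open)
#'
#' @param mappings Output of [map_peptide_to_genome()].
#' @param path Output path.
#' @export
write_bed <- function(mappings, path) {
  bed <- data.frame(mappings$contig, mappings$start, mappings$end,
                    mappings$peptide, 0L, mappings$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peptide evidence and protein groups as TSV
#'
#' List columns are flattened to semicolon-separated fields.
#'
#' @param evidence Output of [assign_peptides()].
#' @param groups Output of [group_proteins()].
#' @param path Output path.
#' @export
write_evidence_tsv <- function(evidence, path) {
  ev <- evidence
  ev$matched_entries <- vapply(ev$matched_entries, paste, character(1),
                               collapse = ";")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_tsv
#' @export
write_groups_tsv <- function(groups, path) {
  g <- groups
  for (col in c("members", "peptides", "assigned_peptides",
                "unique_peptides")) {
    g[[col]] <- vapply(g[[col]], paste, character(1), collapse = ";")
  }
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
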