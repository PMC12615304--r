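#' Normalized spectral abundance factor (NSAF)
#'
#' `NSAF_k = (SpC_k / L_k) / sum_j (SpC_j / L_j)` per state column.
#' Columns with zero total spectral count are left at zero and flagged in
#' the `"zero_states"` attribute rather than divided.
#'
#' @param spectral_counts Matrix of spectral counts, entities x states.
#' @param lengths Per-entity protein lengths in residues (> 0).
#' @return NSAF matrix (each non-flagged column sums to 1).
#' @export
nsaf <- function(spectral_counts, lengths) {
  m <- as.matrix(spectral_counts)
  stopifnot(length(lengths) == nrow(m), all(lengths > 0), all(m >= 0))
  saf <- m / lengths
  tot <- colSums(saf)
  zero <- tot == 0
  out <- saf
  out[, !zero] <- sweep(saf[, !zero, drop = FALSE], 2, tot[!zero], "/")
  attr(out, "zero_states") <- colnames(m)[zero]
  out
}

#' Fragments per kilobase of exon per million mapped fragments (FPKM)
#'
#' `FPKM = count * 1e9 / (length_bp * total_mapped)` per state column.
#'
#' @param counts Matrix of fragment counts, entities x states.
#' @param exon_lengths_bp Per-entity summed exon lengths in bp (> 0).
#' @param total_mapped Per-state library sizes; defaults to column sums.
#' @return FPKM matrix.
#' @export
fpkm <- function(counts, exon_lengths_bp, total_mapped = colSums(counts)) {
  m <- as.matrix(counts)
  stopifnot(length(exon_lengths_bp) == nrow(m), all(exon_lengths_bp > 0))
  if (any(total_mapped <= 0)) {
    stop("total_mapped must be positive for every state", call. = FALSE)
  }
  sweep(m * 1e9 / exon_lengths_bp, 2, total_mapped, "/")
}

#' Row-wise Z-score normalization
#'
#' `(x - mean) / sd` per row with the sample (n-1) standard deviation.
#' Constant rows become all-zero and are flagged in the
#' `"constant_rows"` attribute.
#'
#' @param m Matrix with at least 2 columns.
#' @return Z-scored matrix.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  const <- sd == 0 | is.na(sd)
  z <- (m - mu) / ifelse(const, 1, sd)
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

#' State-specific high-expression calls
#'
#' An entity is specific to a state when its z-score is strictly greater
#' than `hi` in exactly that one state and strictly less than `lo` in
#' every other state.
#'
#' @param z Z-scored matrix (entities x states).
#' @param hi,lo Thresholds (defaults 2 and 0).
#' @return Data frame: `entity_id`, `specific_state` (`NA` when not
#'   specific).
#' @export
state_specific <- function(z, hi = 2, lo = 0) {
  z <- as.matrix(z)
  states <- colnames(z)
  if (is.null(states)) states <- paste0("state", seq_len(ncol(z)))
  call1 <- apply(z, 1, function(x) {
    above <- which(x > hi)
    if (length(above) == 1 && all(x[-above] < lo)) states[above]
    else NA_character_
  })
  data.frame(entity_id = if (is.null(rownames(z)))
    as.character(seq_len(nrow(z))) else rownames(z),
    specific_state = unname(call1), stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that returns `NA` (reported missing)
#' for constant input rather than erroring.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-state correlation between transcript and protein abundance
#'
#' Restricts to entities quantified in both matrices, applies the
#' configured transform (log2 with a small offset by default: 1 for FPKM,
#' half the minimum positive value for NSAF), and computes the Pearson
#' correlation per paired state.
#'
#' @param fpkm_matrix FPKM matrix (entities x transcriptome states).
#' @param nsaf_matrix NSAF matrix (entities x proteome states).
#' @param state_pairing Named character vector mapping proteome state ->
#'   transcriptome state; defaults to identically named columns.
#' @param transform `"log2_offset"` (default) or `"none"`.
#' @param min_shared Minimum shared entities per state (default 3; states
#'   below it are reported `NA`).
#' @return Data frame: `state`, `r`, `n`.
#' @export
correlate_omics <- function(fpkm_matrix, nsaf_matrix, state_pairing = NULL,
                            transform = c("log2_offset", "none"),
                            min_shared = 3) {
  transform <- match.arg(transform)
  shared <- intersect(rownames(fpkm_matrix), rownames(nsaf_matrix))
  if (is.null(state_pairing)) {
    st <- intersect(colnames(nsaf_matrix), colnames(fpkm_matrix))
    state_pairing <- stats::setNames(st, st)
  }
  tx <- function(m, offset) {
    if (transform == "none") m else log2(m + offset)
  }
  res <- lapply(names(state_pairing), function(ps) {
    xs <- fpkm_matrix[shared, state_pairing[[ps]]]
    ys <- nsaf_matrix[shared, ps]
    ok <- !is.na(xs) & !is.na(ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < min_shared) {
      return(data.frame(state = ps, r = NA_real_, n = length(xs)))
    }
    pos <- ys[ys > 0]
    off_n <- if (length(pos)) min(pos) / 2 else 1
    data.frame(state = ps, r = pearson_r(tx(xs, 1), tx(ys, off_n)),
               n = length(xs), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Spectral-count matrix from accepted PSMs per state
#'
#' Counts accepted PSMs per protein group and state, with shared peptides
#' assigned to their anchor group only (count conservation: totals equal
#' the accepted PSM count).
#'
#' @param accepted_psms Accepted PSMs carrying a `state` column.
#' @param groups [group_proteins()] output.
#' @param states State order for the columns.
#' @return Matrix groups x states of spectral counts (rownames = anchor
#'   entry ids).
#' @export
spectral_count_matrix <- function(accepted_psms, groups,
                                  states = sort(unique(accepted_psms$state))) {
  m <- matrix(0L, nrow = nrow(groups), ncol = length(states),
              dimnames = list(groups$anchor, states))
  pep2grp <- stats::setNames(
    rep(seq_len(nrow(groups)), lengths(groups$assigned_peptides)),
    unlist(groups$assigned_peptides))
  hit <- accepted_psms$peptide %in% names(pep2grp)
  p <- accepted_psms[hit, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    gi <- pep2grp[[p$peptide[i]]]
    si <- match(p$state[i], states)
    m[gi, si] <- m[gi, si] + 1L
  }
  m
}
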