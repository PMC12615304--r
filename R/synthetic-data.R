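#' Configuration for the synthetic proteogenome
#'
#' Defines the study conditions the generator emulates: an AT-rich
#' ciliate-style genome with annotated (partly mis-annotated) genes,
#' hidden unannotated genes, tryptic peptides observed as noisy fragment
#' spectra with optional modification mass shifts, and per-state RNA
#' counts correlated with protein abundance across ten life-cycle states.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param n_contigs Number of contigs (default 2).
#' @param n_annotated_genes Annotated genes, including the error genes
#'   (default 50).
#' @param n_hidden_genes Genes present in the genome but absent from the
#'   annotation (default 5).
#' @param n_error_genes Named counts of injected annotation errors
#'   (`start`, `stop`, `intron_boundary`, `intron_coding`).
#' @param at_fraction Genomic AT fraction (default 0.75).
#' @param hidden_gc_boost Additional GC fraction for hidden-gene CDS
#'   (default 0.08), giving novel CDS slightly higher GC than annotated.
#' @param intron_rate Probability that a clean annotated gene carries
#'   real introns (default 0.4; 1 or 2 introns of 50-120 nt).
#' @param cds_codon_range,hidden_codon_range Codon-count ranges for
#'   annotated and hidden CDS (hidden genes are shorter).
#' @param intergenic_range Spacer length range in nt.
#' @param peptide_sampling_depth Peptide spectra sampled per state
#'   (default 200).
#' @param n_noise_spectra Spectra of random peaks with no generating
#'   peptide (default 1000).
#' @param ptm_rates Named per-type modification probabilities applied to
#'   sampled peptides carrying a compatible residue.
#' @param noise_peaks Uniform noise peaks added per peptide spectrum
#'   (default 8).
#' @param mass_error_ppm Gaussian m/z error applied to every peak and
#'   precursor (default 5 ppm).
#' @param n_states Number of states (default 10).
#' @param state_names State labels (defaults to the ten life-cycle states
#'   G, S3, S15, C2, C12, C18, 3A1-27G/S, 3A1-80G/S).
#' @param mrna_protein_correlation Target log-scale correlation between
#'   true mRNA and protein levels per state (default 0.5).
#' @param abundance_sdlog Log-normal spread of true levels (default 1.2).
#' @param nb_dispersion Negative-binomial dispersion for counts (default
#'   0.1).
#' @param rnaseq_depth_factor Scales expected RNA fragment counts
#'   (default 200 per kb at median expression; deep enough that count
#'   noise attenuates log-scale correlations by well under 0.1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_contigs = 2, n_annotated_genes = 50,
                       n_hidden_genes = 5,
                       n_error_genes = c(start = 3, stop = 3,
                                         intron_boundary = 3,
                                         intron_coding = 2),
                       at_fraction = 0.75, hidden_gc_boost = 0.08,
                       intron_rate = 0.4, cds_codon_range = c(90, 200),
                       hidden_codon_range = c(40, 90),
                       intergenic_range = c(150, 400),
                       peptide_sampling_depth = 200,
                       n_noise_spectra = 1000,
                       ptm_rates = c(Phospho = 0.04, Acetyl = 0.04,
                                     Trimethyl = 0.03, Oxidation = 0.03,
                                     GlyGly = 0.02),
                       noise_peaks = 8, mass_error_ppm = 5,
                       n_states = 10,
                       state_names = c("G", "S3", "S15", "C2", "C12",
                                       "C18", "3A1-27G", "3A1-27S",
                                       "3A1-80G", "3A1-80S"),
                       mrna_protein_correlation = 0.5,
                       abundance_sdlog = 1.2, nb_dispersion = 0.1,
                       rnaseq_depth_factor = 200) {
  stopifnot(at_fraction > 0, at_fraction < 1, n_annotated_genes >= sum(n_error_genes),
            n_states == length(state_names),
            mrna_protein_correlation >= 0, mrna_protein_correlation <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.rand_bases <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

.random_dna <- function(n, at) paste(.rand_bases(n, at), collapse = "")

# n random non-stop codons at the given AT fraction
.random_codons <- function(n, at, code) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    b <- matrix(.rand_bases(3L * length(need), at), ncol = 3)
    cs <- paste0(b[, 1], b[, 2], b[, 3])
    ok <- !(cs %in% code$stop_codons)
    out[need[ok]] <- cs[ok]
    need <- need[!ok]
  }
  out
}

# CDS string including the ATG start and the TGA stop
.random_cds <- function(n_codons, at, code) {
  paste0("ATG", paste(.random_codons(n_codons - 1L, at, code), collapse = ""),
         "TGA")
}

.flip_rel <- function(iv, L) cbind(L - iv[, 2], L - iv[, 1])

# Build one gene block. Returns the forward-strand block string, the
# forward-relative true CDS interval (incl. stop), forward-relative
# annotated exon intervals (NULL for hidden genes), and metadata.
.make_gene <- function(gid, type, strand, config, code) {
  at <- config$at_fraction
  if (type == "hidden") {
    nc <- sample(config$hidden_codon_range[1]:config$hidden_codon_range[2], 1)
    cds <- .random_cds(nc, at - config$hidden_gc_boost, code)
    glen <- nchar(cds)
    # planted in-frame stop immediately upstream of the ATG
    if (strand == "+") {
      block <- paste0("TGA", cds)
      true_iv <- c(3L, 3L + glen)
    } else {
      block <- paste0(reverse_complement(cds), "TCA")
      true_iv <- c(0L, glen)
    }
    return(list(block = block, true_iv = true_iv, exons = NULL,
                protein = sub("\\*$", "", translate_dna(cds, code)),
                type = type, error = NA_character_))
  }
  nc <- sample(config$cds_codon_range[1]:config$cds_codon_range[2], 1)
  cds <- .random_cds(nc, at, code)
  clen <- nchar(cds)  # 3 * (nc + 1), incl. stop
  error <- if (type %in% c("start", "stop", "intron_boundary",
                           "intron_coding")) type else NA_character_
  # oriented gene sequence + oriented annotated exon intervals
  if (is.na(error) && stats::runif(1) < config$intron_rate) {
    n_int <- sample(1:2, 1)
    offs <- sort(sample(seq(3L, clen - 6L, by = 3L), n_int))
    pieces <- character(0)
    exons <- NULL
    cur <- 0L; gpos <- 0L
    for (o in offs) {
      exons <- rbind(exons, c(gpos, gpos + (o - cur)))
      pieces <- c(pieces, substring(cds, cur + 1L, o))
      gpos <- gpos + (o - cur)
      ilen <- sample(50:120, 1)
      pieces <- c(pieces,
                  paste0("GT", .random_dna(ilen - 4L, at), "AG"))
      gpos <- gpos + ilen
      cur <- o
    }
    exons <- rbind(exons, c(gpos, gpos + (clen - cur)))
    pieces <- c(pieces, substring(cds, cur + 1L, clen))
    oseq <- paste(pieces, collapse = "")
    oex <- exons
  } else {
    oseq <- cds
    oex <- rbind(c(0L, clen))
    if (!is.na(error)) {
      if (error == "start") {
        k <- sample(5:10, 1)
        oex <- rbind(c(3L * k, clen))
      } else if (error == "stop") {
        k <- sample(5:10, 1)
        oex <- rbind(c(0L, clen - 3L * (k + 1L)))
      } else {
        b <- if (error == "intron_boundary") 8L else 24L  # fake intron codons
        a <- sample(seq(10L, nc - b - 10L), 1)            # codon offset
        oex <- rbind(c(0L, 3L * a), c(3L * (a + b), clen))
      }
    }
  }
  glen <- nchar(oseq)
  if (strand == "+") {
    block <- oseq
    true_iv <- c(0L, glen)
    fex <- oex
  } else {
    block <- reverse_complement(oseq)
    true_iv <- c(0L, glen)
    fex <- .flip_rel(oex, glen)
  }
  list(block = block, true_iv = true_iv, exons = fex,
       protein = sub("\\*$", "", translate_dna(cds, code)),
       type = if (is.na(error)) "annotated" else paste0("error_", error),
       error = error)
}

#' Generate the synthetic genome, annotation and ground-truth ledger
#'
#' Lays out annotated genes (a configured subset with corrupted GFF3
#' records per error category while the genome retains the true CDS),
#' hidden genes absent from the annotation, and AT-rich intergenic
#' spacers. Hidden genes carry an in-frame stop immediately upstream of
#' their start codon so the true ORF is the unique recoverable answer.
#' Per-state true mRNA and protein levels are drawn as correlated
#' log-normals at the configured target correlation. Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return A `protegap_sim` list: `genome` (named contigs), `annotation`
#'   ([gene_models()] of the *annotated* records), `transcripts` (spliced
#'   true CDS per gene), `code`, `config`, and `truth` (ledger with
#'   `genes`, `errors`, `abundance`).
#' @export
generate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  code <- genetic_code("ciliate")
  nerr <- config$n_error_genes
  types <- c(rep(names(nerr), nerr),
             rep("annotated", config$n_annotated_genes - sum(nerr)))
  types <- sample(types)  # shuffle error genes among annotated positions
  all_types <- sample(c(types, rep("hidden", config$n_hidden_genes)))
  ids <- sprintf("g%04d", seq_along(all_types))
  ids[all_types == "hidden"] <- sprintf("hidden%02d",
                                        seq_len(sum(all_types == "hidden")))
  strands <- sample(c("+", "-"), length(all_types), replace = TRUE)
  contig_of <- rep_len(sprintf("ctg%d", seq_len(config$n_contigs)),
                       length(all_types))
  genes <- vector("list", length(all_types))
  for (i in seq_along(all_types)) {
    genes[[i]] <- .make_gene(ids[i], all_types[i], strands[i], config, code)
  }
  contigs <- stats::setNames(vector("list", config$n_contigs),
                             sprintf("ctg%d", seq_len(config$n_contigs)))
  ledger <- list()
  exon_rows <- list()
  for (ctg in names(contigs)) {
    pieces <- character(0)
    pos <- 0L
    for (i in which(contig_of == ctg)) {
      sp <- .random_dna(sample(config$intergenic_range[1]:
                                 config$intergenic_range[2], 1),
                        config$at_fraction)
      pieces <- c(pieces, sp)
      pos <- pos + nchar(sp)
      g <- genes[[i]]
      ledger[[length(ledger) + 1L]] <- data.frame(
        gene_id = ids[i], type = g$type, contig = ctg, strand = strands[i],
        cds_start = pos + g$true_iv[1], cds_end = pos + g$true_iv[2],
        protein = g$protein, error = g$error,
        gc = gc_content(substring(g$block, g$true_iv[1] + 1L, g$true_iv[2])),
        stringsAsFactors = FALSE)
      if (!is.null(g$exons)) {
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene_id = ids[i], contig = ctg, strand = strands[i],
          start = pos + g$exons[, 1], end = pos + g$exons[, 2],
          stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, g$block)
      pos <- pos + nchar(g$block)
    }
    pieces <- c(pieces, .random_dna(sample(config$intergenic_range[1]:
                                             config$intergenic_range[2], 1),
                                    config$at_fraction))
    contigs[[ctg]] <- paste(pieces, collapse = "")
  }
  truth_genes <- do.call(rbind, ledger)
  exons <- do.call(rbind, exon_rows)
  annotated <- truth_genes[truth_genes$type != "hidden", ]
  gm <- gene_models(
    genes = data.frame(gene_id = annotated$gene_id,
                       contig = annotated$contig,
                       strand = annotated$strand, stringsAsFactors = FALSE),
    exons = exons)
  # transcripts: spliced true CDS, sense orientation, for every true gene.
  # Error genes are truly contiguous (their annotated introns/boundaries are
  # the corruption), so only correctly annotated multi-exon genes splice.
  tx <- vapply(seq_len(nrow(truth_genes)), function(i) {
    s <- substring(contigs[[truth_genes$contig[i]]],
                   truth_genes$cds_start[i] + 1L, truth_genes$cds_end[i])
    if (truth_genes$strand[i] == "-") s <- reverse_complement(s)
    s
  }, character(1))
  has_intron <- truth_genes$type == "annotated" &
    truth_genes$gene_id %in% names(which(table(exons$gene_id) > 1))
  for (i in which(has_intron)) {
    e <- exons[exons$gene_id == truth_genes$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), ]
    s <- paste(substring(contigs[[truth_genes$contig[i]]], e$start + 1L,
                         e$end), collapse = "")
    if (truth_genes$strand[i] == "-") s <- reverse_complement(s)
    tx[i] <- s
  }
  names(tx) <- paste0("tx_", truth_genes$gene_id)
  errors <- truth_genes[!is.na(truth_genes$error),
                        c("gene_id", "error", "contig", "strand")]
  names(errors)[2] <- "category"
  ab <- .simulate_abundance(nrow(truth_genes), config)
  rownames(ab$mrna) <- rownames(ab$protein) <- truth_genes$gene_id
  structure(list(
    genome = vapply(contigs, identity, character(1)),
    annotation = gm, transcripts = tx, code = code, config = config,
    truth = list(genes = truth_genes, errors = errors, abundance = ab)),
    class = "protegap_sim")
}

# Correlated log-normal true levels, one independent draw per state.
# The second coordinate is orthogonalized against the first in-sample, so
# the log-scale sample correlation equals the target exactly in every
# state; deviations measured downstream are then count noise only.
.simulate_abundance <- function(n_genes, config) {
  rho <- config$mrna_protein_correlation
  sdl <- config$abundance_sdlog
  m <- p <- matrix(0, n_genes, config$n_states,
                   dimnames = list(NULL, config$state_names))
  for (s in seq_len(config$n_states)) {
    z <- stats::rnorm(n_genes)
    e <- stats::rnorm(n_genes)
    if (n_genes >= 3) {
      z <- drop(scale(z))
      e <- e - mean(e) - z * sum(z * (e - mean(e))) / sum(z^2)
      e <- e / sqrt(sum(e^2) / (n_genes - 1))
    }
    m[, s] <- exp(sdl * z)
    p[, s] <- exp(sdl * (rho * z + sqrt(1 - rho^2) * e))
  }
  list(mrna = m, protein = p)
}

#' @export
print.protegap_sim <- function(x, ...) {
  cat("<protegap_sim>", length(x$genome), "contigs (",
      sum(nchar(x$genome)), "nt ),", nrow(x$truth$genes), "true genes (",
      sum(x$truth$genes$type == "hidden"), "hidden )\n")
  invisible(x)
}

#' Simulate fragment spectra from the true proteome
#'
#' Samples tryptic peptides per state proportional to true protein
#' abundance (and peptide count), emits each as a b/y-ladder spectrum
#' with randomized intensities, Gaussian ppm mass errors, configured
#' modification mass shifts at ledger-recorded sites, uniform noise
#' peaks, and precursor charges in 2-4; appends noise-only spectra with
#' no generating peptide. Deterministic under the config seed.
#'
#' @param sim A `protegap_sim` from [generate_genome()].
#' @param catalog Modification catalog used for planted shifts (default
#'   [ptm_catalog()]).
#' @return `sim` with `spectra` (list) and `truth$spectra` (ledger data
#'   frame: `spectrum_id`, `state`, `gene`, `peptide`, `mod_type`,
#'   `site`, `charge`) added.
#' @export
simulate_spectra <- function(sim, catalog = ptm_catalog()) {
  config <- sim$config
  set.seed(config$seed + 1L)
  constants <- mass_constants()
  tg <- sim$truth$genes
  pool <- do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
    d <- digest(tg$protein[i], max_missed = 1, min_len = 6, max_len = 30)
    d <- d[d$matchable, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(gene = tg$gene_id[i], peptide = d$peptide,
               stringsAsFactors = FALSE)
  }))
  prot <- sim$truth$abundance$protein
  rates <- config$ptm_rates
  cat_idx <- match(names(rates), catalog$name)
  if (anyNA(cat_idx)) stop("ptm_rates name not in catalog", call. = FALSE)
  spectra <- list()
  truth <- list()
  for (s in seq_len(config$n_states)) {
    state <- config$state_names[s]
    w <- prot[pool$gene, s]
    rows <- sample.int(nrow(pool), config$peptide_sampling_depth,
                       replace = TRUE, prob = w)
    for (r in rows) {
      pep <- pool$peptide[r]
      mod_type <- NA_character_; mod_mass <- 0; site <- NA_integer_
      u <- stats::runif(length(rates))
      for (t in seq_along(rates)) {
        if (u[t] >= rates[t]) next
        resid <- strsplit(catalog$residues[cat_idx[t]], "")[[1]]
        compat <- which(strsplit(pep, "")[[1]] %in% resid)
        if (length(compat) == 0) next
        mod_type <- names(rates)[t]
        mod_mass <- catalog$mass[cat_idx[t]]
        site <- compat[sample.int(length(compat), 1)] - 1L
        break
      }
      ions <- theoretical_ions(pep, mod_mass, site, constants = constants)
      ppm_err <- stats::rnorm(nrow(ions), 0, config$mass_error_ppm) * 1e-6
      pk_mz <- ions$mz * (1 + ppm_err)
      pk_int <- stats::runif(nrow(ions), 0.3, 1)
      if (config$noise_peaks > 0) {
        pk_mz <- c(pk_mz, stats::runif(config$noise_peaks, 100,
                                       1.05 * max(ions$mz)))
        pk_int <- c(pk_int, stats::runif(config$noise_peaks, 0.02, 0.15))
      }
      o <- order(pk_mz)
      charge <- sample(2:4, 1, prob = c(0.5, 0.35, 0.15))
      neutral <- peptide_mass(pep, mod_mass, constants)
      pmz <- mz(neutral, charge, constants) *
        (1 + stats::rnorm(1, 0, config$mass_error_ppm) * 1e-6)
      sid <- sprintf("%s|%05d", state, length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- list(
        spectrum_id = sid, precursor_mz = pmz, charge = charge,
        peaks = cbind(mz = pk_mz[o], intensity = pk_int[o]))
      truth[[length(truth) + 1L]] <- data.frame(
        spectrum_id = sid, state = state, gene = pool$gene[r],
        peptide = pep, mod_type = mod_type, site = site, charge = charge,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_noise_spectra)) {
    neutral <- stats::runif(1, 800, 2800)
    n_pk <- sample(30:60, 1)
    pk_mz <- sort(stats::runif(n_pk, 150, neutral))
    sid <- sprintf("NOISE|%05d", i)
    spectra[[length(spectra) + 1L]] <- list(
      spectrum_id = sid, precursor_mz = mz(neutral, 2), charge = 2L,
      peaks = cbind(mz = pk_mz, intensity = stats::runif(n_pk, 0.05, 1)))
    truth[[length(truth) + 1L]] <- data.frame(
      spectrum_id = sid, state = "NOISE", gene = NA_character_,
      peptide = NA_character_, mod_type = NA_character_,
      site = NA_integer_, charge = 2L, stringsAsFactors = FALSE)
  }
  sim$spectra <- spectra
  sim$truth$spectra <- do.call(rbind, truth)
  sim
}

#' Simulate per-state RNA-seq fragment counts
#'
#' Counts are drawn negative-binomially around length-scaled true mRNA
#' levels. Deterministic under the config seed.
#'
#' @param sim A `protegap_sim`.
#' @return `sim` with `rna_counts` (genes x states) and `exon_lengths`
#'   added.
#' @export
simulate_rnaseq <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 2L)
  tg <- sim$truth$genes
  len_kb <- (tg$cds_end - tg$cds_start) / 1000
  m <- sim$truth$abundance$mrna
  mu <- m * len_kb * config$rnaseq_depth_factor
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  sim$rna_counts <- counts
  sim$exon_lengths <- stats::setNames(1000 * len_kb, tg$gene_id)
  sim
}

#' Simulate per-state protein spectral counts from true abundance
#'
#' Length-weighted negative-binomial spectral counts around true protein
#' levels, for quantification studies that do not require full spectra.
#'
#' @param sim A `protegap_sim`.
#' @param mean_spc Mean spectral count at median abundance and length
#'   (default 300).
#' @return `sim` with `spc_counts` (genes x states) added.
#' @export
simulate_spectral_counts <- function(sim, mean_spc = 300) {
  config <- sim$config
  set.seed(config$seed + 3L)
  tg <- sim$truth$genes
  len <- nchar(tg$protein)
  p <- sim$truth$abundance$protein
  mu <- p * (len / mean(len)) * mean_spc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  sim$spc_counts <- counts
  sim
}

#' One-call synthetic study
#'
#' Chains [generate_genome()], [simulate_spectra()], [simulate_rnaseq()]
#' and [simulate_spectral_counts()].
#'
#' @param config A [sim_config()].
#' @return A fully populated `protegap_sim`.
#' @export
simulate_proteogenome <- function(config = sim_config()) {
  sim <- generate_genome(config)
  sim <- simulate_spectra(sim)
  sim <- simulate_rnaseq(sim)
  simulate_spectral_counts(sim)
}

#' Synthetic contaminant entries
#'
#' Two fixed synthetic stand-ins for the common proteomic contaminants
#' (trypsin autolysis products, human keratins). The sequences are
#' invented, not the real proteins.
#'
#' @return Named character vector of two synthetic protein sequences.
#' @export
contaminant_proteins <- function() {
  c(CONTAM_synthetic_trypsin = paste0(
      "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEK",
      "AVQVKVKALPDAQFEVVHSLAK"),
    CONTAM_synthetic_keratin = paste0(
      "MSIRVTQKSYKVSTSGPRAFSSRSYTSGPGSRISSSSFSRVGSSNFRGGLGGGYGGASGMGGITAVTVNQSLLSPLVLEVDPNIQAVR"))
}
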