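#' Read an MGF peak list
#'
#' Minimal Mascot Generic Format reader: BEGIN IONS / TITLE / PEPMASS /
#' CHARGE / peak pairs / END IONS. Peaks are sorted by m/z.
#'
#' @param path MGF file path.
#' @return List of spectra; each spectrum is a list with `spectrum_id`,
#'   `precursor_mz`, `charge` and `peaks` (two-column matrix `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF", call. = FALSE)
  spectra <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    pk <- block[!is_kv & nzchar(block)]
    pm <- if (length(pk)) {
      do.call(rbind, lapply(strsplit(pk, "[ \t]+"), function(x)
        as.numeric(x[1:2])))
    } else matrix(numeric(), ncol = 2)
    colnames(pm) <- c("mz", "intensity")
    pm <- pm[order(pm[, 1]), , drop = FALSE]
    charge <- vals[match("CHARGE", keys)]
    spectra[[i]] <- list(
      spectrum_id = if ("TITLE" %in% keys) vals[match("TITLE", keys)]
                    else paste0("spectrum_", i),
      precursor_mz = as.numeric(sub(" .*", "", vals[match("PEPMASS", keys)])),
      charge = as.integer(sub("\\+$", "", charge)),
      peaks = pm
    )
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output file path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.6f %.4f", s$peaks[, 1], s$peaks[, 2]),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Neutral (uncharged) precursor mass of a spectrum
#'
#' @param spectrum One spectrum (list with `precursor_mz`, `charge`).
#' @param constants [mass_constants()] list.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(spectrum, constants = mass_constants()) {
  spectrum$precursor_mz * spectrum$charge -
    spectrum$charge * constants$proton
}
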