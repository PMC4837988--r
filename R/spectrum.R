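#' Construct a centroided mass spectrum
#'
#' @param mz,intensity numeric peak vectors; m/z must be positive,
#'   intensities non-negative. Peaks are stored sorted by m/z.
#' @param polarity `"positive"` or `"negative"`.
#' @param precursor_mz optional precursor m/z for MS/MS spectra.
#' @return object of class `"mass_spectrum"`.
#' @examples
#' mass_spectrum(c(241.217, 152.996), c(100, 40), "negative",
#'               precursor_mz = 1017.577)
#' @export
mass_spectrum <- function(mz, intensity = rep(1, length(mz)),
                          polarity = c("negative", "positive"),
                          precursor_mz = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && (any(!is.finite(mz)) || any(mz <= 0)))
    stop("all m/z values must be positive and finite")
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be non-negative")
  ord <- order(mz)
  structure(list(peaks = data.frame(mz = as.numeric(mz[ord]),
                                    intensity = as.numeric(intensity[ord])),
                 polarity = polarity,
                 precursor_mz = precursor_mz),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass spectrum> ", x$polarity, " mode, ", nrow(x$peaks), " peaks",
      sep = "")
  if (!is.null(x$precursor_mz))
    cat(", precursor m/z ", format(round(x$precursor_mz, 4), nsmall = 4),
        sep = "")
  cat("\n")
  if (nrow(x$peaks)) {
    rng <- range(x$peaks$mz)
    cat("  m/z range ", round(rng[1], 4), " - ", round(rng[2], 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read spectra from an MGF peak list
#'
#' Minimal Mascot-generic-format reader: `BEGIN IONS`/`END IONS` blocks with
#' optional `TITLE`, `PEPMASS` and `CHARGE` headers and whitespace-separated
#' `m/z intensity` rows. Polarity is taken from the sign of `CHARGE`, or
#' from the `polarity` argument when absent.
#'
#' @param path MGF file.
#' @param polarity fallback polarity for blocks without a signed CHARGE.
#' @return list of [mass_spectrum()] objects.
#' @export
read_mgf <- function(path, polarity = "negative") {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  inblock <- FALSE
  mz <- numeric(0); int <- numeric(0); prec <- NULL; pol <- polarity
  for (ln in trimws(lines)) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (identical(ln, "BEGIN IONS")) {
      inblock <- TRUE
      mz <- numeric(0); int <- numeric(0); prec <- NULL; pol <- polarity
    } else if (identical(ln, "END IONS")) {
      spectra[[length(spectra) + 1L]] <-
        mass_spectrum(mz, int, pol, precursor_mz = prec)
      inblock <- FALSE
    } else if (inblock && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") prec <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      if (key == "CHARGE")
        pol <- if (grepl("-", val, fixed = TRUE)) "negative" else "positive"
    } else if (inblock) {
      v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(v) < 1 || anyNA(v[1:min(2, length(v))]))
        stop("malformed peak line in ", path, ": '", ln, "'")
      mz <- c(mz, v[1]); int <- c(int, if (length(v) > 1) v[2] else 1)
    }
  }
  spectra
}

#' Write spectra to an MGF peak list
#'
#' @param spectra a [mass_spectrum()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=spectrum_%d", i), con)
    if (!is.null(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.4f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=1", if (s$polarity == "negative") "-" else "+"),
               con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.4f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a two-column CSV peak list
#'
#' @param path CSV file with columns `mz` and `intensity` (header optional).
#' @param polarity spectrum polarity (CSV carries none).
#' @param precursor_mz optional precursor m/z.
#' @return a [mass_spectrum()].
#' @export
read_peaks_csv <- function(path, polarity = "negative", precursor_mz = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0)   # zero-length file: empty spectrum
    return(mass_spectrum(numeric(0), numeric(0), polarity,
                         precursor_mz = precursor_mz))
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = header)
  if (nrow(df) == 0)
    return(mass_spectrum(numeric(0), numeric(0), polarity,
                         precursor_mz = precursor_mz))
  if (ncol(df) < 2) df[[2]] <- 1
  mass_spectrum(df[[1]], df[[2]], polarity, precursor_mz = precursor_mz)
}

#' Write a two-column CSV peak list
#'
#' @param spectrum a [mass_spectrum()].
#' @param path output CSV, header `mz,intensity`, 4-decimal m/z.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(spectrum, path) {
  df <- data.frame(mz = sprintf("%.4f", spectrum$peaks$mz),
                   intensity = sprintf("%.6g", spectrum$peaks$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
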