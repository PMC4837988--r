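# Diagnostic ions behind the three precursor-ion scans. The sodiated
# dehydrated diglucose (347+) marks dihexose head groups; the cyclic
# (dehydrated) glycerophosphate anion (153-) marks free terminal
# phosphoglycerol; the deprotonated alanine anion (88-) marks ester-linked
# alanine. `classes` lists the lipid classes whose dominant dissociation
# channel releases the ion.
.DIAGNOSTICS <- function() {
  diglc_dehydr <- .comp_sub(condense(.RES_GLUCOSE(), .RES_GLUCOSE()), .WATER)
  cyclo_gp <- .comp_sub(condense(.RES_PHOSPHATE(), .RES_GLYCEROL()), .WATER)
  list(
    dihexose_347 = list(mz = ion_mz(diglc_dehydr, "sodiated_cation"),
                        polarity = "positive", classes = "DAG_anchor"),
    phosphoglycerol_153 = list(mz = ion_mz(cyclo_gp, "deprotonated_anion"),
                               polarity = "negative",
                               classes = c("PG", "LTA_primer")),
    alaninate_88 = list(mz = ion_mz(.RES_ALANINE(), "deprotonated_anion"),
                        polarity = "negative",
                        classes = c("alanyl_PG", "LTA_primer_Ala",
                                    "LTA_primer_Ala2"))
  )
}

#' Diagnostic precursor-scan ions
#'
#' @param name `"dihexose_347"`, `"phosphoglycerol_153"` or
#'   `"alaninate_88"`; omit for all three.
#' @return named numeric vector of theoretical diagnostic m/z values.
#' @examples
#' diagnostic_mz("alaninate_88")
#' @export
diagnostic_mz <- function(name = NULL) {
  d <- .DIAGNOSTICS()
  out <- vapply(d, `[[`, numeric(1), "mz")
  if (is.null(name)) out else out[[match.arg(name, names(d))]]
}

#' Annotate a spectrum against a theoretical catalog
#'
#' Each observed peak is greedily assigned the nearest catalog ion within
#' `tol` (absolute amu); ties are broken by the smaller number of cuts, then
#' lexicographic cleavage label. Unmatched peaks are kept in the report with
#' `matched = FALSE`, never force-assigned.
#'
#' @param spectrum a [mass_spectrum()].
#' @param species a [lipid_species()], shorthand string, or a ready-made
#'   `fragment_catalog`.
#' @param tol matching tolerance in amu (0.005 suits high-accuracy data, 0.3
#'   unit-resolution data).
#' @param max_cuts passed to [enumerate_fragments()] when a species is given.
#' @return `lipid_annotation` data frame: one row per peak, columns
#'   `peak_mz`, `intensity`, `matched`, `mz_calc`, `delta` (observed -
#'   calculated), `cleavage`, `description`, `formula`, `n_cuts`.
#' @examples
#' sp <- mass_spectrum(c(241.2171, 500.0), c(10, 1), "negative")
#' annotate_spectrum(sp, "(30:0) DAG-Glc-Glc-P-Gro", tol = 0.01)
#' @export
annotate_spectrum <- function(spectrum, species, tol = 0.005,
                              max_cuts = NULL) {
  stopifnot(inherits(spectrum, "mass_spectrum"), tol > 0)
  catalog <- if (inherits(species, "fragment_catalog")) species else
    enumerate_fragments(species, polarity = spectrum$polarity,
                        max_cuts = max_cuts)
  if (nrow(catalog) &&
      !identical(attr(catalog, "spec_polarity"), spectrum$polarity))
    stop("catalog polarity does not match the spectrum")
  n <- nrow(spectrum$peaks)
  out <- data.frame(peak_mz = spectrum$peaks$mz,
                    intensity = spectrum$peaks$intensity,
                    matched = logical(n), mz_calc = rep(NA_real_, n),
                    delta = rep(NA_real_, n),
                    cleavage = rep(NA_character_, n),
                    description = rep(NA_character_, n),
                    formula = rep(NA_character_, n),
                    n_cuts = rep(NA_integer_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- abs(catalog$mz - out$peak_mz[i])
    hit <- which(d <= tol)
    if (!length(hit)) next
    hit <- hit[order(d[hit], catalog$n_cuts[hit], catalog$cleavage[hit])][1]
    out$matched[i] <- TRUE
    out$mz_calc[i] <- catalog$mz[hit]
    out$delta[i] <- out$peak_mz[i] - catalog$mz[hit]
    out$cleavage[i] <- catalog$cleavage[hit]
    out$description[i] <- catalog$description[hit]
    out$formula[i] <- catalog$formula[hit]
    out$n_cuts[i] <- catalog$n_cuts[hit]
  }
  structure(out, class = c("lipid_annotation", "data.frame"),
            species = attr(catalog, "species"), tol = tol)
}

#' @export
print.lipid_annotation <- function(x, ...) {
  st <- match_stats(x)
  cat("<annotation> ", attr(x, "species"), ": ", st$n_matched, "/", nrow(x),
      " peaks matched (tol ", attr(x, "tol"), " amu)\n", sep = "")
  if (st$n_matched)
    cat("  max |delta| ", signif(st$max_abs_delta, 3), " amu, mean |delta| ",
        signif(st$mean_abs_delta, 3), " amu\n", sep = "")
  df <- as.data.frame(x)
  df$peak_mz <- round(df$peak_mz, 4); df$mz_calc <- round(df$mz_calc, 4)
  df$delta <- round(df$delta, 4)
  print(head(df[, c("peak_mz", "mz_calc", "delta", "cleavage",
                    "description")], 12))
  invisible(x)
}

#' Summary statistics of an annotation
#'
#' @param annotations a `lipid_annotation` (or any data frame with `matched`
#'   and `delta` columns).
#' @return list with `n_matched`, `max_abs_delta`, `mean_abs_delta` (both 0
#'   when nothing matched).
#' @export
match_stats <- function(annotations) {
  d <- annotations$delta[annotations$matched %in% TRUE]
  list(n_matched = length(d),
       max_abs_delta = if (length(d)) max(abs(d)) else 0,
       mean_abs_delta = if (length(d)) mean(abs(d)) else 0)
}

#' Emulate a precursor-ion scan over a set of MS/MS spectra
#'
#' Reports, for each precursor, the intensity of the diagnostic fragment if
#' the spectrum contains a peak within `tol` of `diagnostic_mz` - the
#' software equivalent of a precursor-ion-scan trace.
#'
#' @param msms_set list of [mass_spectrum()] objects, each with its
#'   `precursor_mz` set; all must share one polarity.
#' @param diagnostic_mz diagnostic fragment m/z (amu), or one of the names
#'   accepted by [diagnostic_mz()].
#' @param tol matching tolerance in amu.
#' @return data frame `precursor_mz`, `diagnostic_mz` (observed), `intensity`
#'   with one row per precursor whose spectrum shows the ion.
#' @export
precursor_scan <- function(msms_set, diagnostic_mz, tol = 0.005) {
  if (inherits(msms_set, "mass_spectrum")) msms_set <- list(msms_set)
  if (is.character(diagnostic_mz))
    diagnostic_mz <- ltafrag::diagnostic_mz(diagnostic_mz)
  pols <- unique(vapply(msms_set, `[[`, character(1), "polarity"))
  if (length(pols) > 1) stop("all spectra in a scan must share polarity")
  rows <- lapply(msms_set, function(s) {
    if (is.null(s$precursor_mz))
      stop("every spectrum in a precursor scan needs precursor_mz")
    d <- abs(s$peaks$mz - diagnostic_mz)
    hit <- which(d <= tol)
    if (!length(hit)) return(NULL)
    hit <- hit[which.max(s$peaks$intensity[hit])]
    data.frame(precursor_mz = s$precursor_mz,
               diagnostic_mz = s$peaks$mz[hit],
               intensity = s$peaks$intensity[hit])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(precursor_mz = numeric(0), diagnostic_mz = numeric(0),
               intensity = numeric(0))
  out[order(out$precursor_mz), , drop = FALSE]
}

#' Nominate lipid species from a precursor m/z and diagnostic ion
#'
#' Searches the lipid classes whose dominant fragmentation releases the
#' given diagnostic ion, over acyl sum compositions (default total carbons
#' 24-40, double bonds 0-4, covering the odd-chain B. subtilis acyls), for
#' species whose theoretical precursor m/z matches within `tol`; candidates
#' are ranked by absolute mass deviation.
#'
#' @param precursor_mz observed precursor m/z (amu).
#' @param diagnostic `"dihexose_347"`, `"phosphoglycerol_153"` or
#'   `"alaninate_88"`.
#' @param tol precursor tolerance in amu.
#' @param carbons,double_bonds acyl sum-composition search grid.
#' @return data frame `species` (shorthand), `class`, `carbons`,
#'   `double_bonds`, `mz_calc`, `delta`, ranked by `abs(delta)`; zero rows
#'   when nothing matches.
#' @examples
#' nominate_species(1017.58, "phosphoglycerol_153", tol = 0.02)
#' @export
nominate_species <- function(precursor_mz,
                             diagnostic = c("dihexose_347",
                                            "phosphoglycerol_153",
                                            "alaninate_88"),
                             tol = 0.02, carbons = 24:40,
                             double_bonds = 0:4) {
  diagnostic <- match.arg(diagnostic)
  stopifnot(tol > 0)
  classes <- .DIAGNOSTICS()[[diagnostic]]$classes
  grid <- expand.grid(class = classes, carbons = carbons,
                      double_bonds = double_bonds,
                      stringsAsFactors = FALSE)
  grid$mz_calc <- NA_real_
  grid$species <- NA_character_
  for (i in seq_len(nrow(grid))) {
    sp <- lipid_species(grid$class[i], grid$carbons[i], grid$double_bonds[i])
    grid$mz_calc[i] <- ion_mz(species_formula(sp), .default_adduct(sp))
    grid$species[i] <- format_species(sp)
  }
  grid$delta <- grid$mz_calc - precursor_mz
  grid <- grid[abs(grid$delta) <= tol, , drop = FALSE]
  grid <- grid[order(abs(grid$delta)), , drop = FALSE]
  rownames(grid) <- NULL
  grid[, c("species", "class", "carbons", "double_bonds", "mz_calc", "delta")]
}

#' Export an annotation report as TSV
#'
#' Mirrors the layout of the fragment tables: observed, calculated,
#' cleavage, description, signed deviation; row order follows the input
#' peaks.
#'
#' @param annotation a `lipid_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  out <- data.frame(observed = sprintf("%.4f", df$peak_mz),
                    calculated = ifelse(df$matched,
                                        sprintf("%.4f", df$mz_calc), ""),
                    cleavage = ifelse(df$matched, df$cleavage, ""),
                    description = ifelse(df$matched, df$description,
                                         "unmatched"),
                    delta = ifelse(df$matched, sprintf("%.4f", df$delta), ""))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
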