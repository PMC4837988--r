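# Seed handling: run `expr` under a deterministic RNG state without
# disturbing the caller's stream. A NULL seed uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Instrument noise model for simulated spectra
#'
#' @param mz_error_sd per-peak Gaussian m/z error, amu. The presets are
#'   `"qtof"` (5e-4 amu, high-accuracy) and `"qtrap"` (0.2 amu,
#'   unit-resolution); pass one of these strings as `preset` instead of
#'   numbers.
#' @param n_noise_peaks background peaks drawn uniformly over the scan
#'   range.
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of signal
#'   peak intensities (arbitrary units).
#' @param noise_intensity_max background intensities are uniform on
#'   (0, `noise_intensity_max`].
#' @param seed integer seed making every simulation reproducible; NULL uses
#'   the session RNG stream.
#' @param preset optional `"qtof"` or `"qtrap"` shortcut for `mz_error_sd`.
#' @return list of class `"noise_model"`.
#' @examples
#' noise_model(preset = "qtof", n_noise_peaks = 50, seed = 1)
#' @export
noise_model <- function(mz_error_sd = 5e-4, n_noise_peaks = 0L,
                        intensity_meanlog = log(1000),
                        intensity_sdlog = 0.6, noise_intensity_max = 50,
                        seed = NULL, preset = NULL) {
  if (!is.null(preset))
    mz_error_sd <- switch(match.arg(preset, c("qtof", "qtrap")),
                          qtof = 5e-4, qtrap = 0.2)
  stopifnot(mz_error_sd >= 0, n_noise_peaks >= 0)
  structure(list(mz_error_sd = mz_error_sd,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 noise_intensity_max = noise_intensity_max,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

.noise_peaks <- function(noise, range) {
  if (noise$n_noise_peaks == 0L)
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  data.frame(mz = runif(noise$n_noise_peaks, range[1], range[2]),
             intensity = runif(noise$n_noise_peaks, 0,
                               noise$noise_intensity_max))
}

#' Define a lipid mixture
#'
#' @param species character vector of shorthand names (or list of
#'   [lipid_species()]).
#' @param abundance positive relative abundances, recycled to length.
#' @param scan_range `[min, max]` m/z window of full scans; must cover all
#'   precursor ions.
#' @return list of class `"lipid_mixture"`.
#' @export
lipid_mixture <- function(species, abundance = 1,
                          scan_range = c(400, 1700)) {
  if (is.character(species)) species <- lapply(species, parse_species)
  stopifnot(length(species) >= 0, all(abundance > 0),
            length(scan_range) == 2, scan_range[1] < scan_range[2])
  abundance <- rep_len(abundance, length(species))
  for (sp in species) {
    mz <- min(vapply(.CLASS_INFO[[sp$class]]$adducts,
                     function(a) precursor_mz(sp, a), numeric(1)))
    if (mz < scan_range[1] || precursor_mz(sp) > scan_range[2])
      stop("scan range does not cover precursor of ", format_species(sp))
  }
  structure(list(species = species, abundance = abundance,
                 scan_range = scan_range),
            class = "lipid_mixture")
}

#' Default B. subtilis membrane mixture
#'
#' The qualitative cluster structure of a direct-infusion negative-mode
#' profile of B. subtilis polar lipids: dominant (30:0)/(32:0) PG, a
#' cardiolipin cluster (doubly charged around 650-680, singly charged near
#' 1300), dehydrated lyso-cardiolipin near 1100, alanyl-PG, the LTA primer
#' and its mono-/di-alanylated derivatives as minor species. Relative
#' abundances are order-of-magnitude settings chosen to reproduce the
#' described intensity ordering, not measured values.
#'
#' @return a [lipid_mixture()].
#' @export
bsubtilis_mixture <- function() {
  lipid_mixture(
    species = c("(30:0) PG", "(32:0) PG",
                "(60:0) CL", "(64:0) CL", "(47:0) lyso-CL",
                "(30:0) Ala-PG", "(32:0) Ala-PG",
                "(30:0) DAG-Glc-Glc-P-Gro", "(32:0) DAG-Glc-Glc-P-Gro",
                "(30:0) DAG-Glc-Glc-P-Gro-Ala",
                "(32:0) DAG-Glc-Glc-P-Gro-Ala",
                "(30:0) DAG-Glc-Glc-P-Gro-(Ala)2",
                "(32:0) DAG-Glc-Glc-P-Gro-(Ala)2"),
    abundance = c(1.0, 0.8,
                  0.30, 0.20, 0.15,
                  0.30, 0.25,
                  0.25, 0.20,
                  0.12, 0.10,
                  0.06, 0.05))
}

# Species whose phosphoglycerol is embedded or alanine-capped release the
# cyclic glycerophosphate anion only weakly (5% of the terminal-group
# intensity): cardiolipins (embedded) and every alanylated class (capped).
.free_terminal_pg <- function(species)
  species$class %in% c("PG", "LTA_primer")

#' Simulate an MS/MS spectrum of one species
#'
#' One peak per catalog ion, with Gaussian m/z jitter and log-normal
#' intensities, plus uniform background peaks; deterministic for a given
#' seed. The diagnostic cyclic-glycerophosphate peak of species whose
#' phosphoglycerol is embedded or alanine-capped is damped to 5% of its
#' log-normal draw.
#'
#' @param species [lipid_species()] or shorthand.
#' @param polarity defaults to the class convention.
#' @param noise a [noise_model()].
#' @param max_cuts catalog depth, passed to [enumerate_fragments()].
#' @return a [mass_spectrum()] with `precursor_mz` set.
#' @examples
#' simulate_msms("(30:0) DAG-Glc-Glc-P-Gro",
#'               noise = noise_model(seed = 1, n_noise_peaks = 10))
#' @export
simulate_msms <- function(species, polarity = NULL, noise = noise_model(),
                          max_cuts = NULL) {
  if (is.character(species)) species <- parse_species(species)
  catalog <- enumerate_fragments(species, polarity = polarity,
                                 max_cuts = max_cuts)
  polarity <- attr(catalog, "spec_polarity")
  prec <- precursor_mz(species)
  .with_seed(noise$seed, {
    n <- nrow(catalog)
    mz <- catalog$mz + rnorm(n, 0, noise$mz_error_sd)
    int <- rlnorm(n, noise$intensity_meanlog, noise$intensity_sdlog)
    damp <- !.free_terminal_pg(species) &
      abs(catalog$mz - diagnostic_mz("phosphoglycerol_153")) < 0.01
    int[damp] <- 0.05 * int[damp]
    bg <- .noise_peaks(noise, c(50, prec + 10))
    mass_spectrum(c(mz, bg$mz), c(int, bg$intensity), polarity,
                  precursor_mz = prec)
  })
}

#' Simulate a full-scan spectrum of a mixture
#'
#' One molecular-ion peak per species, abundance-scaled with log-normal
#' variation and m/z jitter; cardiolipins appear mainly as doubly
#' deprotonated dianions at half m/z with a weaker singly charged ion.
#' Uniform background peaks are added over the scan range.
#'
#' @param mixture a [lipid_mixture()].
#' @param polarity scan polarity; species whose class convention differs are
#'   skipped.
#' @param noise a [noise_model()].
#' @return a [mass_spectrum()].
#' @export
simulate_full_scan <- function(mixture, polarity = "negative",
                               noise = noise_model()) {
  stopifnot(inherits(mixture, "lipid_mixture"))
  .with_seed(noise$seed, {
    mzs <- numeric(0); ints <- numeric(0)
    for (i in seq_along(mixture$species)) {
      sp <- mixture$species[[i]]
      if (!identical(.default_polarity(sp), polarity)) next
      adducts <- .CLASS_INFO[[sp$class]]$adducts
      weights <- if (length(adducts) == 2) c(0.3, 1) else 1
      for (j in seq_along(adducts)) {
        mz <- precursor_mz(sp, adducts[j]) + rnorm(1, 0, noise$mz_error_sd)
        if (mz < mixture$scan_range[1] || mz > mixture$scan_range[2]) next
        mzs <- c(mzs, mz)
        ints <- c(ints, mixture$abundance[i] * weights[j] *
                    rlnorm(1, noise$intensity_meanlog, noise$intensity_sdlog))
      }
    }
    bg <- .noise_peaks(noise, mixture$scan_range)
    mass_spectrum(c(mzs, bg$mz), c(ints, bg$intensity), polarity)
  })
}

#' Simulate a precursor-ion-scan trace over a mixture
#'
#' Simulates an MS/MS spectrum per mixture species (by default with
#' `max_cuts = 1`, the dominant single-dissociation channel that a
#' collision-energy-optimised precursor scan reads out) and keeps the
#' precursors whose spectrum shows the diagnostic ion; each retained
#' precursor's intensity is its diagnostic peak intensity scaled by species
#' abundance.
#'
#' @param mixture a [lipid_mixture()].
#' @param diagnostic name accepted by [diagnostic_mz()] or a numeric m/z.
#' @param noise a [noise_model()].
#' @param tol diagnostic matching tolerance, amu.
#' @param max_cuts fragmentation depth of the per-species simulation.
#' @return a [mass_spectrum()] whose peaks are the responding precursors;
#'   polarity follows the diagnostic.
#' @examples
#' tr <- simulate_precursor_scan(bsubtilis_mixture(), "alaninate_88",
#'                               noise = noise_model(seed = 7))
#' round(tr$peaks$mz)
#' @export
simulate_precursor_scan <- function(mixture, diagnostic,
                                    noise = noise_model(), tol = 0.005,
                                    max_cuts = 1L) {
  stopifnot(inherits(mixture, "lipid_mixture"))
  if (is.character(diagnostic)) {
    polarity <- .DIAGNOSTICS()[[match.arg(diagnostic,
                                          names(.DIAGNOSTICS()))]]$polarity
    diag_mz <- diagnostic_mz(diagnostic)
  } else {
    diag_mz <- as.numeric(diagnostic)
    polarity <- "negative"
  }
  mzs <- numeric(0); ints <- numeric(0)
  for (i in seq_along(mixture$species)) {
    sp <- mixture$species[[i]]
    if (!identical(.default_polarity(sp), polarity)) next
    if (!.CLASS_INFO[[sp$class]]$fragmentable) next
    sub_noise <- noise
    if (!is.null(noise$seed)) sub_noise$seed <- noise$seed + i
    spec <- simulate_msms(sp, noise = sub_noise, max_cuts = max_cuts)
    if (spec$precursor_mz < mixture$scan_range[1] ||
        spec$precursor_mz > mixture$scan_range[2]) next
    d <- abs(spec$peaks$mz - diag_mz)
    hit <- which(d <= tol)
    if (!length(hit)) next
    mzs <- c(mzs, spec$precursor_mz)
    ints <- c(ints, mixture$abundance[i] * max(spec$peaks$intensity[hit]))
  }
  out <- mass_spectrum(mzs, ints, polarity)
  attr(out, "diagnostic_mz") <- diag_mz
  out
}
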