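test_that("the primer MS/MS peak list is fully annotated at 0.01 amu", {
  tab <- reference_fragment_table(2)
  spec <- mass_spectrum(tab$observed, rep(1, nrow(tab)), "negative",
                        precursor_mz = 1017.577)
  ann <- annotate_spectrum(spec, "(30:0) DAG-Glc-Glc-P-Gro", tol = 0.01)
  expect_identical(sum(ann$matched), 12L)
  expect_lte(match_stats(ann)$max_abs_delta, 0.01)
})

test_that("empty spectra and unmatched peaks are handled gracefully", {
  empty <- mass_spectrum(numeric(0), numeric(0), "negative")
  ann <- annotate_spectrum(empty, "(30:0) PG", tol = 0.01)
  expect_identical(nrow(ann), 0L)
  st <- match_stats(ann)
  expect_identical(unlist(st), c(n_matched = 0, max_abs_delta = 0,
                                 mean_abs_delta = 0))
  # a far-out peak is reported unmatched, never force-assigned
  far <- mass_spectrum(c(241.2173, 10000), c(1, 1), "negative")
  ann2 <- annotate_spectrum(far, "(30:0) PG", tol = 0.01)
  expect_identical(ann2$matched, c(TRUE, FALSE))
  expect_equal(match_stats(data.frame(matched = TRUE, delta = -0.0015)
                           )$max_abs_delta, 0.0015)
})

test_that("a zero-error synthetic spectrum annotates with delta 0", {
  for (s in c("(30:0) DAG-Glc-Glc-P-Gro", "(32:0) DAG-Glc-Glc")) {
    spec <- simulate_msms(s, noise = noise_model(mz_error_sd = 0, seed = 1))
    ann <- annotate_spectrum(spec, s, tol = 1e-6)
    expect_true(all(ann$matched))
    expect_identical(max(abs(ann$delta)), 0)
  }
})

test_that("widening the tolerance never loses annotations", {
  spec <- simulate_msms("(30:0) DAG-Glc-Glc-P-Gro-Ala",
                        noise = noise_model(mz_error_sd = 0.003,
                                            n_noise_peaks = 30, seed = 11))
  counts <- vapply(c(1e-4, 1e-3, 5e-3, 1e-2, 0.05, 0.3), function(tol)
    sum(annotate_spectrum(spec, "(30:0) DAG-Glc-Glc-P-Gro-Ala",
                          tol = tol)$matched), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("precursor scans pick out the diagnostic-bearing species", {
  mix <- c("(30:0) PG", "(32:0) PG",
           "(30:0) DAG-Glc-Glc-P-Gro", "(32:0) DAG-Glc-Glc-P-Gro",
           "(30:0) Ala-PG", "(32:0) Ala-PG",
           "(30:0) DAG-Glc-Glc-P-Gro-Ala", "(32:0) DAG-Glc-Glc-P-Gro-Ala")
  msms <- lapply(mix, function(s)
    simulate_msms(s, noise = noise_model(mz_error_sd = 0), max_cuts = 1))
  hits153 <- precursor_scan(msms, "phosphoglycerol_153", tol = 0.005)
  expect_identical(round(sort(hits153$precursor_mz)),
                   c(693, 722, 1018, 1046))
  hits88 <- precursor_scan(msms, "alaninate_88", tol = 0.005)
  expect_identical(round(sort(hits88$precursor_mz)),
                   c(765, 793, 1089, 1117))
  none <- precursor_scan(msms, 10000, tol = 0.005)
  expect_identical(nrow(none), 0L)
})

test_that("nomination ranks the published species first", {
  top <- function(mz, diag) nominate_species(mz, diag, tol = 0.02)[1, ]
  expect_identical(top(1017.58, "phosphoglycerol_153")$species,
                   "(30:0) DAG-Glc-Glc-P-Gro")
  expect_identical(top(1159.65, "alaninate_88")$species,
                   "(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")
  expect_identical(top(915.60, "dihexose_347")$species,
                   "(32:0) DAG-Glc-Glc")
  expect_identical(nrow(nominate_species(887.05, "phosphoglycerol_153",
                                         tol = 0.02)), 0L)
})

test_that("nomination is self-consistent for every diagnostic class", {
  cases <- list(c("DAG_anchor", "dihexose_347"),
                c("PG", "phosphoglycerol_153"),
                c("LTA_primer", "phosphoglycerol_153"),
                c("alanyl_PG", "alaninate_88"),
                c("LTA_primer_Ala", "alaninate_88"),
                c("LTA_primer_Ala2", "alaninate_88"))
  for (cs in cases) {
    for (carb in c(28L, 31L, 34L)) {
      sp <- lipid_species(cs[1], carb, 1L)
      hits <- nominate_species(precursor_mz(sp), cs[2], tol = 0.01)
      expect_identical(hits$species[1], format_species(sp))
    }
  }
})
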