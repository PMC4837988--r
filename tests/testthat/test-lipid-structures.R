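test_that("shorthand parsing recovers class, composition and chains", {
  sp <- parse_species("(32:0) DAG-Glc-Glc")
  expect_identical(sp$class, "DAG_anchor")
  expect_identical(sp$sum, c(carbons = 32L, double_bonds = 0L))
  expect_identical(sp$hexoses, 2L)
  expect_false(sp$resolved)
  # default split prefers the dominant odd chains, larger first
  expect_identical(vapply(sp$chains, `[[`, 1L, "carbons"), c(17L, 15L))

  sp2 <- parse_species("(15:0/15:0) DAG-Glc-Glc-P-Gro")
  expect_true(sp2$resolved)
  expect_identical(vapply(sp2$chains, `[[`, 1L, "carbons"), c(15L, 15L))

  sp3 <- parse_species("(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")
  expect_identical(sp3$class, "LTA_primer_Ala2")
  expect_identical(sp3$ala_count, 2L)

  expect_error(parse_species("(30:0) DAG-Gal-Gal"), "unknown lipid class")
  expect_error(parse_species("bogus species"), "malformed")
  expect_error(parse_species("(15:0/15:0/15:0) PG"), "expected 2 chains")
})

test_that("every species named in the study is parseable", {
  shorthands <- c("(30:0) DAG-Glc-Glc", "(32:0) DAG-Glc-Glc",
                  "(30:0) DAG-Glc-Glc-P-Gro", "(32:0) DAG-Glc-Glc-P-Gro",
                  "(30:0) DAG-Glc-Glc-P-Gro-Ala",
                  "(32:0) DAG-Glc-Glc-P-Gro-Ala",
                  "(30:0) DAG-Glc-Glc-P-Gro-(Ala)2",
                  "(32:0) DAG-Glc-Glc-P-Gro-(Ala)2",
                  "(30:0) PG", "(32:0) PG", "(30:0) Ala-PG", "(32:0) Ala-PG",
                  "(60:0) CL", "(47:0) lyso-CL")
  for (s in shorthands) {
    sp <- parse_species(s)
    expect_s3_class(sp, "lipid_species")
    expect_gt(precursor_mz(sp), 0)
  }
  expect_identical(length(parse_species("(60:0) CL")$chains), 4L)
  expect_identical(length(parse_species("(45:0) lyso-CL")$chains), 3L)
})

test_that("species formulas follow condensation chemistry", {
  expect_identical(
    format_formula(species_formula(parse_species("(32:0) DAG-Glc-Glc"))),
    "C47H88O15")
  ltap <- species_formula(parse_species("(30:0) DAG-Glc-Glc-P-Gro"))
  expect_equal(ion_mz(ltap, "deprotonated_anion"), 1017.5770,
               tolerance = 2e-3)
  # one ester-linked alanine adds exactly a dehydrated alanine
  ala1 <- species_formula(parse_species("(30:0) DAG-Glc-Glc-P-Gro-Ala"))
  diff <- ala1 - ltap
  expect_identical(as.integer(diff[c("C", "H", "N", "O")]),
                   c(3L, 5L, 1L, 1L))
})

test_that("resolved chain splits with equal totals give one formula", {
  splits <- list("(30:0) DAG-Glc-Glc-P-Gro",
                 "(15:0/15:0) DAG-Glc-Glc-P-Gro",
                 "(14:0/16:0) DAG-Glc-Glc-P-Gro",
                 "(13:0/17:0) DAG-Glc-Glc-P-Gro")
  formulas <- vapply(splits, function(s)
    format_formula(species_formula(parse_species(s))), character(1))
  expect_identical(length(unique(formulas)), 1L)
})

test_that("alanylation ladder steps by one dehydrated alanine (71 amu)", {
  mz0 <- precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro"))
  mz1 <- precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro-Ala"))
  mz2 <- precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro-(Ala)2"))
  expect_equal(mz1 - mz0, 71.0371, tolerance = 5e-4)
  expect_equal(mz2 - mz1, 71.0371, tolerance = 5e-4)
  expect_identical(round(mz1 - mz0), 71)
})

test_that("precursor m/z matches the published molecular ions", {
  expect_equal(precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro-Ala")),
               1088.6140, tolerance = 2e-3)
  expect_equal(precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")),
               1159.6510, tolerance = 2e-3)
  expect_identical(round(precursor_mz(parse_species("(30:0) PG"))), 693)
  # nominal anion mass: neutral nominal minus one hydrogen
  expect_identical(nominal_mass(species_formula(parse_species("(32:0) PG")))
                   - 1L, 721L)
  expect_error(precursor_mz(parse_species("(30:0) PG"), "sodiated_cation"),
               "incompatible")
})
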