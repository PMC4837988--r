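test_that("enumerated catalogs contain the published calculated masses", {
  for (i in 1:4) {
    tab <- reference_fragment_table(i)
    cat_ <- catalog_for_table(i)
    rows <- tab[tab$in_catalog & tab$calculated != ERRATUM_CALC, ]
    for (r in seq_len(nrow(rows))) {
      expect_lt(min(abs(cat_$mz - rows$calculated[r])), 2e-3,
                label = sprintf("table %d, %s (%s)", i, rows$calculated[r],
                                rows$description[r]))
    }
  }
  # the inconsistently printed "- H3O" row is checked against the value
  # implied by its own "- H" companion (one water lighter)
  cat2 <- catalog_for_table(2)
  expect_lt(min(abs(cat2$mz - ERRATUM_CONSISTENT)), 2e-3)
})

test_that("cleavage labels reproduce the published assignments", {
  cat1 <- catalog_for_table(1)
  # a single cut yields both retained sides under one bond label, so assert
  # that the published (label, mass) pairing is present
  has <- function(cl, mz)
    any(cat1$cleavage == cl & abs(cat1$mz - mz) < 2e-3)
  expect_true(has("d", 347.0955))
  expect_true(has("c", 365.1060))
  expect_true(has("f", 753.5496))
  expect_true(has("b1 & f", 483.2936))
  expect_true(has("a1 & c", 299.2588))
  # allylic channel: double acid loss retaining two hydrogens
  allyl <- cat1[grepl("CH2=CH-CH2", cat1$description), ]
  expect_identical(nrow(allyl), 1L)
  expect_equal(allyl$mz, 405.1374, tolerance = 2e-3)
  expect_identical(allyl$cleavage, "b1 & b2")
})

test_that("rearrangement ions exist only for the di-alanylated primer", {
  sp <- special_rearrangements("(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")
  expect_identical(nrow(sp), 2L)
  expect_equal(sort(sp$mz), c(159.0770, 1115.6610), tolerance = 2e-3)
  expect_identical(nrow(special_rearrangements("(30:0) DAG-Glc-Glc-P-Gro-Ala")),
                   0L)
  expect_identical(nrow(special_rearrangements("(30:0) PG")), 0L)
  cat4 <- catalog_for_table(4)
  expect_identical(sum(cat4$special), 2L)
})

test_that("neutral losses recover the masses quoted in the annotation", {
  anchor <- parse_species("(32:0) DAG-Glc-Glc")
  cat1 <- catalog_for_table(1)
  ion645 <- cat1[abs(cat1$mz - 645.3464) < 2e-3, ]
  loss <- neutral_loss(anchor, ion645)
  expect_identical(loss$formula, "C17H34O2")  # (17:0) fatty acid
  expect_identical(loss$nominal, 270L)
  ala1 <- parse_species("(30:0) DAG-Glc-Glc-P-Gro-Ala")
  cat3 <- catalog_for_table(3)
  ion999 <- cat3[abs(cat3$mz - 999.5661) < 2e-3, ]
  expect_identical(neutral_loss(ala1, ion999)$nominal, 89L)  # alanine
  self <- neutral_loss(ion645, ion645)
  expect_identical(self$nominal, 0L)
  expect_identical(self$formula, "")
  expect_error(neutral_loss(ion645, cat1[nrow(cat1), ]),
               "sub-composition")
})

test_that("fragment compositions conserve mass against the precursor", {
  for (s in c("(30:0) DAG-Glc-Glc-P-Gro", "(32:0) DAG-Glc-Glc",
              "(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")) {
    sp <- parse_species(s)
    cat_ <- enumerate_fragments(sp)
    prec <- species_formula(sp)
    for (r in seq_len(nrow(cat_))) {
      loss <- neutral_loss(prec, cat_[r, ])
      expect_true(all(loss$composition >= 0))
      expect_equal(monoisotopic_mass(loss$composition) +
                     monoisotopic_mass(parse_formula(cat_$formula[r])),
                   monoisotopic_mass(prec), tolerance = 1e-9)
    }
  }
})

test_that("identical chains collapse symmetric cuts to single ions", {
  cat2 <- catalog_for_table(2)
  expect_false(any(duplicated(paste(cat2$formula, cat2$adduct))))
  fa <- cat2[cat2$description == "(15:0) FA - H", ]
  expect_identical(nrow(fa), 1L)
  # the resolved 15:0/15:0 and the unresolved (30:0) catalog agree
  cat2r <- enumerate_fragments("(15:0/15:0) DAG-Glc-Glc-P-Gro")
  expect_equal(sort(cat2r$mz), sort(cat2$mz), tolerance = 1e-9)
})

test_that("graph enumeration agrees with the brute-force oracle", {
  g <- toy_graph()
  got <- ltafrag:::.enumerate_graph(g, max_cuts = 3L)
  got_masses <- sort(unique(round(vapply(got, function(f)
    monoisotopic_mass(f$composition), numeric(1)), 6)))
  expect_identical(got_masses, oracle_neutral_masses(g))
})

test_that("catalog options are validated and applied", {
  expect_error(enumerate_fragments("(30:0) PG", max_cuts = 0), "max_cuts")
  expect_error(enumerate_fragments("(30:0) PG", max_cuts = 4), "max_cuts")
  expect_error(enumerate_fragments("(30:0) PG", polarity = "positive"),
               "incompatible")
  cat_ <- enumerate_fragments("(30:0) DAG-Glc-Glc-P-Gro")
  expect_true(all(cat_$mz >= 50))
  expect_false(is.unsorted(cat_$mz))
  # cardiolipins are catalogued at the molecular-ion level only
  cl <- enumerate_fragments("(60:0) CL")
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$adduct, c("deprotonated_anion",
                               "double_deprotonated_dianion"))
  expect_true(any(cl$mz > 645 & cl$mz < 680))
})
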