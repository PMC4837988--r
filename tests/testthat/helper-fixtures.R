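# Shared fixtures and an independent brute-force fragment oracle.

# The one reference row whose printed calculated mass is internally
# inconsistent: the "(15:0) MAG-Glc-Glc-P - H3O" (b1 & j) entry is printed
# as 701.3051, but the companion "- H" form (a1 & j) is printed 719.3257 and
# an acid-vs-ketene pair must differ by exactly one water (18.0106), giving
# 701.3151; recomputation from composition C30H59O16P confirms 701.3155.
ERRATUM_CALC <- 701.3051
ERRATUM_CONSISTENT <- 719.3257 - 18.010565

WATER_MASS <- monoisotopic_mass("H2O")

ref_tables <- function() reference_fragment_table()

catalog_for_table <- function(i) {
  enumerate_fragments(reference_table_species()[[paste0("table", i)]])
}

# Toy residue graph for oracle equivalence: a 4-residue linear chain
# acyl--glycerol--glucose--phosphate with 3 condensation linkages. Labels
# avoid the unenumerated glycosidic flank.
toy_graph <- function() {
  list(
    residues = list(
      fa1  = list(formula = acyl_formula(3, 0), type = "acyl"),
      gro  = list(formula = parse_formula("C3H8O3"), type = "glycerol"),
      glc1 = list(formula = parse_formula("C6H12O6"), type = "hexose"),
      p    = list(formula = parse_formula("H3O4P"), type = "phosphate")
    ),
    linkages = list(
      list(r1 = "fa1", r2 = "gro", lab1 = "b1", lab2 = "a1"),
      list(r1 = "gro", r2 = "glc1", lab1 = "d", lab2 = "c"),
      list(r1 = "glc1", r2 = "p", lab1 = "h", lab2 = "g")
    )
  )
}

# Brute-force oracle: every sub-multiset of residues that is connected in
# the graph, at every water state from fully hydrolysed down to one lost
# water per boundary cut. Returns the set of neutral monoisotopic masses.
oracle_neutral_masses <- function(graph) {
  ids <- names(graph$residues)
  n <- length(ids)
  masses <- numeric(0)
  for (mask in 1:(2^n - 1)) {
    subset <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    inside <- vapply(graph$linkages, function(l)
      l$r1 %in% subset && l$r2 %in% subset, logical(1))
    boundary <- vapply(graph$linkages, function(l)
      xor(l$r1 %in% subset, l$r2 %in% subset), logical(1))
    # connectivity: grow from the first residue over internal linkages
    reach <- subset[1]
    repeat {
      grew <- FALSE
      for (l in graph$linkages[inside]) {
        if (l$r1 %in% reach && !(l$r2 %in% reach)) {
          reach <- c(reach, l$r2); grew <- TRUE
        }
        if (l$r2 %in% reach && !(l$r1 %in% reach)) {
          reach <- c(reach, l$r1); grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (length(reach) != length(subset)) next
    free <- sum(vapply(subset, function(r)
      monoisotopic_mass(graph$residues[[r]]$formula), numeric(1)))
    base <- free - sum(inside) * WATER_MASS
    for (k in 0:sum(boundary)) masses <- c(masses, base - k * WATER_MASS)
  }
  sort(unique(round(masses, 6)))
}
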