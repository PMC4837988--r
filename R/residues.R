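# Free (unbonded) formulas of the residues making up the lipid classes.
# All structures are condensation products of these; every linkage costs one
# water.

.RES_GLYCEROL  <- function() composition(C = 3, H = 8, O = 3)   # C3H8O3
.RES_GLUCOSE   <- function() composition(C = 6, H = 12, O = 6)  # C6H12O6
.RES_PHOSPHATE <- function() composition(H = 3, O = 4, P = 1)   # H3PO4
.RES_ALANINE   <- function() composition(C = 3, H = 7, N = 1, O = 2)

#' Free-acid formula of an acyl chain
#'
#' A chain with `carbons` carbons and `double_bonds` double bonds has the
#' free fatty acid formula C(n)H(2n-2d)O2.
#'
#' @param carbons total carbons including the carboxyl carbon (>= 2).
#' @param double_bonds number of C=C double bonds.
#' @return element composition of the free fatty acid.
#' @examples
#' acyl_formula(15, 0) # pentadecanoic acid C15H30O2
#' @export
acyl_formula <- function(carbons, double_bonds = 0) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2) stop("acyl chain needs >= 2 carbons")
  if (is.na(double_bonds) || double_bonds < 0 || double_bonds > carbons %/% 2)
    stop("double bond count out of range for ", carbons, " carbons")
  composition(C = carbons, H = 2L * carbons - 2L * double_bonds, O = 2)
}

# Named neutral-loss compositions used throughout the annotation prose:
# free fatty acids, ketene (acid - H2O), anhydroglucose, cycloglycerol,
# alanine, cyclo-alanyl-glycerol, CO2.
.LOSS_TABLE <- function() {
  list(
    anhydroglucose = .comp_sub(.RES_GLUCOSE(), .WATER),
    cycloglycerol  = .comp_sub(.RES_GLYCEROL(), .WATER),
    alanine        = .RES_ALANINE(),
    dehydroalanine = .comp_sub(.RES_ALANINE(), .WATER),
    alanylglycerol = condense(.RES_ALANINE(), .RES_GLYCEROL()),
    cycloalanylglycerol = .comp_sub(condense(.RES_ALANINE(), .RES_GLYCEROL()),
                                    .WATER),
    co2 = composition(C = 1, O = 2)
  )
}
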