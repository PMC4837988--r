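# Lipid-class registry. `token` is the shorthand class name; `n_chains` the
# number of acyl chains; `hexoses` the dihexose head (glucose in B. subtilis);
# `n_ala` the number of ester-linked alanines; `adducts` the ion types the
# class is observed as; `fragmentable` whether the bond-cutting fragmenter
# applies (cardiolipins are modelled at the molecular-ion level only).
.CLASS_INFO <- list(
  DAG_anchor = list(token = "DAG-Glc-Glc", n_chains = 2L, hexoses = 2L,
                    n_ala = 0L, polarity = "positive",
                    adducts = "sodiated_cation", fragmentable = TRUE),
  LTA_primer = list(token = "DAG-Glc-Glc-P-Gro", n_chains = 2L, hexoses = 2L,
                    n_ala = 0L, polarity = "negative",
                    adducts = "deprotonated_anion", fragmentable = TRUE),
  LTA_primer_Ala = list(token = "DAG-Glc-Glc-P-Gro-Ala", n_chains = 2L,
                        hexoses = 2L, n_ala = 1L, polarity = "negative",
                        adducts = "deprotonated_anion", fragmentable = TRUE),
  LTA_primer_Ala2 = list(token = "DAG-Glc-Glc-P-Gro-(Ala)2", n_chains = 2L,
                         hexoses = 2L, n_ala = 2L, polarity = "negative",
                         adducts = "deprotonated_anion", fragmentable = TRUE),
  PG = list(token = "PG", n_chains = 2L, hexoses = 0L, n_ala = 0L,
            polarity = "negative", adducts = "deprotonated_anion",
            fragmentable = TRUE),
  alanyl_PG = list(token = "Ala-PG", n_chains = 2L, hexoses = 0L, n_ala = 1L,
                   polarity = "negative", adducts = "deprotonated_anion",
                   fragmentable = TRUE),
  cardiolipin = list(token = "CL", n_chains = 4L, hexoses = 0L, n_ala = 0L,
                     polarity = "negative",
                     adducts = c("deprotonated_anion",
                                 "double_deprotonated_dianion"),
                     fragmentable = FALSE),
  lyso_cardiolipin = list(token = "lyso-CL", n_chains = 3L, hexoses = 0L,
                          n_ala = 0L, polarity = "negative",
                          adducts = c("deprotonated_anion",
                                      "double_deprotonated_dianion"),
                          fragmentable = FALSE)
)

#' Supported lipid classes
#'
#' @return character vector of class identifiers accepted by
#'   [lipid_species()] and returned by [parse_species()].
#' @export
lipid_classes <- function() names(.CLASS_INFO)

# Split an unresolved (C:D) sum composition into per-chain compositions.
# Two-chain species prefer odd-carbon chains, the dominant B. subtilis
# pattern: (30:0) -> 15:0/15:0, (32:0) -> 17:0/15:0. Larger chain first.
.default_chain_split <- function(carbons, double_bonds, n_chains) {
  if (n_chains == 2L) {
    c1 <- carbons %/% 2L
    if (c1 %% 2L == 0L && carbons - c1 + 1L >= c1 - 1L && c1 > 2L) c1 <- c1 - 1L
    cs <- sort(c(c1, carbons - c1), decreasing = TRUE)
  } else {
    base <- carbons %/% n_chains
    cs <- rep(base, n_chains)
    r <- carbons %% n_chains
    if (r > 0) cs[seq_len(r)] <- cs[seq_len(r)] + 1L
    cs <- sort(cs, decreasing = TRUE)
  }
  ds <- integer(n_chains)
  d <- double_bonds
  i <- 1L
  while (d > 0L) {               # spread double bonds round-robin
    ds[i] <- ds[i] + 1L
    d <- d - 1L
    i <- if (i == n_chains) 1L else i + 1L
  }
  Map(function(ci, di) c(carbons = ci, double_bonds = di),
      as.integer(cs), as.integer(ds))
}

#' Construct a lipid species
#'
#' @param class one of [lipid_classes()].
#' @param carbons,double_bonds unresolved acyl sum composition (total
#'   carbons : total double bonds); ignored when `chains` is given.
#' @param chains optional list of resolved chains, each `c(carbons,
#'   double_bonds)`; its length must equal the class chain count.
#' @return object of class `"lipid_species"`.
#' @examples
#' lipid_species("LTA_primer", 30, 0)
#' lipid_species("LTA_primer", chains = list(c(15, 0), c(15, 0)))
#' @export
lipid_species <- function(class, carbons = NULL, double_bonds = 0L,
                          chains = NULL) {
  info <- .CLASS_INFO[[class]]
  if (is.null(info)) stop("unknown lipid class: ", class)
  if (!is.null(chains)) {
    if (length(chains) != info$n_chains)
      stop(class, " carries ", info$n_chains, " chains, got ", length(chains))
    chains <- lapply(chains, function(ch) {
      ch <- as.integer(ch)
      if (length(ch) == 1L) ch <- c(ch, 0L)
      acyl_formula(ch[1], ch[2])  # validates
      c(carbons = ch[1], double_bonds = ch[2])
    })
    total <- c(carbons = sum(vapply(chains, `[[`, 1L, "carbons")),
               double_bonds = sum(vapply(chains, `[[`, 1L, "double_bonds")))
    if (!is.null(carbons) &&
        (total[["carbons"]] != carbons || total[["double_bonds"]] != double_bonds))
      stop("resolved chains do not sum to the stated (",
           carbons, ":", double_bonds, ") composition")
    resolved <- TRUE
  } else {
    if (is.null(carbons)) stop("give either a sum composition or chains")
    total <- c(carbons = as.integer(carbons),
               double_bonds = as.integer(double_bonds))
    if (total[["carbons"]] < 2L * info$n_chains)
      stop("sum composition too small for ", info$n_chains, " chains")
    chains <- .default_chain_split(total[["carbons"]],
                                   total[["double_bonds"]], info$n_chains)
    resolved <- FALSE
  }
  structure(list(class = class, chains = chains, sum = total,
                 resolved = resolved, hexoses = info$hexoses,
                 ala_count = info$n_ala),
            class = "lipid_species")
}

#' Parse a lipid shorthand name
#'
#' Grammar: `"(C:D) CLASS"` with CLASS one of `DAG-Glc-Glc`,
#' `DAG-Glc-Glc-P-Gro`, `DAG-Glc-Glc-P-Gro-Ala`, `DAG-Glc-Glc-P-Gro-(Ala)2`,
#' `PG`, `Ala-PG`, `CL`, `lyso-CL`. A slash-separated composition such as
#' `"(15:0/17:0)"` resolves the individual chains; a plain `"(32:0)"` is an
#' unresolved sum that defaults to the dominant odd-chain split.
#'
#' @param shorthand species name, e.g. `"(30:0) DAG-Glc-Glc-P-Gro-Ala"`.
#' @return a [lipid_species()] object.
#' @examples
#' parse_species("(32:0) DAG-Glc-Glc")
#' parse_species("(15:0/15:0) DAG-Glc-Glc-P-Gro")
#' @export
parse_species <- function(shorthand) {
  stopifnot(is.character(shorthand), length(shorthand) == 1)
  m <- regexec("^\\s*\\(([0-9:/]+)\\)\\s+(\\S.*?)\\s*$", shorthand)
  parts <- regmatches(shorthand, m)[[1]]
  if (length(parts) != 3)
    stop("malformed species shorthand: '", shorthand, "'")
  comp_tok <- parts[2]; class_tok <- parts[3]
  cls <- NULL
  for (nm in names(.CLASS_INFO))
    if (identical(.CLASS_INFO[[nm]]$token, class_tok)) cls <- nm
  if (is.null(cls)) stop("unknown lipid class token: '", class_tok, "'")
  pieces <- strsplit(comp_tok, "/", fixed = TRUE)[[1]]
  cd <- lapply(pieces, function(p) {
    v <- suppressWarnings(as.integer(strsplit(p, ":", fixed = TRUE)[[1]]))
    if (length(v) != 2 || anyNA(v))
      stop("malformed acyl composition token: '", p, "'")
    v
  })
  if (length(cd) == 1L) {
    lipid_species(cls, carbons = cd[[1]][1], double_bonds = cd[[1]][2])
  } else {
    if (length(cd) != .CLASS_INFO[[cls]]$n_chains)
      stop("expected ", .CLASS_INFO[[cls]]$n_chains,
           " chains for ", class_tok, ", got ", length(cd))
    lipid_species(cls, chains = cd)
  }
}

#' Canonical shorthand of a species
#'
#' @param species a [lipid_species()] object.
#' @param resolved render the per-chain composition instead of the sum.
#' @return character shorthand.
#' @export
format_species <- function(species, resolved = species$resolved) {
  stopifnot(inherits(species, "lipid_species"))
  tok <- .CLASS_INFO[[species$class]]$token
  comp <- if (resolved) {
    paste(vapply(species$chains,
                 function(ch) paste0(ch[["carbons"]], ":", ch[["double_bonds"]]),
                 character(1)), collapse = "/")
  } else {
    paste0(species$sum[["carbons"]], ":", species$sum[["double_bonds"]])
  }
  paste0("(", comp, ") ", tok)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid species> ", format_species(x), "\n", sep = "")
  cat("  class:    ", x$class, "\n", sep = "")
  cat("  chains:   ", paste(vapply(x$chains, function(ch)
    paste0(ch[["carbons"]], ":", ch[["double_bonds"]]), character(1)),
    collapse = ", "),
    if (!x$resolved) "  (default split of unresolved sum)", "\n", sep = "")
  cat("  formula:  ", format_formula(species_formula(x)), "\n", sep = "")
  mz <- precursor_mz(x)
  cat("  precursor: ", format(round(mz, 4), nsmall = 4), " (",
      .default_adduct(x), ")\n", sep = "")
  invisible(x)
}

.default_adduct <- function(species) .CLASS_INFO[[species$class]]$adducts[1]

.default_polarity <- function(species) .CLASS_INFO[[species$class]]$polarity

# Residue graph of a species: residues carry free formulas; each linkage is a
# condensation bond with the two flanking scissile-bond labels. Cutting
# `lab1` leaves the bridging oxygen (and transferred hydrogen) with the side
# containing `r1`, so a retained fragment on the r1 side keeps its water
# (hydrolysed form) while the r2 side comes off dehydrated; `lab2` is the
# mirror bond.
.species_graph <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  cls <- species$class
  res <- list()
  lnk <- list()
  add_res <- function(id, formula, type) res[[id]] <<- list(formula = formula,
                                                            type = type)
  add_lnk <- function(r1, r2, lab1, lab2) lnk[[length(lnk) + 1L]] <<-
      list(r1 = r1, r2 = r2, lab1 = lab1, lab2 = lab2)

  chains <- species$chains
  if (cls %in% c("cardiolipin", "lyso_cardiolipin")) {
    # two phosphatidyl arms on a central glycerol; arm 2 loses one chain in
    # the lyso form
    add_res("groC", .RES_GLYCEROL(), "glycerol")
    n <- length(chains); k <- 0L
    for (arm in 1:2) {
      g <- paste0("gro", arm); p <- paste0("p", arm)
      add_res(g, .RES_GLYCEROL(), "glycerol")
      add_res(p, .RES_PHOSPHATE(), "phosphate")
      add_lnk(g, p, paste0("h", arm), paste0("g", arm))
      add_lnk(p, "groC", paste0("j", arm), paste0("i", arm))
      n_arm <- if (arm == 1L) 2L else n - 2L
      for (i in seq_len(n_arm)) {
        k <- k + 1L
        fa <- paste0("fa", k)
        add_res(fa, acyl_formula(chains[[k]][["carbons"]],
                                 chains[[k]][["double_bonds"]]), "acyl")
        add_lnk(fa, g, paste0("b", k), paste0("a", k))
      }
    }
    return(list(residues = res, linkages = lnk))
  }

  add_res("gro", .RES_GLYCEROL(), "glycerol")
  for (i in seq_along(chains)) {
    fa <- paste0("fa", i)
    add_res(fa, acyl_formula(chains[[i]][["carbons"]],
                             chains[[i]][["double_bonds"]]), "acyl")
    add_lnk(fa, "gro", paste0("b", i), paste0("a", i))
  }
  if (species$hexoses > 0L) {
    add_res("glc1", .RES_GLUCOSE(), "hexose")
    add_res("glc2", .RES_GLUCOSE(), "hexose")
    add_lnk("gro", "glc1", "d", "c")
    add_lnk("glc1", "glc2", "f", "e")
  }
  if (cls %in% c("LTA_primer", "LTA_primer_Ala", "LTA_primer_Ala2",
                 "PG", "alanyl_PG")) {
    add_res("p", .RES_PHOSPHATE(), "phosphate")
    add_res("groh", .RES_GLYCEROL(), "glycerol")
    anchor_res <- if (species$hexoses > 0L) "glc2" else "gro"
    add_lnk(anchor_res, "p", "h", "g")
    add_lnk("p", "groh", "j", "i")
  }
  if (species$ala_count >= 1L) {
    add_res("ala1", .RES_ALANINE(), "alanine")
    add_lnk("groh", "ala1", "l", "k")
  }
  if (species$ala_count >= 2L) {
    add_res("ala2", .RES_ALANINE(), "alanine")
    add_lnk("groh", "ala2", "n", "m")
  }
  list(residues = res, linkages = lnk)
}

#' Neutral molecular formula of a species
#'
#' Sum of the free residue formulas minus one water per condensation bond
#' (acyl esters, glycosidic bonds, the glucose-glycerol linkage, the two
#' phosphodiester flanks and any alanyl esters). Resolved and unresolved
#' chain descriptions with equal totals give identical formulas.
#'
#' @param species a [lipid_species()] object.
#' @return element composition of the neutral molecule.
#' @examples
#' format_formula(species_formula(parse_species("(32:0) DAG-Glc-Glc")))
#' @export
species_formula <- function(species) {
  g <- .species_graph(species)
  out <- .empty_composition()
  for (r in g$residues) out <- .comp_add(out, r$formula)
  .comp_sub(out, composition(H = 2L * length(g$linkages),
                             O = length(g$linkages)))
}

#' Precursor m/z of a species
#'
#' @param species a [lipid_species()] object.
#' @param adduct ion type; defaults to the class convention (sodiated for the
#'   neutral glycolipid anchor, deprotonated for phospholipids and LTA
#'   species; cardiolipins additionally support the doubly deprotonated
#'   dianion). Requesting an adduct the class is not observed as is an error.
#' @return m/z in amu.
#' @examples
#' precursor_mz(parse_species("(30:0) DAG-Glc-Glc-P-Gro"))
#' @export
precursor_mz <- function(species, adduct = .default_adduct(species)) {
  stopifnot(inherits(species, "lipid_species"))
  allowed <- .CLASS_INFO[[species$class]]$adducts
  if (!adduct %in% allowed)
    stop("adduct '", adduct, "' incompatible with class ", species$class)
  ion_mz(species_formula(species), adduct)
}
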