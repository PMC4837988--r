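# Core bond-cutting enumerator on a residue graph.
#
# Cutting a condensation linkage splits the (tree-shaped) residue graph in
# two. The bridging oxygen and a transferred hydrogen stay with one side:
# that side keeps the water of hydrolysis (its free-residue bookkeeping is
# unchanged) and the other side comes off dehydrated (minus one H2O). Which
# side keeps the water is what the two flanking scissile-bond labels encode,
# so every (cut set, water state) pair maps to a unique label set. Compounded
# over cuts this generates the whole "- H" / "- H3O" / "- H5O2" suffix family
# without per-row rules.
#
# One channel needs more than water bookkeeping: when both acyl esters are
# cut and both acids leave with their water, the glycerol backbone retains
# two hydrogens and an allylic cation results (the CH2=CH-CH2-Glc-Glc ion);
# that variant is emitted explicitly with a +H2 adjustment.
.enumerate_graph <- function(graph, max_cuts) {
  res_ids <- names(graph$residues)
  lnk <- graph$linkages
  n_lnk <- length(lnk)

  neighbours <- function(cut_idx) {
    adj <- setNames(vector("list", length(res_ids)), res_ids)
    for (i in seq_len(n_lnk)) {
      if (i %in% cut_idx) next
      l <- lnk[[i]]
      adj[[l$r1]] <- c(adj[[l$r1]], l$r2)
      adj[[l$r2]] <- c(adj[[l$r2]], l$r1)
    }
    adj
  }
  components <- function(cut_idx) {
    adj <- neighbours(cut_idx)
    seen <- setNames(logical(length(res_ids)), res_ids)
    comps <- list()
    for (r in res_ids) {
      if (seen[[r]]) next
      queue <- r; comp <- character(0)
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (seen[[v]]) next
        seen[[v]] <- TRUE
        comp <- c(comp, v)
        queue <- c(queue, adj[[v]])
      }
      comps[[length(comps) + 1L]] <- comp
    }
    comps
  }

  out <- list()
  emit <- function(residues, labels, n_cuts, water_lost, comp, allylic = FALSE) {
    out[[length(out) + 1L]] <<- list(
      residues = residues, labels = labels, n_cuts = n_cuts,
      water_lost = water_lost, composition = comp, allylic = allylic)
  }

  # molecular species: no cuts
  full <- .empty_composition()
  for (r in graph$residues) full <- .comp_add(full, r$formula)
  full <- .comp_sub(full, composition(H = 2L * n_lnk, O = n_lnk))
  emit(res_ids, character(0), 0L, 0L, full)

  if (max_cuts < 1L || n_lnk == 0L) return(out)
  for (k in seq_len(min(max_cuts, n_lnk))) {
    for (cut in as.list(as.data.frame(combn(n_lnk, k)))) {
      comps <- components(cut)
      for (comp_res in comps) {
        boundary <- cut[vapply(cut, function(i) {
          l <- lnk[[i]]
          xor(l$r1 %in% comp_res, l$r2 %in% comp_res)
        }, logical(1))]
        # components not touching every cut re-appear in smaller cut sets
        if (length(boundary) != k) next
        n_internal <- sum(vapply(lnk[setdiff(seq_len(n_lnk), cut)],
                                 function(l) l$r1 %in% comp_res &&
                                   l$r2 %in% comp_res, logical(1)))
        free_sum <- .empty_composition()
        for (r in comp_res)
          free_sum <- .comp_add(free_sum, graph$residues[[r]]$formula)
        base <- .comp_sub(free_sum,
                          composition(H = 2L * n_internal, O = n_internal))
        states <- expand.grid(rep(list(c(FALSE, TRUE)), k))  # TRUE = lose H2O
        for (si in seq_len(nrow(states))) {
          lose <- as.logical(states[si, ])
          labels <- vapply(seq_along(boundary), function(bi) {
            l <- lnk[[boundary[[bi]]]]
            on_comp_side <- l$r1 %in% comp_res
            if (lose[bi]) {
              if (on_comp_side) l$lab2 else l$lab1  # far-side bond cut
            } else {
              if (on_comp_side) l$lab1 else l$lab2  # oxygen stays here
            }
          }, character(1))
          # the glycosidic flank opposite "f" is never assigned in the
          # reference tables; its cuts only duplicate compositions reachable
          # through labelled bonds, so it is not enumerated
          if ("e" %in% labels) next
          w <- sum(lose)
          comp_f <- .comp_sub(base, composition(H = 2L * w, O = w))
          if (any(comp_f < 0)) next
          emit(comp_res, sort(labels), k, w, comp_f)
          # allylic double acid loss from one glycerol
          acyl_lost <- vapply(seq_along(boundary), function(bi) {
            l <- lnk[[boundary[[bi]]]]
            lose[bi] && grepl("^fa", if (l$r1 %in% comp_res) l$r2 else l$r1)
          }, logical(1))
          if (sum(acyl_lost) == 2L)
            emit(comp_res, sort(labels), k, w,
                 .comp_add(comp_f, composition(H = 2)), allylic = TRUE)
        }
      }
    }
  }
  out
}

.sum_tag <- function(chains) {
  paste0("(", sum(vapply(chains, `[[`, 1L, "carbons")), ":",
         sum(vapply(chains, `[[`, 1L, "double_bonds")), ")")
}

.molecular_name <- function(species) {
  tag <- .sum_tag(species$chains)
  switch(species$class,
    DAG_anchor = paste(tag, "DAG-Glc-Glc"),
    LTA_primer = paste(tag, "LTAP"),
    LTA_primer_Ala = paste(tag, "LTAP-Ala"),
    LTA_primer_Ala2 = paste(tag, "LTAP-Ala2"),
    PG = paste(tag, "PG"),
    alanyl_PG = paste(tag, "Ala-PG"),
    cardiolipin = paste(tag, "CL"),
    lyso_cardiolipin = paste(tag, "lyso-CL"))
}

# Human-readable fragment description in the vocabulary of the annotation
# tables (MAG/DAG, Glc, P, Gro, Ala; "- H"/"- H3O"/"- H5O2" water suffixes).
.render_description <- function(species, frag, adduct) {
  if (frag$n_cuts == 0L) {
    core <- .molecular_name(species)
  } else {
    ids <- frag$residues
    chains_present <- grep("^fa", ids, value = TRUE)
    chain_idx <- as.integer(sub("^fa", "", chains_present))
    n_glc <- sum(grepl("^glc", ids))
    has_gro <- "gro" %in% ids
    segs <- character(0)
    if (frag$allylic) {
      segs <- "CH2=CH-CH2"
    } else if (has_gro) {
      chs <- species$chains[chain_idx]
      segs <- if (length(chs) == 2L) paste(.sum_tag(chs), "DAG")
      else if (length(chs) == 1L) paste(.sum_tag(chs), "MAG")
      else "Gro"
    } else if (length(chain_idx) == 1L) {
      ch <- species$chains[[chain_idx]]
      segs <- paste0("(", ch[["carbons"]], ":", ch[["double_bonds"]], ") FA")
    }
    if (n_glc > 0) segs <- c(segs, rep("Glc", n_glc))
    if ("p" %in% ids) segs <- c(segs, "P")
    if ("groh" %in% ids) segs <- c(segs, "Gro")
    n_ala <- sum(grepl("^ala", ids))
    if (n_ala == 1L) segs <- c(segs, "Ala")
    if (n_ala == 2L) segs <- c(segs, "(Ala)2")
    core <- paste(segs, collapse = "-")
  }
  w <- if (frag$allylic) 0L else frag$water_lost
  suffix <- switch(adduct,
    deprotonated_anion = c("- H", "- H3O", "- H5O2", "- H7O3")[w + 1L],
    double_deprotonated_dianion = "- 2H",
    sodiated_cation = if (w == 0L) "+ Na+" else
      paste0("- ", if (w == 1L) "H2O" else paste0(w, " H2O"), " + Na+"),
    protonated_cation = if (w == 0L) "+ H+" else
      if (w == 1L) "- OH" else paste0("- OH - ", w - 1L, " H2O"))
  paste(core, suffix)
}

.default_max_cuts <- function(species) if (species$ala_count > 0L) 3L else 2L

#' Enumerate theoretical fragment ions of a lipid species
#'
#' Cuts every subset of up to `max_cuts` labelled scissile bonds of the
#' species' residue graph, emits each charge-retaining side in both water
#' states per cut (hydrolysed vs dehydrated, which is what the paired bond
#' labels such as c/d, g/h, i/j, k/l encode), applies the adduct convention
#' of the polarity (anions are deprotonated; cations are sodiated when they
#' contain a hexose and otherwise appear as dehydrated protonated ions, the
#' `[MAG - OH]+` type), and deduplicates ions with identical composition and
#' adduct, so equivalent cuts of two identical acyl chains collapse to single
#' entries. The allylic double-acid-loss channel and, for the di-alanylated
#' primer, the two rearrangement ions of [special_rearrangements()] are
#' included. Cardiolipin and lyso-cardiolipin are catalogued as molecular
#' ions only.
#'
#' @param species a [lipid_species()] or shorthand string.
#' @param polarity `"positive"` or `"negative"`; defaults to the class
#'   convention. Must be compatible with the class adducts.
#' @param max_cuts maximum simultaneous bond cuts, 1-3; defaults to 2, or 3
#'   for alanylated classes.
#' @param include_rearrangements include the di-alanylated rearrangement
#'   ions.
#' @param min_mz ions below this m/z are suppressed.
#' @return a `fragment_catalog` data frame sorted by m/z with columns `mz`,
#'   `polarity`, `adduct`, `cleavage`, `n_cuts`, `water_lost`, `formula`,
#'   `description`, `special`.
#' @examples
#' cat32 <- enumerate_fragments("(32:0) DAG-Glc-Glc")
#' subset(cat32, cleavage == "d")  # sodiated dehydrated diglucose, 347.0954
#' @export
enumerate_fragments <- function(species, polarity = NULL, max_cuts = NULL,
                                include_rearrangements = TRUE, min_mz = 50) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(inherits(species, "lipid_species"))
  info <- .CLASS_INFO[[species$class]]
  if (is.null(polarity)) polarity <- info$polarity
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (!identical(polarity, info$polarity))
    stop("polarity '", polarity, "' incompatible with class ", species$class)
  if (is.null(max_cuts)) max_cuts <- .default_max_cuts(species)
  if (max_cuts < 1 || max_cuts > 3) stop("max_cuts must be between 1 and 3")

  if (!info$fragmentable) {
    comp <- species_formula(species)
    rows <- lapply(info$adducts, function(ad) {
      data.frame(mz = ion_mz(comp, ad), polarity = polarity, adduct = ad,
                 cleavage = "M", n_cuts = 0L, water_lost = 0L,
                 formula = format_formula(comp),
                 description = paste(.molecular_name(species),
                                     if (ad == "deprotonated_anion") "- H"
                                     else "- 2H"),
                 special = FALSE, stringsAsFactors = FALSE)
    })
    cat_df <- do.call(rbind, rows)
  } else {
    graph <- .species_graph(species)
    frags <- .enumerate_graph(graph, max_cuts)
    rows <- vector("list", length(frags))
    for (i in seq_along(frags)) {
      f <- frags[[i]]
      adduct <- if (polarity == "negative") {
        "deprotonated_anion"
      } else if (any(grepl("^glc", f$residues))) {
        "sodiated_cation"
      } else {
        "protonated_cation"
      }
      if (adduct == "deprotonated_anion" && f$composition[["H"]] < 1) next
      mz <- ion_mz(f$composition, adduct)
      if (mz < min_mz) next
      cleav <- if (f$n_cuts == 0L) "M" else paste(f$labels, collapse = " & ")
      rows[[i]] <- data.frame(
        mz = mz, polarity = polarity, adduct = adduct, cleavage = cleav,
        n_cuts = f$n_cuts, water_lost = f$water_lost,
        formula = format_formula(f$composition),
        description = .render_description(species, f, adduct),
        special = FALSE, stringsAsFactors = FALSE)
    }
    cat_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    # deduplicate by (composition, adduct); keep the simplest cleavage
    ord <- order(cat_df$n_cuts, cat_df$water_lost, cat_df$cleavage)
    cat_df <- cat_df[ord, ]
    cat_df <- cat_df[!duplicated(paste(cat_df$formula, cat_df$adduct)), ]
    if (include_rearrangements && polarity == "negative") {
      sp <- special_rearrangements(species)
      if (nrow(sp)) cat_df <- rbind(cat_df, as.data.frame(sp))
    }
  }
  cat_df <- cat_df[order(cat_df$mz), ]
  rownames(cat_df) <- NULL
  structure(cat_df,
            class = c("fragment_catalog", "data.frame"),
            species = format_species(species), spec_polarity = polarity,
            max_cuts = max_cuts)
}

#' Rearrangement ions of the di-alanylated primer
#'
#' Two ions require a two-step rearrangement rather than plain bond cutting
#' and are only formed by the di-alanylated primer: the deprotonated
#' alanyl-alanine dipeptide (one alanine migrating onto the other before
#' cleavage) and the molecular anion after loss of CO2 (rearrangement
#' exposing a terminal carboxyl that decarboxylates). Any other species
#' yields an empty catalog.
#'
#' @param species a [lipid_species()] or shorthand string.
#' @return `fragment_catalog` with 0 or 2 rows.
#' @examples
#' special_rearrangements("(30:0) DAG-Glc-Glc-P-Gro-(Ala)2")
#' @export
special_rearrangements <- function(species) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(inherits(species, "lipid_species"))
  empty <- data.frame(mz = numeric(0), polarity = character(0),
                      adduct = character(0), cleavage = character(0),
                      n_cuts = integer(0), water_lost = integer(0),
                      formula = character(0), description = character(0),
                      special = logical(0), stringsAsFactors = FALSE)
  if (species$class != "LTA_primer_Ala2")
    return(structure(empty, class = c("fragment_catalog", "data.frame"),
                     species = format_species(species),
                     spec_polarity = "negative", max_cuts = 0L))
  alaala <- condense(.RES_ALANINE(), .RES_ALANINE())
  decarb <- .comp_sub(species_formula(species), composition(C = 1, O = 2))
  df <- data.frame(
    mz = c(ion_mz(alaala, "deprotonated_anion"),
           ion_mz(decarb, "deprotonated_anion")),
    polarity = "negative", adduct = "deprotonated_anion",
    cleavage = "rearrangement", n_cuts = 0L, water_lost = c(1L, 0L),
    formula = c(format_formula(alaala), format_formula(decarb)),
    description = c("Ala-Ala - H",
                    paste(.molecular_name(species), "- CO2 - H")),
    special = TRUE, stringsAsFactors = FALSE)
  structure(df, class = c("fragment_catalog", "data.frame"),
            species = format_species(species), spec_polarity = "negative",
            max_cuts = 0L)
}

#' @export
print.fragment_catalog <- function(x, n = 10, ...) {
  cat("<fragment catalog> ", attr(x, "species"), ", ",
      attr(x, "spec_polarity"), " mode, ", nrow(x), " ions\n", sep = "")
  df <- as.data.frame(x)
  df$mz <- round(df$mz, 4)
  print(head(df[, c("mz", "cleavage", "description", "formula")], n))
  if (nrow(df) > n) cat("... and", nrow(df) - n, "more ions\n")
  invisible(x)
}

.comp_of <- function(x) {
  if (inherits(x, "lipid_species")) return(species_formula(x))
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, "formula" %in% names(x))
    return(parse_formula(x$formula))
  }
  .as_comp(x)
}

#' Neutral loss between a precursor and a fragment
#'
#' Element-wise composition difference, reported with its nominal and
#' monoisotopic mass; this is the arithmetic behind statements like "neutral
#' loss of (17:0) fatty acid (270 amu)".
#'
#' @param precursor,fragment species, compositions, formula strings or
#'   single catalog rows. The fragment must be a sub-composition of the
#'   precursor.
#' @return list with `composition`, `formula`, `nominal`, `monoisotopic`.
#' @examples
#' neutral_loss(parse_species("(30:0) DAG-Glc-Glc-P-Gro-Ala"),
#'              parse_species("(30:0) DAG-Glc-Glc-P-Gro"))$nominal # 71
#' @export
neutral_loss <- function(precursor, fragment) {
  a <- .comp_of(precursor); b <- .comp_of(fragment)
  d <- .comp_sub(a, b)
  if (any(d < 0))
    stop("fragment is not a sub-composition of the precursor")
  list(composition = d, formula = format_formula(d),
       nominal = nominal_mass(d), monoisotopic = monoisotopic_mass(d))
}

#' Export a fragment catalog as TSV
#'
#' @param catalog a `fragment_catalog`.
#' @param path output file; m/z printed with 4 decimals, UTF-8, header row.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$mz <- sprintf("%.4f", df$mz)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
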