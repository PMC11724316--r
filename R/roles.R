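#' Chemical-role categories
#'
#' Every atom is assigned exactly one category used throughout the
#' classification:
#' `Oph` (OP1/OP2 anionic phosphate oxygens), `Or` (O2'/O3'/O4'/O5' ribose
#' and bridging oxygens), `Ob` (nucleobase O2/O4/O6 carbonyls), `Nb`
#' (non-protonated nucleobase N1/N3/N7), `Ow` (water oxygen), `Obb`
#' (amino-acid backbone carbonyl), `Ocoo` (Asp/Glu carboxylate), `Ocno`
#' (Asn/Gln carbonyl), `OHprot` (Ser/Thr/Tyr hydroxyl), `NHis`
#' (non-protonated His ND1/NE2), `metal`, and `other` for everything else.
#'
#' @format character vector of category names, canonical order.
#' @export
ROLE_LEVELS <- c("Oph", "Or", "Ob", "Nb", "Ocoo", "Obb", "Ocno",
                 "OHprot", "Ow", "NHis", "metal", "other")

# Canonical category order used when assembling site labels.
LABEL_ORDER <- c("Oph", "Or", "Ob", "Nb", "Ocoo", "Obb", "Ocno",
                 "OHprot", "Ow", "NHis")

LIGAND_ROLES <- c("Oph", "Or", "Ob", "Nb", "Ow", "Obb", "Ocoo",
                  "Ocno", "OHprot", "NHis")

PURINES <- c("A", "G", "DA", "DG")

# Non-protonated ring nitrogens per parent base under standard protonation:
# (G)N1, (U/T)N3, glycosidic N9/N1 and amino nitrogens are excluded.
NB_ALLOWED <- list(
  A = c("N1", "N3", "N7"),
  G = c("N3", "N7"),
  C = c("N3"),
  U = character(), `T` = character()
)

#' Default alias table for modified nucleotides
#'
#' Maps modified-residue codes to the parent base used for role templates
#' (e.g. pseudouridine O2 is a nucleobase carbonyl).  Extend by passing
#' your own tibble with columns `residue_name`, `parent` to
#' [assign_roles()].
#'
#' @return tibble with columns `residue_name`, `parent`.
#' @export
base_aliases <- function() {
  tibble::tribble(
    ~residue_name, ~parent,
    "DA", "A", "DG", "G", "DC", "C", "DT", "T", "DU", "U",
    "PSU", "U", "H2U", "U", "4SU", "U", "3MU", "U", "5MU", "T",
    "UR3", "U", "OMU", "U",
    "1MA", "A", "2MA", "A", "6MA", "A", "MA6", "A", "OMA", "A", "A2M", "A",
    "2MG", "G", "7MG", "G", "M2G", "G", "OMG", "G", "1MG", "G", "G7M", "G",
    "5MC", "C", "OMC", "C", "4OC", "C", "M4C", "C", "5HC", "C", "C5L", "C"
  )
}

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

#' Assign a chemical-role category to every atom
#'
#' Total function: every atom receives exactly one category (see
#' [ROLE_LEVELS]); O/N atoms of unknown residues degrade to `"other"` with
#' a warning naming the residues.  Waters are recognised by residue name
#' (HOH/WAT/DOD), metals by element (MG/K/NA/ZN by default).  Protonation
#' is encoded statically in the non-protonated-nitrogen template, so
#' (G)N1 and (U)N3 are never `Nb`.
#'
#' @param atoms an `mg_structure` from [read_structure()] or a fixture.
#' @param aliases tibble mapping modified residue codes to parent bases;
#'   defaults to [base_aliases()].
#' @param metals character vector of element symbols treated as metals.
#' @return the input with a `role` column appended.
#' @examples
#' st <- assign_roles(make_fixture("Oph5Ow")$atoms)
#' dplyr::count(st, role)
#' @export
assign_roles <- function(atoms, aliases = base_aliases(),
                         metals = METAL_ELEMENTS) {
  resname <- toupper(atoms$residue_name)
  parent <- aliases$parent[match(resname, toupper(aliases$residue_name))]
  base <- dplyr::coalesce(parent, resname)
  name <- atoms$name
  element <- toupper(atoms$element)

  is_water <- resname %in% WATER_RESIDUES
  is_metal <- element %in% toupper(metals) & resname %in% toupper(metals)
  is_nt <- base %in% names(NB_ALLOWED)
  is_aa <- resname %in% AMINO_ACIDS

  nb_hit <- mapply(function(b, n) n %in% NB_ALLOWED[[b]],
                   ifelse(is_nt, base, "U"), name)

  role <- dplyr::case_when(
    element == "H" ~ "other",
    is_metal ~ "metal",
    is_water & element == "O" ~ "Ow",
    is_nt & name %in% c("OP1", "OP2") ~ "Oph",
    is_nt & name %in% c("O2'", "O3'", "O4'", "O5'") ~ "Or",
    is_nt & name %in% c("O2", "O4", "O6") ~ "Ob",
    is_nt & nb_hit ~ "Nb",
    is_aa & name %in% c("O", "OXT") ~ "Obb",
    resname %in% c("ASP") & name %in% c("OD1", "OD2") ~ "Ocoo",
    resname %in% c("GLU") & name %in% c("OE1", "OE2") ~ "Ocoo",
    resname %in% c("ASN") & name == "OD1" ~ "Ocno",
    resname %in% c("GLN") & name == "OE1" ~ "Ocno",
    resname == "SER" & name == "OG" ~ "OHprot",
    resname == "THR" & name == "OG1" ~ "OHprot",
    resname == "TYR" & name == "OH" ~ "OHprot",
    resname == "HIS" & name %in% c("ND1", "NE2") ~ "NHis",
    .default = "other"
  )

  unknown <- element %in% c("O", "N") & role == "other" &
    !is_water & !is_nt & !is_aa & !is_metal
  if (any(unknown)) {
    rlang::warn(paste0(
      "O/N atoms of unknown residue(s) categorised 'other': ",
      paste(unique(resname[unknown]), collapse = ", ")))
  }
  atoms$role <- role
  atoms
}

require_roles <- function(atoms) {
  if (!"role" %in% names(atoms)) {
    rlang::abort("atom table has no 'role' column; run assign_roles() first")
  }
  atoms
}
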