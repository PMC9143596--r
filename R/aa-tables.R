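# Shared amino-acid tables: the 20 standard residues, the binary
# physicochemical property sets used for column conservation, the
# side-chain class partition used for sequence-space maps, and an
# element-based vdW radius table for SASA.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. All enumeration and
#' classification routines in the package are restricted to this set.
#'
#' @return Character vector of 20 one-letter codes.
#' @export
standard_aa <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Binary physicochemical property table
#'
#' Ten binary properties per residue (hydrophobic, polar, small, tiny,
#' aliphatic, aromatic, charged, positive, negative, proline), following
#' the classic set-based classification of amino-acid physicochemistry
#' used by alignment viewers for conservation shading. Column
#' conservation counts how many of these properties have uniform
#' membership status down an alignment column.
#'
#' @return Logical matrix, 20 residues (rows) by 10 properties (columns).
#' @seealso [column_conservation()]
#' @export
aa_property_table <- function() {
  props <- list(
    hydrophobic = c("A", "C", "F", "G", "H", "I", "K", "L", "M", "T",
                    "V", "W", "Y"),
    polar       = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T",
                    "W", "Y"),
    small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    tiny        = c("A", "G", "S"),
    aliphatic   = c("I", "L", "V"),
    aromatic    = c("F", "H", "W", "Y"),
    charged     = c("D", "E", "H", "K", "R"),
    positive    = c("H", "K", "R"),
    negative    = c("D", "E"),
    proline     = "P"
  )
  aa <- standard_aa()
  tab <- vapply(props, function(members) aa %in% members,
                logical(length(aa)))
  rownames(tab) <- aa
  tab
}

#' Default side-chain class partition (P1-P6)
#'
#' Partition of the 20 standard amino acids into six side-chain classes
#' used to coarse-grain site-saturation sequence-space maps: P1 small
#' aliphatic, P2 aromatic, P3 polar uncharged, P4 positively charged,
#' P5 negatively charged, P6 reserved (empty by default, available for
#' user re-partitions). The partition is editable: pass a modified copy
#' to [classify_residue()] or [class_map()]; every map output records the
#' table that produced it.
#'
#' @return Named list of character vectors, classes `P1` to `P6`.
#' @export
residue_class_table <- function() {
  list(
    P1 = c("G", "A", "V", "L", "I", "P"),
    P2 = c("F", "Y", "W"),
    P3 = c("S", "T", "N", "Q", "C", "M"),
    P4 = c("K", "R", "H"),
    P5 = c("D", "E"),
    P6 = character(0)
  )
}

#' Classify a residue into its side-chain class
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @param class_table Class partition as returned by
#'   [residue_class_table()]. Must partition the 20 standard residues.
#' @return Character vector of class ids (e.g. `"P2"`).
#' @examples
#' classify_residue("D")  # "P5" (negatively charged)
#' classify_residue("F")  # "P2" (aromatic)
#' @export
classify_residue <- function(aa, class_table = residue_class_table()) {
  validate_class_table(class_table)
  lookup <- class_table_lookup(class_table)
  bad <- !aa %in% names(lookup)
  if (any(bad)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  unname(lookup[aa])
}

class_table_lookup <- function(class_table) {
  members <- unlist(class_table, use.names = FALSE)
  stats::setNames(rep(names(class_table), lengths(class_table)), members)
}

validate_class_table <- function(class_table) {
  members <- unlist(class_table, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("class table is not a partition: duplicated residue(s) ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  missing <- setdiff(standard_aa(), members)
  if (length(missing)) {
    stop("class table is not a partition: missing residue(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(class_table)
}

#' Element-based van der Waals radii
#'
#' Standard Bondi-type radii in Angstrom, used to expand atoms by the
#' probe radius in Shrake-Rupley SASA. Editable: pass a modified named
#' vector to [sasa()].
#'
#' @return Named numeric vector of radii (Angstrom) keyed by element symbol.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

# Three-letter -> one-letter residue code mapping for topology handling.
aa_three_to_one <- function() {
  c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
    HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
    PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
    TRP = "W", TYR = "Y")
}
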