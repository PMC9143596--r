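# Multiple-sequence-alignment handling: readers, pairwise identity,
# physicochemical column conservation, and candidate-site nomination.

GAP_CHARS <- c("-", ".")

#' Construct an aligned sequence set
#'
#' @param ids Character vector of sequence identifiers.
#' @param rows Character vector of equal-length gapped amino-acid strings
#'   (same length as `ids`).
#' @param ref_id Identifier of the reference enzyme; used to build the
#'   column-to-reference-residue map.
#' @return An object of class `aligned_set`: list with elements `ids`,
#'   `rows` (named by id), `ref_id` and `column_to_ref` (integer vector,
#'   one entry per alignment column; `NA` where the reference has a gap,
#'   otherwise the 1-based reference residue number).
#' @export
aligned_set <- function(ids, rows, ref_id) {
  if (length(ids) != length(rows)) {
    stop("ids and rows must have the same length")
  }
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("alignment format error: records have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  }
  if (!ref_id %in% ids) {
    stop("reference id '", ref_id, "' not found in alignment")
  }
  names(rows) <- ids
  ref_chars <- aln_chars(rows[[ref_id]])
  is_gap <- ref_chars %in% GAP_CHARS
  column_to_ref <- rep(NA_integer_, length(ref_chars))
  column_to_ref[!is_gap] <- seq_len(sum(!is_gap))
  structure(
    list(ids = ids, rows = rows, ref_id = ref_id,
         column_to_ref = column_to_ref),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set: ", length(x$ids), " sequences, ",
      nchar(x$rows[[1]]), " columns, reference '", x$ref_id, "'\n",
      sep = "")
  invisible(x)
}

aln_chars <- function(row) strsplit(row, "", fixed = TRUE)[[1]]

aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, aln_chars))
}

#' Read an alignment from file
#'
#' Supports aligned FASTA and Clustal. All records must have equal
#' (gapped) length.
#'
#' @param path Path to the alignment file.
#' @param ref_id Reference sequence identifier (defaults to the first
#'   record).
#' @param format `"fasta"` or `"clustal"`; guessed from the file
#'   extension / first line when omitted.
#' @return An [aligned_set()].
#' @export
read_alignment <- function(path, ref_id = NULL,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- if (format == "clustal") {
    seqinr::read.alignment(path, format = "clustal",
                           forceToLower = FALSE, oldclustal = TRUE)
  } else {
    seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  }
  ids <- aln$nam
  rows <- toupper(unlist(aln$seq, use.names = FALSE))
  if (is.null(ref_id)) ref_id <- ids[[1L]]
  aligned_set(ids, rows, ref_id)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An [aligned_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$ids), unname(aln$rows)))
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise percent identity between two aligned sequences
#'
#' Identity = 100 x (columns where both rows carry the same non-gap
#' residue) / (columns where at least one row is non-gap). Columns where
#' both rows are gaps do not count.
#'
#' @param aln An [aligned_set()].
#' @param id_a,id_b Sequence identifiers.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(aln, id_a, id_b) {
  for (id in c(id_a, id_b)) {
    if (!id %in% aln$ids) stop("unknown sequence id '", id, "'")
  }
  a <- aln_chars(aln$rows[[id_a]])
  b <- aln_chars(aln$rows[[id_b]])
  gap_a <- a %in% GAP_CHARS
  gap_b <- b %in% GAP_CHARS
  denom <- sum(!(gap_a & gap_b))
  if (denom == 0L) stop("both sequences are all gaps")
  matches <- sum(!gap_a & !gap_b & a == b)
  100 * matches / denom
}

#' Physicochemical conservation score per alignment column
#'
#' For each column, the score is the number of binary physicochemical
#' properties (see [aa_property_table()]) whose membership status is
#' uniform across all non-gap residues in the column -- i.e. every
#' residue has the property, or none does. A column of identical
#' residues scores 11 (the "identity" grade, rendered `*` by alignment
#' viewers); mixed columns score 0-10. Gaps are skipped; an all-gap
#' column scores 0 and is flagged.
#'
#' @param aln An [aligned_set()].
#' @param property_table Logical residue-by-property matrix
#'   ([aa_property_table()] by default).
#' @param gap_flag_frac Columns with a gap fraction above this value are
#'   flagged low-confidence (default 0.5).
#' @return Integer vector of per-column scores with attributes
#'   `all_gap` (logical) and `low_confidence` (logical).
#' @export
column_conservation <- function(aln,
                                property_table = aa_property_table(),
                                gap_flag_frac = 0.5) {
  mat <- aln_matrix(aln)
  if (ncol(mat) == 0L) stop("empty alignment")
  n_props <- ncol(property_table)
  scores <- integer(ncol(mat))
  all_gap <- logical(ncol(mat))
  low_conf <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[!col %in% GAP_CHARS]
    gap_frac <- 1 - length(res) / length(col)
    low_conf[j] <- gap_frac > gap_flag_frac
    if (length(res) == 0L) {
      all_gap[j] <- TRUE
      scores[j] <- 0L
      next
    }
    bad <- !res %in% rownames(property_table)
    if (any(bad)) {
      stop("column ", j, ": unknown residue code(s) ",
           paste(unique(res[bad]), collapse = ", "))
    }
    if (length(unique(res)) == 1L) {
      scores[j] <- n_props + 1L
      next
    }
    sub <- property_table[unique(res), , drop = FALSE]
    uniform <- colSums(sub) %in% c(0L, nrow(sub))
    scores[j] <- sum(uniform)
  }
  structure(scores, all_gap = all_gap, low_confidence = low_conf)
}

#' Build a site-annotation table
#'
#' @param residue_number Integer vector of 1-based reference positions.
#' @param amino_acid One-letter codes at those positions.
#' @param region `"loop"` or `"non-loop"` per site.
#' @param conservation Integer conservation scores in `[0, 11]`.
#' @param catalytic Logical: catalytic-triad membership.
#' @param near_active_site Logical: loop residues flagged as lining the
#'   active site (an input annotation read off the structure, not
#'   computed here).
#' @return A `data.frame` of class `site_annotation`.
#' @export
site_annotation <- function(residue_number, amino_acid, region,
                            conservation,
                            catalytic = FALSE,
                            near_active_site = FALSE) {
  n <- length(residue_number)
  region <- match.arg(region, c("loop", "non-loop"),
                      several.ok = TRUE)
  df <- data.frame(
    residue_number = as.integer(residue_number),
    amino_acid = rep_len(amino_acid, n),
    region = rep_len(region, n),
    conservation = as.integer(rep_len(conservation, n)),
    catalytic = rep_len(catalytic, n),
    near_active_site = rep_len(near_active_site, n),
    stringsAsFactors = FALSE
  )
  if (any(df$conservation < 0L | df$conservation > 11L)) {
    stop("conservation scores must lie in [0, 11]")
  }
  class(df) <- c("site_annotation", "data.frame")
  df
}

#' Read site annotations from a YAML/JSON config
#'
#' The config is a list of records with fields `residue_number`,
#' `amino_acid`, `region`, `conservation`, and optional `catalytic` and
#' `near_active_site`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [site_annotation()] table.
#' @export
read_site_config <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  get0s <- function(rec, field, default) {
    if (is.null(rec[[field]])) default else rec[[field]]
  }
  site_annotation(
    residue_number = vapply(recs, `[[`, numeric(1), "residue_number"),
    amino_acid = vapply(recs, `[[`, character(1), "amino_acid"),
    region = vapply(recs, `[[`, character(1), "region"),
    conservation = vapply(recs, `[[`, numeric(1), "conservation"),
    catalytic = vapply(recs, get0s, logical(1), "catalytic", FALSE),
    near_active_site = vapply(recs, get0s, logical(1),
                              "near_active_site", FALSE)
  )
}

#' Nominate candidate mutation sites
#'
#' A site is nominated when it is a loop residue flagged near the active
#' site, or a non-loop residue with conservation strictly below
#' `score_cutoff`, or explicitly listed in `overrides` (sites reported
#' by earlier mutagenesis studies, included for validation despite their
#' score). Catalytic residues are never nominated; naming one in
#' `overrides` is an error.
#'
#' @param annotations A [site_annotation()] table.
#' @param score_cutoff Conservation cutoff; strict `<` (default 6).
#' @param overrides Integer vector of residue numbers to force-include.
#' @return The annotation table with logical columns `nominated` and
#'   `override` added.
#' @export
nominate_sites <- function(annotations, score_cutoff = 6,
                           overrides = integer(0)) {
  overrides <- as.integer(overrides)
  bad_cat <- intersect(overrides,
                       annotations$residue_number[annotations$catalytic])
  if (length(bad_cat)) {
    stop("override names catalytic residue(s): ",
         paste(bad_cat, collapse = ", "))
  }
  unknown <- setdiff(overrides, annotations$residue_number)
  if (length(unknown)) {
    stop("override names unannotated residue(s): ",
         paste(unknown, collapse = ", "))
  }
  rule <- (annotations$region == "loop" & annotations$near_active_site) |
    (annotations$region == "non-loop" &
       annotations$conservation < score_cutoff)
  override <- annotations$residue_number %in% overrides
  annotations$override <- override
  annotations$nominated <- (rule | override) & !annotations$catalytic
  annotations
}

#' Write site annotations as TSV
#'
#' @param annotations A [site_annotation()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
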