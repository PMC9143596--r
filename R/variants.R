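# Variant and library enumeration: exact combination counts,
# combinatorial alanine scanning, and single/double site-saturation
# mutagenesis grids.

#' Exact binomial coefficient
#'
#' Number of ways to choose `r` mutation sites from `n` candidates,
#' n! / ((n-r)! r!), as an exact integer-valued double.
#'
#' @param n Total number of candidate sites (non-negative integer).
#' @param r Number of sites chosen, `0 <= r <= n`.
#' @return The count as a numeric scalar.
#' @examples
#' count_combinations(8, 4)  # 70
#' @export
count_combinations <- function(n, r) {
  if (length(n) != 1L || length(r) != 1L ||
      n < 0 || r < 0 || r > n ||
      n != round(n) || r != round(r)) {
    stop("require integers 0 <= r <= n")
  }
  round(choose(n, r))
}

#' Canonical variant label
#'
#' Substitutions are rendered `<WT><position><new>` and joined with `/`
#' in ascending position order (e.g. `"D112M/S238F"`); the wild type is
#' labelled `"WT"`.
#'
#' @param sites Integer vector of residue numbers.
#' @param wt_aas One-letter WT residues at those sites.
#' @param new_aas One-letter substituted residues.
#' @return A single label string.
#' @export
variant_label <- function(sites, wt_aas, new_aas) {
  if (length(sites) == 0L) return("WT")
  if (any(wt_aas == new_aas)) {
    stop("self-substitution in label: ",
         paste0(wt_aas, sites, new_aas)[wt_aas == new_aas][1])
  }
  ord <- order(sites)
  paste0(wt_aas[ord], sites[ord], new_aas[ord], collapse = "/")
}

new_variant <- function(sites, wt_aas, new_aas) {
  ord <- order(sites)
  list(
    sites = as.integer(sites[ord]),
    wt_aas = wt_aas[ord],
    new_aas = new_aas[ord],
    label = variant_label(sites, wt_aas, new_aas)
  )
}

new_library <- function(variants, scheme, sites, wt_residues,
                        includes_wt) {
  labels <- vapply(variants, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate variant labels in library")
  }
  structure(
    list(variants = variants, labels = labels, scheme = scheme,
         sites = as.integer(sites), wt_residues = wt_residues,
         includes_wt = includes_wt),
    class = "variant_library"
  )
}

#' @export
print.variant_library <- function(x, ...) {
  cat("variant_library [", x$scheme, "]: ", length(x$variants),
      " variants over sites ", paste(x$sites, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.variant_library <- function(x) length(x$variants)

#' @export
as.data.frame.variant_library <- function(x, ...) {
  df <- data.frame(
    label = x$labels,
    r = vapply(x$variants, function(v) length(v$sites), integer(1)),
    substitutions = vapply(x$variants, function(v) {
      if (length(v$sites) == 0L) return("")
      paste0(v$sites, ":", v$new_aas, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  df$sites <- I(lapply(x$variants, `[[`, "sites"))
  df$new_aas <- I(lapply(x$variants, `[[`, "new_aas"))
  df
}

check_sites <- function(sites, catalytic_sites) {
  if (anyDuplicated(sites)) stop("duplicate sites")
  bad <- intersect(sites, catalytic_sites)
  if (length(bad)) {
    stop("catalytic residue(s) cannot be mutated: ",
         paste(bad, collapse = ", "))
  }
  invisible(sites)
}

#' Combinatorial alanine-scanning library
#'
#' Enumerates one variant per subset of the candidate sites of size
#' `r` in `[r_min, r_max]`, substituting every chosen site with alanine.
#' With all 2^n - 1 non-empty subsets of 8 sites this yields the
#' 8/28/56/70/56/28/8/1 (total 255) library. Variants are ordered by
#' `r`, then lexicographically by label.
#'
#' @param sites Integer vector of distinct candidate residue numbers.
#' @param wt_residues Named character vector: WT one-letter residue per
#'   site (names = residue numbers). No site may already be alanine.
#' @param r_min,r_max Subset-size range (defaults 1 to `length(sites)`).
#' @param catalytic_sites Residue numbers that must never appear.
#' @return A `variant_library` with scheme `"asm_combinatorial"`.
#' @export
alanine_combinatorial <- function(sites, wt_residues,
                                  r_min = 1L, r_max = length(sites),
                                  catalytic_sites = integer(0)) {
  sites <- as.integer(sites)
  check_sites(sites, catalytic_sites)
  wt <- wt_residues[as.character(sites)]
  if (anyNA(wt)) {
    stop("wt_residues missing for site(s): ",
         paste(sites[is.na(wt)], collapse = ", "))
  }
  if (any(wt == "A")) {
    stop("site(s) already alanine in the wild type: ",
         paste(sites[wt == "A"], collapse = ", "))
  }
  if (r_min < 1L || r_max > length(sites) || r_min > r_max) {
    stop("require 1 <= r_min <= r_max <= number of sites")
  }
  variants <- list()
  for (r in seq(r_min, r_max)) {
    subsets <- if (length(sites) == 1L) {
      list(sites)
    } else {
      utils::combn(sort(sites), r, simplify = FALSE)
    }
    vs <- lapply(subsets, function(s) {
      new_variant(s, wt_residues[as.character(s)], rep("A", length(s)))
    })
    labels <- vapply(vs, `[[`, character(1), "label")
    variants <- c(variants, vs[order(labels)])
  }
  new_library(variants, "asm_combinatorial", sites, wt_residues,
              includes_wt = FALSE)
}

#' Single-site saturation library
#'
#' All 19 substitutions of one site (every standard amino acid except
#' the WT residue), optionally with a WT record, giving 20 rows per
#' site.
#'
#' @param site Residue number (not catalytic).
#' @param wt_residue One-letter WT residue at the site.
#' @param include_wt Include the unmutated record (default `TRUE`).
#' @param catalytic_sites Residue numbers that must never appear.
#' @return A `variant_library` with scheme `"ssm_single"`.
#' @export
ssm_single <- function(site, wt_residue, include_wt = TRUE,
                       catalytic_sites = integer(0)) {
  site <- as.integer(site)
  check_sites(site, catalytic_sites)
  if (!wt_residue %in% standard_aa()) {
    stop("non-standard wt residue '", wt_residue, "'")
  }
  wt_residues <- stats::setNames(wt_residue, as.character(site))
  variants <- lapply(setdiff(standard_aa(), wt_residue), function(aa) {
    new_variant(site, wt_residue, aa)
  })
  if (include_wt) {
    variants <- c(list(new_variant(integer(0), character(0),
                                   character(0))), variants)
  }
  new_library(variants, "ssm_single", site, wt_residues, include_wt)
}

#' Double-site saturation library
#'
#' The full 20 x 20 grid over two sites: 1 WT row, 2 x 19 single
#' substitutions and 19^2 = 361 double substitutions, 400 rows total.
#'
#' @param site_a,site_b Distinct residue numbers (not catalytic).
#' @param wt_a,wt_b One-letter WT residues at the two sites.
#' @param catalytic_sites Residue numbers that must never appear.
#' @return A `variant_library` with scheme `"ssm_double"`.
#' @export
ssm_double <- function(site_a, site_b, wt_a, wt_b,
                       catalytic_sites = integer(0)) {
  site_a <- as.integer(site_a); site_b <- as.integer(site_b)
  if (site_a == site_b) stop("site_a and site_b must differ")
  check_sites(c(site_a, site_b), catalytic_sites)
  for (wt in c(wt_a, wt_b)) {
    if (!wt %in% standard_aa()) {
      stop("non-standard wt residue '", wt, "'")
    }
  }
  wt_residues <- stats::setNames(c(wt_a, wt_b),
                                 as.character(c(site_a, site_b)))
  variants <- list()
  for (aa_a in standard_aa()) {
    for (aa_b in standard_aa()) {
      sub_a <- aa_a != wt_a
      sub_b <- aa_b != wt_b
      sites <- c(if (sub_a) site_a, if (sub_b) site_b)
      variants[[length(variants) + 1L]] <- new_variant(
        as.integer(sites),
        c(if (sub_a) wt_a, if (sub_b) wt_b),
        c(if (sub_a) aa_a, if (sub_b) aa_b)
      )
    }
  }
  new_library(variants, "ssm_double", c(site_a, site_b), wt_residues,
              includes_wt = TRUE)
}

#' Export a variant library as TSV
#'
#' Columns: `label`, `r`, `substitutions` (comma-joined `site:aa`
#' pairs, empty for WT).
#'
#' @param library A `variant_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  df <- as.data.frame(library)
  utils::write.table(df[, c("label", "r", "substitutions")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant library TSV
#'
#' @param path Path written by [write_library()].
#' @param scheme Scheme tag to attach.
#' @param wt_residues Named character vector of WT residues per site.
#' @return A `variant_library`.
#' @export
read_library <- function(path, scheme = "imported",
                         wt_residues = character(0)) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "character"))
  df$substitutions[is.na(df$substitutions)] <- ""
  variants <- lapply(df$substitutions, function(s) {
    if (!nzchar(s)) {
      return(new_variant(integer(0), character(0), character(0)))
    }
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    sites <- as.integer(vapply(parts, `[[`, character(1), 1L))
    aas <- vapply(parts, `[[`, character(1), 2L)
    wt <- wt_residues[as.character(sites)]
    if (anyNA(wt)) stop("wt_residues missing for imported site(s)")
    new_variant(sites, wt, aas)
  })
  sites <- sort(unique(unlist(lapply(variants, `[[`, "sites"))))
  new_library(variants, scheme, sites, wt_residues,
              includes_wt = any(df$r == 0L))
}
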