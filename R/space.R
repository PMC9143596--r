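# Sequence-space summaries: deltadeltaG distributions by mutation count,
# fixed-site maps over combinatorial alanine-scan records, and
# side-chain-class maps over site-saturation grids.

new_space_map <- function(kind, axes, values, n, aggregator,
                          excluded_n = 0L, class_table = NULL) {
  structure(list(kind = kind, axes = axes, values = values, n = n,
                 aggregator = aggregator, excluded_n = excluded_n,
                 class_table = class_table),
            class = "space_map")
}

#' @export
print.space_map <- function(x, ...) {
  cat("space_map [", x$kind, "], aggregator = ", x$aggregator,
      ", cells = ", length(x$values),
      ", records excluded (undefined deltaG) = ", x$excluded_n, "\n",
      sep = "")
  invisible(x)
}

drop_undefined <- function(records) {
  keep <- !is.na(records$delta_delta_g)
  structure(records[keep, , drop = FALSE],
            excluded_n = sum(!keep))
}

aggregate_fun <- function(aggregator) {
  switch(aggregator,
         min = function(x) min(x),
         mean = function(x) mean(x),
         median = function(x) stats::median(x),
         stop("unknown aggregator '", aggregator,
              "' (use min, mean or median)"))
}

#' deltadeltaG distribution by number of mutation sites
#'
#' Summarizes screen records per mutation count r: n, min, quartiles,
#' mean, max. Rows for r values with no records carry `n = 0` and `NA`
#' summaries.
#'
#' @param records Screen-record `data.frame` with columns `r` and
#'   `delta_delta_g` (records with `NA` deltadeltaG are excluded and
#'   counted in the `excluded_n` element).
#' @param r_max Largest r row to emit (default: max observed).
#' @return A `space_map` of kind `"mutation_count"` whose `values` is
#'   the per-r summary `data.frame`.
#' @export
map_by_mutation_count <- function(records, r_max = NULL) {
  records <- drop_undefined(records)
  excluded <- attr(records, "excluded_n")
  if (is.null(r_max)) r_max <- max(records$r, 1L)
  rows <- lapply(seq_len(r_max), function(r) {
    v <- records$delta_delta_g[records$r == r]
    if (length(v) == 0L) {
      return(data.frame(r = r, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_,
                        mean = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(r = r, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], mean = mean(v), max = max(v))
  })
  summary <- do.call(rbind, rows)
  new_space_map("mutation_count", axes = list(r = seq_len(r_max)),
                values = summary, n = summary$n, aggregator = "summary",
                excluded_n = excluded)
}

#' Fixed-site map over combinatorial records
#'
#' Matrix indexed (r, site): the aggregate deltadeltaG over all variants
#' of size r that contain the given site. Each size-r variant therefore
#' contributes to exactly r cells of row r. Default aggregator is `min`
#' (the screening question: does any variant containing this site
#' improve binding?).
#'
#' @param records Screen-record `data.frame` with columns `r`,
#'   `delta_delta_g` and a list-column `sites` (integer vectors).
#' @param sites Site axis (default: all sites observed).
#' @param aggregator `"min"`, `"mean"` or `"median"`.
#' @return A `space_map` of kind `"fixed_site"` with matrices `values`
#'   and `n` (rows r, columns sites). Sites absent from every record
#'   give all-`NA` columns, flagged in `empty_sites`.
#' @export
fixed_site_map <- function(records, sites = NULL, aggregator = "min") {
  agg <- aggregate_fun(aggregator)
  records <- drop_undefined(records)
  excluded <- attr(records, "excluded_n")
  observed <- sort(unique(unlist(records$sites)))
  if (is.null(sites)) sites <- observed
  sites <- as.integer(sites)
  r_max <- max(records$r, 1L)
  values <- matrix(NA_real_, nrow = r_max, ncol = length(sites),
                   dimnames = list(r = seq_len(r_max),
                                   site = as.character(sites)))
  counts <- matrix(0L, nrow = r_max, ncol = length(sites),
                   dimnames = dimnames(values))
  for (j in seq_along(sites)) {
    has_site <- vapply(records$sites, function(s) sites[j] %in% s,
                       logical(1))
    for (r in seq_len(r_max)) {
      v <- records$delta_delta_g[has_site & records$r == r]
      counts[r, j] <- length(v)
      if (length(v)) values[r, j] <- agg(v)
    }
  }
  m <- new_space_map("fixed_site", axes = list(r = seq_len(r_max),
                                               site = sites),
                     values = values, n = counts,
                     aggregator = aggregator, excluded_n = excluded)
  m$empty_sites <- sites[colSums(counts) == 0L]
  m
}

aa_at_site <- function(records, site, wt_residues) {
  wt <- wt_residues[[as.character(site)]]
  if (is.null(wt)) stop("wt_residues missing for site ", site)
  vapply(seq_len(nrow(records)), function(i) {
    s <- records$sites[[i]]
    k <- match(site, s)
    if (is.na(k)) wt else records$new_aas[[i]][k]
  }, character(1))
}

#' Side-chain-class map over site-saturation records
#'
#' For a single-site saturation library, aggregates deltadeltaG per
#' amino acid (20 cells, ordered by class) and per class (6 cells). For
#' a double grid, builds the 20 x 20 amino-acid matrix ordered by class
#' and the 6 x 6 class-aggregated matrix. Cells carry the aggregate and
#' the record count; the class table used is recorded in the output.
#'
#' @param records Screen-record `data.frame` with `delta_delta_g` and
#'   list-columns `sites` / `new_aas`.
#' @param site_axes One or two residue numbers defining the axes.
#' @param wt_residues Named character vector giving the WT residue at
#'   each axis site (unmutated records count under the WT residue).
#' @param aggregator `"mean"` (default), `"min"` or `"median"`.
#' @param class_table Class partition ([residue_class_table()]).
#' @return A `space_map` of kind `"class_single"` or `"class_double"`;
#'   elements `values`/`n` are the amino-acid level map and
#'   `class_values`/`class_n` the class-level aggregation.
#' @export
class_map <- function(records, site_axes, wt_residues,
                      aggregator = "mean",
                      class_table = residue_class_table()) {
  validate_class_table(class_table)
  agg <- aggregate_fun(aggregator)
  records <- drop_undefined(records)
  excluded <- attr(records, "excluded_n")
  aa_order <- unlist(class_table, use.names = FALSE)
  class_of <- class_table_lookup(class_table)
  classes <- names(class_table)
  axis_aa <- lapply(site_axes, aa_at_site, records = records,
                    wt_residues = wt_residues)
  if (length(site_axes) == 1L) {
    values <- stats::setNames(rep(NA_real_, length(aa_order)), aa_order)
    counts <- stats::setNames(rep(0L, length(aa_order)), aa_order)
    for (aa in aa_order) {
      v <- records$delta_delta_g[axis_aa[[1]] == aa]
      counts[aa] <- length(v)
      if (length(v)) values[aa] <- agg(v)
    }
    class_values <- stats::setNames(rep(NA_real_, length(classes)),
                                    classes)
    class_n <- stats::setNames(rep(0L, length(classes)), classes)
    for (cl in classes) {
      v <- records$delta_delta_g[class_of[axis_aa[[1]]] == cl]
      class_n[cl] <- length(v)
      if (length(v)) class_values[cl] <- agg(v)
    }
    m <- new_space_map("class_single",
                       axes = list(site = site_axes[[1]],
                                   aa = aa_order, class = classes),
                       values = values, n = counts,
                       aggregator = aggregator, excluded_n = excluded,
                       class_table = class_table)
    m$class_values <- class_values
    m$class_n <- class_n
    return(m)
  }
  if (length(site_axes) != 2L) stop("site_axes must have length 1 or 2")
  dn <- list(aa_a = aa_order, aa_b = aa_order)
  values <- matrix(NA_real_, 20, 20, dimnames = dn)
  counts <- matrix(0L, 20, 20, dimnames = dn)
  for (i in seq_len(nrow(records))) {
    a <- axis_aa[[1]][i]; b <- axis_aa[[2]][i]
    counts[a, b] <- counts[a, b] + 1L
  }
  # aggregate amino-acid cells
  key <- paste(axis_aa[[1]], axis_aa[[2]])
  split_v <- split(records$delta_delta_g, key)
  for (k in names(split_v)) {
    ab <- strsplit(k, " ", fixed = TRUE)[[1]]
    values[ab[1], ab[2]] <- agg(split_v[[k]])
  }
  cdn <- list(class_a = classes, class_b = classes)
  class_values <- matrix(NA_real_, length(classes), length(classes),
                         dimnames = cdn)
  class_n <- matrix(0L, length(classes), length(classes),
                    dimnames = cdn)
  ckey <- paste(class_of[axis_aa[[1]]], class_of[axis_aa[[2]]])
  csplit <- split(records$delta_delta_g, ckey)
  for (k in names(csplit)) {
    ab <- strsplit(k, " ", fixed = TRUE)[[1]]
    class_values[ab[1], ab[2]] <- agg(csplit[[k]])
    class_n[ab[1], ab[2]] <- length(csplit[[k]])
  }
  m <- new_space_map("class_double",
                     axes = list(site_a = site_axes[[1]],
                                 site_b = site_axes[[2]],
                                 aa = aa_order, class = classes),
                     values = values, n = counts,
                     aggregator = aggregator, excluded_n = excluded,
                     class_table = class_table)
  m$class_values <- class_values
  m$class_n <- class_n
  m
}

#' Export a space map as long-form TSV
#'
#' One row per cell with its axis values, aggregate and count.
#'
#' @param map A `space_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_space_map <- function(map, path) {
  df <- space_map_long(map)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

space_map_long <- function(map) {
  if (map$kind == "mutation_count") {
    return(map$values)
  }
  if (is.matrix(map$values)) {
    dn <- dimnames(map$values)
    df <- expand.grid(a = dn[[1]], b = dn[[2]],
                      stringsAsFactors = FALSE)
    names(df) <- names(dn)
    df$value <- as.vector(map$values)
    df$n <- as.vector(map$n)
    return(df)
  }
  data.frame(cell = names(map$values),
             value = unname(map$values), n = unname(map$n),
             stringsAsFactors = FALSE)
}

#' Export a space map as JSON
#'
#' @param map A `space_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_space_map_json <- function(map, path) {
  payload <- list(kind = map$kind, aggregator = map$aggregator,
                  excluded_n = map$excluded_n,
                  cells = space_map_long(map),
                  class_table = map$class_table)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
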