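# Domain tables and CSV I/O: trees, ring series, atmospheres.

# Eight crown illumination classes, in increasing order of light exposure.
CII_CLASSES <- c("1", "2a", "2b", "2c", "3a", "3b", "4", "5")

FOREST_TYPES <- c("temperate", "tropical", "open")

TREE_COLUMNS <- c("tree_id", "species", "site_id", "forest_type",
                  "sampling_year", "age_years", "dbh_cm", "height_m",
                  "cii_class", "d13c_outer_permil")

RING_COLUMNS <- c("tree_id", "calendar_year", "ring_index",
                  "block_span_years", "d13c_permil")

ATMOS_COLUMNS <- c("year", "ca_ppm", "d13c_air_permil")

# Plausibility window for C3 wood delta13C; outside it we warn, never reject.
D13C_HARD_RANGE <- c(-40, -10)
D13C_SOFT_RANGE <- c(-35, -18)

#' Crown illumination class to ordinal score
#'
#' Maps the eight field classes of the modified crown illumination index
#' (1, 2a, 2b, 2c, 3a, 3b, 4, 5) onto the ordered scores 1..8, from
#' understory crowns receiving no direct light (1) to crowns with full
#' overhead and lateral exposure (8). The map is the order-preserving
#' bijection onto the class sequence.
#'
#' @param cii_class Character vector of class labels.
#' @return Integer vector in 1..8.
#' @examples
#' cii_to_ordinal(c("1", "2b", "5"))
#' @export
cii_to_ordinal <- function(cii_class) {
  idx <- match(as.character(cii_class), CII_CLASSES)
  if (anyNA(idx))
    stop(sprintf("unknown crown illumination class: %s",
                 paste(unique(cii_class[is.na(idx)]), collapse = ", ")))
  idx
}

#' Estimate rings missing between core and pith
#'
#' When an increment core misses the pith, the number of unrepresented rings
#' is estimated as the distance to the pith divided by the mean ring width of
#' the species and diameter class, rounded half away from zero.
#'
#' @param distance_to_pith_mm Distance from the innermost sampled ring to the
#'   geometric pith, mm (>= 0).
#' @param mean_ring_width_mm Mean ring width for the species/diameter class,
#'   mm (> 0). Typically supplied from a user-side lookup table.
#' @return Non-negative integer count of missing rings.
#' @examples
#' estimate_missing_rings(10, 2)  # 5
#' estimate_missing_rings(7, 2)   # 3.5 -> 4
#' @export
estimate_missing_rings <- function(distance_to_pith_mm, mean_ring_width_mm) {
  if (any(mean_ring_width_mm <= 0))
    stop("mean_ring_width_mm must be positive")
  if (any(distance_to_pith_mm < 0))
    stop("distance_to_pith_mm must be non-negative")
  x <- distance_to_pith_mm / mean_ring_width_mm
  as.integer(floor(x + 0.5))  # half away from zero (inputs are non-negative)
}

#' Mean delta13C of the outermost rings
#'
#' Computes the unweighted mean delta13C of the `n` most recent annual rings
#' of one tree, emulating a bulked sample of the last rings formed. If fewer
#' than `n` rings are available all are used and the result is flagged as a
#' short series.
#'
#' @param rings Data frame of ring observations for a single tree with
#'   columns `calendar_year` and `d13c_permil` (see [read_ring_table()]).
#' @param n Number of outermost rings to average. Default 5.
#' @return A list with `mean_d13c_permil`, `first_year`, `last_year`,
#'   `n_used` and logical `short_series`.
#' @export
outer_ring_mean <- function(rings, n = 5) {
  if (!is.data.frame(rings) || nrow(rings) == 0)
    stop("rings must be a non-empty data frame of one tree's rings")
  if (n < 1) stop("n must be at least 1")
  ord <- order(rings$calendar_year, decreasing = TRUE)
  take <- utils::head(ord, n)
  list(
    mean_d13c_permil = mean(rings$d13c_permil[take]),
    first_year = min(rings$calendar_year[take]),
    last_year = max(rings$calendar_year[take]),
    n_used = length(take),
    short_series = length(take) < n
  )
}

# ---- readers -------------------------------------------------------------

# Case-insensitive header alignment shared by all readers.
align_columns <- function(df, wanted, what) {
  idx <- match(tolower(wanted), tolower(names(df)))
  missing <- wanted[is.na(idx)]
  if (length(missing) > 0)
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  out <- df[, idx, drop = FALSE]
  names(out) <- wanted
  out
}

as_numeric_checked <- function(x, column, what) {
  if (is.numeric(x)) return(x)
  suppressWarnings(out <- as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0)
    stop(sprintf("%s: unparseable numeric in column '%s' at row(s) %s", what,
                 column, paste(bad, collapse = ", ")))
  out
}

#' Read and validate a tree table
#'
#' Reads a comma-separated tree table (one row per sampled tree) and applies
#' the domain invariants. Rows violating hard invariants (unknown crown
#' class or forest type, non-positive age/height/diameter, delta13C outside
#' the physically admissible window) are rejected with row-numbered
#' diagnostics; delta13C values outside the typical C3-wood range
#' [-35, -18] permil are kept but produce a warning.
#'
#' @param path Path to a CSV file with columns `tree_id`, `species`,
#'   `site_id`, `forest_type`, `sampling_year`, `age_years`, `dbh_cm` (may be
#'   empty for uncorable seedlings), `height_m`, `cii_class`,
#'   `d13c_outer_permil`. Header matching is case-insensitive.
#' @return A data frame of class `tree_table` with the canonical columns plus
#'   `cii_ordinal`.
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  df <- align_columns(raw, TREE_COLUMNS, sprintf("tree table '%s'", path))
  df$sampling_year <- as.integer(as_numeric_checked(df$sampling_year,
                                                    "sampling_year", path))
  df$age_years <- as.integer(as_numeric_checked(df$age_years, "age_years",
                                                path))
  df$dbh_cm <- as_numeric_checked(df$dbh_cm, "dbh_cm", path)
  df$height_m <- as_numeric_checked(df$height_m, "height_m", path)
  df$d13c_outer_permil <- as_numeric_checked(df$d13c_outer_permil,
                                             "d13c_outer_permil", path)
  validate_tree_table(df, what = path)
}

#' Validate (or revalidate) a tree table
#'
#' Applies the tree-table invariants to an in-memory data frame; used by
#' [read_tree_table()] and available directly for programmatically built
#' tables. Invalid rows are dropped with a warning naming the rows and the
#' violated rule.
#'
#' @param df Data frame with the tree-table columns.
#' @param what Label used in diagnostics.
#' @return Validated data frame of class `tree_table` with `cii_ordinal`.
#' @export
validate_tree_table <- function(df, what = "tree table") {
  df <- as.data.frame(df)[, intersect(TREE_COLUMNS, names(df)), drop = FALSE]
  missing <- setdiff(TREE_COLUMNS, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  df$cii_class <- as.character(df$cii_class)
  problems <- character(0)
  bad <- rep(FALSE, nrow(df))
  flag <- function(rule, which) {
    if (any(which)) {
      problems <<- c(problems,
                     sprintf("row(s) %s: %s",
                             paste(which(which), collapse = ", "), rule))
      bad <<- bad | which
    }
  }
  flag("unknown cii_class", !(df$cii_class %in% CII_CLASSES))
  flag("unknown forest_type", !(df$forest_type %in% FOREST_TYPES))
  flag("age_years must be >= 1", is.na(df$age_years) | df$age_years < 1)
  flag("height_m must be > 0", is.na(df$height_m) | df$height_m <= 0)
  flag("dbh_cm must be > 0 when present", !is.na(df$dbh_cm) & df$dbh_cm <= 0)
  flag(sprintf("d13c_outer_permil outside [%g, %g]", D13C_HARD_RANGE[1],
               D13C_HARD_RANGE[2]),
       is.na(df$d13c_outer_permil) |
         df$d13c_outer_permil < D13C_HARD_RANGE[1] |
         df$d13c_outer_permil > D13C_HARD_RANGE[2])
  if (length(problems) > 0)
    warning(sprintf("%s: rejected %d row(s):\n  %s", what, sum(bad),
                    paste(problems, collapse = "\n  ")), call. = FALSE)
  out <- df[!bad, , drop = FALSE]
  soft <- out$d13c_outer_permil < D13C_SOFT_RANGE[1] |
    out$d13c_outer_permil > D13C_SOFT_RANGE[2]
  if (any(soft))
    warning(sprintf(
      "%s: %d value(s) of d13c_outer_permil outside the typical range [%g, %g] permil (kept)",
      what, sum(soft), D13C_SOFT_RANGE[1], D13C_SOFT_RANGE[2]),
      call. = FALSE)
  out$cii_ordinal <- cii_to_ordinal(out$cii_class)
  rownames(out) <- NULL
  class(out) <- c("tree_table", "data.frame")
  out
}

#' Read a ring-series table
#'
#' Reads per-ring (or per-ring-block) delta13C series for individual trees.
#' Decadal blocks carry `block_span_years = 10` and are dated by their
#' midpoint calendar year. Within each tree, `ring_index` must increase
#' strictly with `calendar_year`.
#'
#' @param path CSV with columns `tree_id`, `calendar_year`, `ring_index`,
#'   `block_span_years`, `d13c_permil`.
#' @return A data frame of class `ring_table`.
#' @export
read_ring_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  df <- align_columns(raw, RING_COLUMNS, sprintf("ring table '%s'", path))
  df$calendar_year <- as.integer(as_numeric_checked(df$calendar_year,
                                                    "calendar_year", path))
  df$ring_index <- as.integer(as_numeric_checked(df$ring_index, "ring_index",
                                                 path))
  df$block_span_years <- as.integer(as_numeric_checked(df$block_span_years,
                                                       "block_span_years",
                                                       path))
  df$d13c_permil <- as_numeric_checked(df$d13c_permil, "d13c_permil", path)
  validate_ring_table(df, what = path)
}

#' @rdname read_ring_table
#' @param df In-memory data frame with the ring-table columns.
#' @param what Label used in diagnostics.
#' @export
validate_ring_table <- function(df, what = "ring table") {
  missing <- setdiff(RING_COLUMNS, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  df <- as.data.frame(df)[, RING_COLUMNS, drop = FALSE]
  if (any(df$ring_index < 1)) stop(sprintf("%s: ring_index must be >= 1", what))
  if (any(df$block_span_years < 1))
    stop(sprintf("%s: block_span_years must be >= 1", what))
  for (id in unique(df$tree_id)) {
    sub <- df[df$tree_id == id, ]
    ord <- order(sub$calendar_year)
    if (is.unsorted(sub$ring_index[ord], strictly = TRUE))
      stop(sprintf(
        "%s: ring_index must increase strictly with calendar_year for tree %s",
        what, id))
  }
  rownames(df) <- NULL
  class(df) <- c("ring_table", "data.frame")
  df
}

#' Read an atmospheric record from CSV
#'
#' @param path CSV with columns `year`, `ca_ppm`, `d13c_air_permil`.
#' @return An `atmos` object (see [atmosphere_record()]).
#' @export
read_atmosphere_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  df <- align_columns(raw, ATMOS_COLUMNS,
                      sprintf("atmospheric table '%s'", path))
  atmosphere_record(
    year = as.integer(as_numeric_checked(df$year, "year", path)),
    ca_ppm = as_numeric_checked(df$ca_ppm, "ca_ppm", path),
    d13c_air_permil = as_numeric_checked(df$d13c_air_permil,
                                         "d13c_air_permil", path)
  )
}

# ---- writers -------------------------------------------------------------

write_canonical_csv <- function(df, columns, path) {
  df <- as.data.frame(df)[, columns, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write domain tables back to their canonical CSV schemas
#'
#' The writers emit exactly the reader schemas (same column set and order,
#' no row names, empty string for missing values), so a read - write - read
#' round trip reproduces identical records and identical inputs give
#' bit-identical files.
#'
#' @param df Table to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree_table <- function(df, path) {
  write_canonical_csv(df, TREE_COLUMNS, path)
}

#' @rdname write_tree_table
#' @export
write_ring_table <- function(df, path) {
  write_canonical_csv(df, RING_COLUMNS, path)
}

#' @rdname write_tree_table
#' @export
write_atmosphere_table <- function(df, path) {
  write_canonical_csv(df, ATMOS_COLUMNS, path)
}
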