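#' Construct a multi-brand weekly sales panel
#'
#' The panel is the package's central container: a brands-by-weeks matrix of
#' weekly equivalized unit sales, a designated treated brand, and per-brand
#' metadata. Cells may be `NA` for brands with incomplete reporting; such
#' brands are flagged and must be removed with [filter_brands()] before any
#' modelling (the pipeline never imputes).
#'
#' @param sales Numeric matrix, brands in rows (rownames = brand ids), weeks
#'   in columns (columns 1..T in order).
#' @param treated_id Brand id of the treated (intervention) brand.
#' @param brand_meta Optional data.frame with at least a `brand` column;
#'   recognised extra columns: `major_brand`, `product_type`.
#' @param week_end_dates Optional `Date` vector of length T (week-ending
#'   Saturdays); metadata only, all computation uses integer week indices.
#' @return An object of class `sales_panel`.
#' @export
sales_panel <- function(sales, treated_id, brand_meta = NULL,
                        week_end_dates = NULL) {
  if (!is.matrix(sales) || !is.numeric(sales)) {
    stop("'sales' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(sales))) stop("'sales' needs brand ids as rownames",
                                     call. = FALSE)
  if (anyDuplicated(rownames(sales))) {
    stop("duplicate brand ids in panel", call. = FALSE)
  }
  if (any(sales < 0, na.rm = TRUE)) {
    stop("sales must be non-negative", call. = FALSE)
  }
  if (!treated_id %in% rownames(sales)) {
    stop("treated brand '", treated_id, "' not present in panel", call. = FALSE)
  }
  n_weeks <- ncol(sales)
  colnames(sales) <- as.character(seq_len(n_weeks))
  if (!is.null(week_end_dates) && length(week_end_dates) != n_weeks) {
    stop("week_end_dates must have one entry per week", call. = FALSE)
  }
  if (is.null(brand_meta)) {
    brand_meta <- data.frame(brand = rownames(sales),
                             stringsAsFactors = FALSE)
  }
  if (!"brand" %in% names(brand_meta)) {
    stop("brand_meta must have a 'brand' column", call. = FALSE)
  }
  brand_meta <- brand_meta[match(rownames(sales), brand_meta$brand), ,
                           drop = FALSE]
  brand_meta$brand <- rownames(sales)
  rownames(brand_meta) <- NULL
  incomplete <- rownames(sales)[apply(sales, 1L, anyNA)]
  structure(list(sales = sales,
                 brand_ids = rownames(sales),
                 week_index = seq_len(n_weeks),
                 week_end_dates = week_end_dates,
                 treated_id = treated_id,
                 brand_meta = brand_meta,
                 incomplete_brands = incomplete),
            class = "sales_panel")
}

#' @export
print.sales_panel <- function(x, ...) {
  cat("Weekly sales panel:", length(x$brand_ids), "brands x",
      length(x$week_index), "weeks\n")
  cat("  treated brand:", x$treated_id, "\n")
  tot <- sum(x$sales, na.rm = TRUE)
  cat("  total equivalized units:", format(round(tot), big.mark = ","), "\n")
  if (length(x$incomplete_brands)) {
    cat("  incomplete brands:", length(x$incomplete_brands),
        "(remove with filter_brands())\n")
  }
  invisible(x)
}

#' Read a long-format weekly sales table into a panel
#'
#' Expects a delimited file with one row per (brand, week) cell. Column names
#' are declared through `schema`, so arbitrary extracts can be ingested
#' without renaming. Missing (brand, week) combinations become `NA` cells and
#' flag the brand as incomplete; duplicated combinations are an integrity
#' error, as are negative or non-numeric sales.
#'
#' @param path Path to a CSV (or TSV via `sep`) file.
#' @param treated_id Treated brand id (must appear in the file).
#' @param schema Named list mapping roles to column names; roles `brand`,
#'   `week`, `sales` are required, `product_type` optional.
#' @param sep Field separator, default comma.
#' @return A [sales_panel()].
#' @export
read_panel <- function(path, treated_id,
                       schema = list(brand = "brand", week = "week",
                                     sales = "sales"),
                       sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  needed <- c("brand", "week", "sales")
  for (role in needed) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(df)) {
      stop("schema error: no column for role '", role, "' (looked for '",
           if (is.null(col)) "?" else col, "')", call. = FALSE)
    }
  }
  brand <- as.character(df[[schema$brand]])
  week <- df[[schema$week]]
  if (!is.numeric(week)) {
    stop("schema error: week column must be an integer week index",
         call. = FALSE)
  }
  week <- as.integer(week)
  sales <- df[[schema$sales]]
  if (!is.numeric(sales)) {
    stop("value error: sales column is not numeric", call. = FALSE)
  }
  if (any(is.na(sales)) || any(sales < 0)) {
    stop("value error: sales must be non-negative and non-missing",
         call. = FALSE)
  }
  key <- paste(brand, week, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("integrity error: duplicate rows for (",
         sub("\r", ", week ", dup), ")", call. = FALSE)
  }
  brands <- sort(unique(brand))
  n_weeks <- max(week)
  if (min(week) < 1L) stop("value error: week indices must start at 1",
                           call. = FALSE)
  m <- matrix(NA_real_, nrow = length(brands), ncol = n_weeks,
              dimnames = list(brands, as.character(seq_len(n_weeks))))
  m[cbind(match(brand, brands), week)] <- sales
  meta <- NULL
  if (!is.null(schema$product_type) && schema$product_type %in% names(df)) {
    meta <- unique(data.frame(brand = brand,
                              product_type = as.character(df[[schema$product_type]]),
                              stringsAsFactors = FALSE))
    if (anyDuplicated(meta$brand)) {
      stop("integrity error: conflicting product_type for a brand",
           call. = FALSE)
    }
  }
  sales_panel(m, treated_id = treated_id, brand_meta = meta)
}

#' Write a panel back to long format
#'
#' Inverse of [read_panel()]: one row per non-missing (brand, week) cell,
#' sorted by brand then week so output bytes are deterministic.
#'
#' @param panel A [sales_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "sales_panel"))
  long <- data.frame(
    brand = rep(panel$brand_ids, each = length(panel$week_index)),
    week = rep(panel$week_index, times = length(panel$brand_ids)),
    sales = as.vector(t(panel$sales)),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$sales), , drop = FALSE]
  long <- long[order(long$brand, long$week), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate sub-brands into major brands
#'
#' Retail extracts report brands as printed on packaging, so one manufacturer
#' may appear as several sub-brands. This sums weekly sales of sub-brands
#' sharing a major-brand label; brands absent from the mapping map to
#' themselves. If the treated brand is a constituent of a mapped group, the
#' treated id is remapped to the major label. A brand that was never
#' explicitly mapped but collides with the treated brand's major label is a
#' configuration error: it would silently contaminate the treated unit.
#'
#' @param panel A [sales_panel()].
#' @param mapping Named character vector, `names` = sub-brand ids,
#'   values = major-brand labels.
#' @return A [sales_panel()] at major-brand resolution.
#' @export
aggregate_subbrands <- function(panel, mapping = character()) {
  stopifnot(inherits(panel, "sales_panel"))
  ids <- panel$brand_ids
  major <- ifelse(ids %in% names(mapping), unname(mapping[ids]), ids)
  names(major) <- ids
  treated_major <- major[[panel$treated_id]]
  group <- ids[major == treated_major]
  implicit <- group[!group %in% names(mapping) & group != panel$treated_id]
  if (length(implicit)) {
    stop("configuration error: brand '", implicit[1],
         "' is not an explicit sub-brand of '", treated_major,
         "' but would be merged into the treated unit", call. = FALSE)
  }
  # any NA constituent week makes the major-brand week NA (no partial sums)
  has_na <- rowsum((is.na(panel$sales)) + 0, group = major, reorder = TRUE) > 0
  agg <- rowsum(ifelse(is.na(panel$sales), 0, panel$sales),
                group = major, reorder = TRUE)
  agg[has_na] <- NA_real_
  # keep first-occurrence brand order rather than rowsum's alphabetical one
  ord <- unique(unname(major))
  agg <- agg[match(ord, rownames(agg)), , drop = FALSE]
  meta <- panel$brand_meta
  meta$major_brand <- unname(major[meta$brand])
  keep_first <- !duplicated(meta$major_brand)
  meta_major <- meta[keep_first, , drop = FALSE]
  meta_major$brand <- meta_major$major_brand
  meta_major <- meta_major[match(rownames(agg), meta_major$brand), ,
                           drop = FALSE]
  sales_panel(agg, treated_id = treated_major,
              brand_meta = meta_major,
              week_end_dates = panel$week_end_dates)
}

#' Apply the sample-inclusion rules
#'
#' Removes (1) brands with any missing week (complete-case rule: incomplete
#' reporters are excluded, never imputed) and (2) brands whose
#' `product_type` is in `exclusions` (e.g. nicotine-free accessories). The
#' counts and share of total sales removed are reported via `message()`.
#' Removing the treated brand is a fatal configuration error. The operation
#' is idempotent.
#'
#' @param panel A [sales_panel()].
#' @param exclusions Character vector of `product_type` labels to drop.
#' @return A filtered [sales_panel()].
#' @export
filter_brands <- function(panel, exclusions = character()) {
  stopifnot(inherits(panel, "sales_panel"))
  ids <- panel$brand_ids
  drop_incomplete <- ids %in% panel$incomplete_brands
  drop_type <- rep(FALSE, length(ids))
  if (length(exclusions) && "product_type" %in% names(panel$brand_meta)) {
    drop_type <- panel$brand_meta$product_type %in% exclusions
  }
  drop <- drop_incomplete | drop_type
  if (panel$treated_id %in% ids[drop]) {
    stop("fatal configuration error: treated brand '", panel$treated_id,
         "' would be removed by filtering", call. = FALSE)
  }
  if (any(drop)) {
    total <- sum(panel$sales, na.rm = TRUE)
    removed <- sum(panel$sales[drop, , drop = FALSE], na.rm = TRUE)
    share <- if (total > 0) 100 * removed / total else 0
    message(sprintf(
      "filter_brands: removed %d brand(s) (%d incomplete, %d excluded type) carrying %s%.2f%% of total sales",
      sum(drop), sum(drop_incomplete), sum(drop_type & !drop_incomplete),
      if (share < 0.1 && share > 0) "<0.1% = " else "", share))
  }
  keep <- !drop
  sales_panel(panel$sales[keep, , drop = FALSE],
              treated_id = panel$treated_id,
              brand_meta = panel$brand_meta[keep, , drop = FALSE],
              week_end_dates = panel$week_end_dates)
}

#' Write pipeline result tables and a run manifest
#'
#' Writes each table in `tables` as `<name>.csv` under `path` (created if
#' needed) plus `manifest.json` recording configuration, seed, and package
#' version. Output is deterministic: identical inputs produce byte-identical
#' files.
#'
#' @param tables Named list of data.frames; must be non-empty.
#' @param path Output directory.
#' @param manifest Optional list of run metadata merged into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, path, manifest = list()) {
  if (!is.list(tables) || length(tables) == 0L ||
      is.null(names(tables)) || any(names(tables) == "")) {
    stop("refusing to write: 'tables' must be a non-empty named list",
         call. = FALSE)
  }
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]]) || nrow(tables[[nm]]) == 0L) {
      stop("refusing to write: table '", nm, "' is empty", call. = FALSE)
    }
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(format(tables[[nm]], trim = TRUE, digits = 15,
                            scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  man <- c(manifest,
           list(package = "synthsales",
                version = as.character(utils::packageVersion("synthsales")),
                tables = names(tables)))
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, mf))
}
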