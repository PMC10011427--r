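#' Construct a feature table
#'
#' A feature table bundles a rectangular block of n objects by p variables
#' with a schema declaring the measurement kind of every column.  It is the
#' common input of the standardization, distance and clustering layers.
#'
#' Supported kinds are `"binary"` (values encodable as 0/1), `"nominal"`
#' (unordered categories compared only for equality), `"ordinal"` (integer
#' ranks in `1..levels`) and `"numeric"`.  Binary columns are a special case
#' of nominal with two levels; the distance layer decides how they enter a
#' dissimilarity.  Missing values are rejected: the generalized distance
#' function used downstream is defined for complete mixed data only, and a
#' silent imputation would corrupt every derived index.
#'
#' @param values data frame or matrix of observations, one row per object.
#'   Row names (or the `ids` argument) identify objects; algorithmic indices
#'   are positional and reported 1-based.
#' @param kinds character vector, one of `"binary"`, `"nominal"`,
#'   `"ordinal"`, `"numeric"` per column.
#' @param levels integer vector of the number of ordinal levels `M_j`
#'   (ignored, and may be `NA`, for non-ordinal columns).
#' @param weights non-negative per-variable weights, default 1.
#' @param ids optional character vector of row identifiers; defaults to the
#'   row names of `values`, or `"O1" ... "On"`.
#' @return An object of class `"feature_table"`: a list with elements
#'   `values` (numeric matrix), `schema` (data frame with columns `name`,
#'   `kind`, `levels`, `weight`) and `ids`.
#' @examples
#' ft <- feature_table(data.frame(size = c(1, 4, 2), type = c(0, 1, 1)),
#'                     kinds = c("numeric", "binary"))
#' ft
#' @export
feature_table <- function(values, kinds, levels = NULL, weights = NULL,
                          ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("'values' must be a matrix or data frame")
  if (nrow(values) == 0L) stop("no objects: the table has zero rows")
  p <- ncol(values)
  if (length(kinds) != p)
    stop("schema covers ", length(kinds), " columns but the table has ", p)
  kinds <- match.arg(kinds, c("binary", "nominal", "ordinal", "numeric"),
                     several.ok = TRUE)
  if (is.null(levels)) levels <- rep(NA_integer_, p)
  if (is.null(weights)) weights <- rep(1, p)
  if (any(weights < 0)) stop("variable weights must be non-negative")
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("O", seq_len(nrow(values)))
  if (anyDuplicated(ids)) stop("row identifiers must be unique")
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))

  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, nm)
  schema <- data.frame(name = nm, kind = kinds,
                       levels = as.integer(levels), weight = as.numeric(weights),
                       stringsAsFactors = FALSE)
  ft <- structure(list(values = values, schema = schema, ids = ids),
                  class = "feature_table")
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  values <- ft$values
  schema <- ft$schema
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value in row '", ft$ids[bad[1L]], "', column '",
         schema$name[bad[2L]], "': the table must be complete")
  }
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    kind <- schema$kind[j]
    if (kind == "binary" && !all(x %in% c(0, 1)))
      stop("binary column '", schema$name[j], "' contains values other than 0/1")
    if (kind == "ordinal") {
      M <- schema$levels[j]
      if (is.na(M) || M < 2L)
        stop("ordinal column '", schema$name[j], "' needs levels >= 2")
      if (!all(x == round(x)) || any(x < 1) || any(x > M))
        stop("ordinal column '", schema$name[j],
             "' has ranks outside 1..", M)
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$values), " objects x ", ncol(x$values),
      " variables\n", sep = "")
  tab <- table(factor(x$schema$kind,
                      levels = c("binary", "nominal", "ordinal", "numeric")))
  cat("Kinds:", paste0(names(tab)[tab > 0], "=", tab[tab > 0], collapse = ", "),
      "\n")
  std <- attr(x, "provenance")
  if (!is.null(std))
    cat("Standardization:", paste(unique(std), collapse = ", "), "\n")
  invisible(x)
}

#' Number of objects / variables in a feature table
#' @param ft a `feature_table`.
#' @return integer.
#' @export
n_objects <- function(ft) nrow(ft$values)

#' @rdname n_objects
#' @export
n_variables <- function(ft) ncol(ft$values)

#' Read a feature table from CSV plus a JSON schema
#'
#' The CSV must carry a header row; an optional first column named `id` (or
#' any non-schema column) supplies row identifiers.  The schema file is a
#' JSON array of objects `{"name", "kind", "levels"?, "weight"?}` covering
#' every data column.
#'
#' @param csv_path path to an RFC-4180 CSV file with a header.
#' @param schema_path path to the JSON schema.
#' @return a [feature_table].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(csv_path, schema_path) {
  if (!file.exists(csv_path)) stop("input file not found: ", csv_path)
  if (!file.exists(schema_path)) stop("schema file not found: ", schema_path)
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("no objects: '", csv_path, "' has a header only")
  schema <- jsonlite::fromJSON(schema_path)
  if (is.null(schema$name) || is.null(schema$kind))
    stop("schema must list 'name' and 'kind' for every column")
  bad_kind <- setdiff(schema$kind, c("binary", "nominal", "ordinal", "numeric"))
  if (length(bad_kind))
    stop("unknown variable kind in schema: ", paste(bad_kind, collapse = ", "))
  ids <- NULL
  extra <- setdiff(names(raw), schema$name)
  if (length(extra) >= 1L) {
    ids <- as.character(raw[[extra[1L]]])
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols))
    stop("schema names columns absent from the CSV: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, schema$name, drop = FALSE]
  feature_table(raw, kinds = schema$kind,
                levels = if (!is.null(schema$levels)) schema$levels,
                weights = if (!is.null(schema$weight)) schema$weight,
                ids = ids)
}

#' Write a feature table to CSV plus a JSON schema
#'
#' Round-trips exactly with [read_feature_table()].
#'
#' @param ft a `feature_table`.
#' @param csv_path,schema_path output paths.
#' @return invisibly, `ft`.
#' @export
write_feature_table <- function(ft, csv_path, schema_path) {
  df <- data.frame(id = ft$ids, as.data.frame(ft$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  schema <- ft$schema
  jsonlite::write_json(schema, schema_path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(ft)
}

#' Environmental-health scores of 25 Asia-Pacific countries
#'
#' The package's worked example: min-max standardized 2022 scores of 25
#' Asia-Pacific countries on four environmental-health issues -- air quality
#' (AQ), water and sanitation (WS), heavy metals (HM) and waste management
#' (WM).  Values are carried to the two decimal places at which they were
#' published; row identifiers are three-letter country codes and the row
#' order follows ascending per-row standard deviation, so positional object
#' numbers ("object 13") match the published worked example.
#'
#' @return a [feature_table] with 25 rows and 4 numeric columns, all values
#'   already inside `[0, 1]`.
#' @examples
#' env <- environment_scores()
#' env$values["TLS", ]
#' @export
environment_scores <- function() {
  path <- system.file("extdata", "asia_pacific_env.csv", package = "dricluster",
                      mustWork = TRUE)
  schema <- system.file("extdata", "asia_pacific_env_schema.json",
                        package = "dricluster", mustWork = TRUE)
  read_feature_table(path, schema)
}
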