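#' Covariate tables with type metadata
#'
#' A `covariate_table` is a `data.frame` of one row per subject carrying a
#' schema that declares, for every covariate column, its kind (`"continuous"`
#' or `"categorical"`) and whether it is modelled on the log scale
#' (biochemical measurements are typically log-transformed so that simulated
#' values are strictly positive). An optional column of per-subject sampling
#' weights can be designated; it is excluded from the covariates and used to
#' reweight estimation. Missing values are allowed and handled per covariate.
#'
#' @param data a `data.frame` of covariates (plus, optionally, a weight
#'   column).
#' @param kinds named character vector mapping covariate names to
#'   `"continuous"` or `"categorical"`. Unnamed covariates default by column
#'   type: numeric columns are continuous, character/factor/logical columns
#'   categorical.
#' @param log_scale character vector of covariate names modelled on the log
#'   scale (continuous, strictly positive), or a named logical vector.
#' @param weight_col optional name of the sampling-weight column.
#' @param units optional named character vector of units, kept as metadata.
#' @return an object of class `covariate_table` (also a `data.frame`).
#' @examples
#' tab <- covariate_table(
#'   data.frame(age = c(30, 41), scr = c(0.8, 1.1), sex = c("f", "m")),
#'   log_scale = "scr"
#' )
#' ct_schema(tab)$kinds
#' @export
covariate_table <- function(data, kinds = NULL, log_scale = NULL,
                            weight_col = NULL, units = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(weight_col)) {
    if (!is_string(weight_col) || !weight_col %in% names(data))
      stop_domain("weight column '", weight_col, "' not found in data")
    w <- data[[weight_col]]
    if (!is.numeric(w) || any(w < 0, na.rm = TRUE) || !any(w > 0, na.rm = TRUE))
      stop_domain("sampling weights must be nonnegative and not all zero")
  }
  covs <- setdiff(names(data), weight_col)

  kind_of <- function(nm) {
    if (!is.null(kinds) && nm %in% names(kinds)) {
      k <- match.arg(kinds[[nm]], c("continuous", "categorical"))
      return(k)
    }
    if (is.numeric(data[[nm]])) "continuous" else "categorical"
  }
  kinds_full <- vapply(covs, kind_of, character(1))

  if (is.logical(log_scale)) {
    log_full <- setNames(rep(FALSE, length(covs)), covs)
    log_full[intersect(names(log_scale)[log_scale], covs)] <- TRUE
  } else {
    bad <- setdiff(log_scale, covs)
    if (length(bad))
      stop_domain("log_scale names not in covariates: ",
                  paste(bad, collapse = ", "))
    log_full <- setNames(covs %in% (log_scale %||% character()), covs)
  }
  if (any(log_full & kinds_full == "categorical"))
    stop_domain("log_scale applies to continuous covariates only")

  structure(
    data,
    schema = list(kinds = kinds_full, log_scale = log_full,
                  weight_col = weight_col, units = units),
    class = c("covariate_table", "data.frame")
  )
}

#' @rdname covariate_table
#' @param x a `covariate_table`.
#' @export
ct_schema <- function(x) {
  s <- attr(x, "schema", exact = TRUE)
  if (is.null(s)) stop_domain("not a covariate_table: schema missing")
  s
}

#' @rdname covariate_table
#' @export
ct_covariates <- function(x) names(ct_schema(x)$kinds)

#' @rdname covariate_table
#' @export
ct_weights <- function(x) {
  wc <- ct_schema(x)$weight_col
  if (is.null(wc)) NULL else x[[wc]]
}

# subsetting keeps the schema whenever all covariates survive
#' @export
`[.covariate_table` <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  out <- y[...]
  if (is.data.frame(out) && all(ct_covariates(x) %in% names(out))) {
    attr(out, "schema") <- attr(x, "schema")
    class(out) <- c("covariate_table", "data.frame")
  }
  out
}

#' Drop a covariate column (schema-aware)
#' @param x a `covariate_table`.
#' @param cols covariate names to remove.
#' @return the table without `cols`, schema updated.
#' @export
ct_drop <- function(x, cols) {
  s <- ct_schema(x)
  keep <- setdiff(names(x), cols)
  covariate_table(as.data.frame(x)[keep],
                  kinds = s$kinds[setdiff(names(s$kinds), cols)],
                  log_scale = names(which(s$log_scale))[
                    !names(which(s$log_scale)) %in% cols],
                  weight_col = if (!is.null(s$weight_col) &&
                                   s$weight_col %in% keep) s$weight_col,
                  units = s$units)
}

#' Read / write covariate tables as CSV
#'
#' `write_covariate_csv()` writes the table as plain CSV together with a
#' sidecar JSON file describing the schema (covariate kinds, log-scale flags,
#' weight column, units and, when present, simulation metadata such as seeds
#' and acceptance rates). `read_covariate_csv()` reads them back; without a
#' sidecar the schema is inferred from column types and the arguments.
#'
#' @param x a `covariate_table`.
#' @param path CSV file path.
#' @param metadata_path sidecar JSON path; default `<path>.meta.json`.
#' @param extra named list merged into the sidecar metadata.
#' @return `read_covariate_csv()` returns a `covariate_table`;
#'   `write_covariate_csv()` returns `path` invisibly.
#' @export
write_covariate_csv <- function(x, path, metadata_path = NULL, extra = list()) {
  s <- ct_schema(x)
  write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- c(list(kinds = as.list(s$kinds),
                 log_scale = names(which(s$log_scale)),
                 weight_col = s$weight_col,
                 units = as.list(s$units %||% setNames(list(), character()))),
            extra)
  jsonlite::write_json(meta, metadata_path %||% paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_covariate_csv
#' @param kinds,log_scale,weight_col overrides used when no sidecar exists
#'   (same meaning as in [covariate_table()]).
#' @export
read_covariate_csv <- function(path, metadata_path = NULL, kinds = NULL,
                               log_scale = NULL, weight_col = NULL) {
  if (!file.exists(path)) stop_domain("input file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mp <- metadata_path %||% paste0(path, ".meta.json")
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    kinds <- kinds %||% unlist(meta$kinds)
    log_scale <- log_scale %||% meta$log_scale
    weight_col <- weight_col %||% meta$weight_col
  }
  covariate_table(df, kinds = kinds, log_scale = log_scale,
                  weight_col = weight_col)
}
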