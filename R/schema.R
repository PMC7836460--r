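#' Variable schema for Hypericum perforatum habitat samples
#'
#' The study design measures thirteen predictors at every sampling point --
#' three landform variables (altitude, slope, hill aspect), the plant's
#' phenological stage, and nine soil variables -- plus the response,
#' hypericin content in mg/g dry mass. This function returns the frozen
#' schema: one row per variable with its kind (continuous or
#' ordinal-categorical), unit, physical bounds, and, for ordinals, the
#' ordered label-to-code map.
#'
#' Hill aspect is coded north (1), east (2), south (3), west (4);
#' phenological stage vegetative (1), flowering (2), seed ripening (3).
#' Both enter the design matrix as their integer codes, not one-hot:
#' the model family counts exactly 13 inputs and both orderings carry a
#' monotone habitat signal.
#'
#' @return A data.frame with columns `name`, `kind`, `unit`, `min`, `max`,
#'   and a list-column `codes` (named integer vector for ordinals, NULL
#'   otherwise). The first 13 rows are the predictors in the frozen design
#'   matrix order; the last row is the target `hypericin`.
#' @export
#' @examples
#' hypericum_schema()$name
hypericum_schema <- function() {
  codes <- vector("list", 14L)
  codes[[3L]] <- c(north = 1L, east = 2L, south = 3L, west = 4L)
  codes[[4L]] <- c(vegetative = 1L, flowering = 2L, seed_ripening = 3L)
  out <- data.frame(
    name = c("altitude", "slope", "aspect", "phenology",
             "organic_carbon", "total_nitrogen", "phosphorus", "potassium",
             "sand", "silt", "clay", "ec", "ph", "hypericin"),
    kind = c("continuous", "continuous", "ordinal", "ordinal",
             rep("continuous", 9L), "continuous"),
    unit = c("m", "%", "code", "code", "%", "%", "ppm", "ppm",
             "%", "%", "%", "dS/m", "pH", "mg/g"),
    min = c(1103, 5, 1, 1, 0, 0.1, 0.5, 103, 35, 20, 5, 0.02, 6.2, 0),
    max = c(3822, 35, 4, 3, 2.6, 0.57, 5.7, 287, 50, 50, 35, 0.2, 7.9, Inf),
    stringsAsFactors = FALSE
  )
  out$codes <- codes
  out
}

#' Names of the 13 predictor variables, in frozen design-matrix order
#' @return Character vector of length 13.
#' @export
predictor_names <- function() {
  sc <- hypericum_schema()
  sc$name[sc$name != "hypericin"]
}

#' Construct a sample table from a data.frame
#'
#' Validates a data.frame of habitat samples against [hypericum_schema()]:
#' all 13 predictors must be present (the hypericin target is optional),
#' ordinal columns may be given as text labels (converted to codes) or as
#' valid integer codes, and every value must be finite. Extra columns are
#' dropped; column order is normalised to the schema order so that the
#' encoded design matrix never depends on the input column order.
#'
#' @param df A data.frame with (case-insensitively) named columns.
#' @return An object of class `sample_table`: a data.frame in schema column
#'   order with attribute `has_target`.
#' @export
as_sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  sc <- hypericum_schema()
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(predictor_names(), names(df))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_target <- "hypericin" %in% names(df)
  keep <- c(predictor_names(), if (has_target) "hypericin")
  df <- df[, keep, drop = FALSE]

  for (i in seq_len(nrow(sc))) {
    nm <- sc$name[i]
    if (!nm %in% names(df)) next
    v <- df[[nm]]
    if (sc$kind[i] == "ordinal") {
      df[[nm]] <- decode_ordinal(v, sc$codes[[i]], nm)
    } else {
      if (is.character(v) || is.factor(v)) {
        vv <- suppressWarnings(as.numeric(as.character(v)))
        bad <- which(is.na(vv) & !is.na(as.character(v)))
        if (length(bad) > 0L) {
          stop(sprintf("column '%s': unparseable value '%s' in row %d",
                       nm, as.character(v)[bad[1L]], bad[1L]), call. = FALSE)
        }
        v <- vv
      }
      if (anyNA(v) || any(!is.finite(v))) {
        stop(sprintf("column '%s': missing or non-finite value in row %d",
                     nm, which(!is.finite(v))[1L]), call. = FALSE)
      }
      df[[nm]] <- as.numeric(v)
    }
  }
  if (has_target && any(df$hypericin < 0)) {
    stop("hypericin content must be non-negative", call. = FALSE)
  }
  structure(df, has_target = has_target,
            class = c("sample_table", "data.frame"))
}

# Text labels or integer codes -> integer codes, with a helpful error.
decode_ordinal <- function(v, codes, nm) {
  if (is.factor(v)) v <- as.character(v)
  if (is.character(v)) {
    num <- suppressWarnings(as.numeric(v))
    out <- integer(length(v))
    for (k in seq_along(v)) {
      if (!is.na(num[k])) {
        out[k] <- as.integer(num[k])
      } else {
        key <- gsub("[ -]", "_", tolower(trimws(v[k])))
        if (!key %in% names(codes)) {
          stop(sprintf(
            "column '%s': unknown label '%s' in row %d (valid labels: %s)",
            nm, v[k], k, paste(names(codes), collapse = ", ")), call. = FALSE)
        }
        out[k] <- codes[[key]]
      }
    }
    v <- out
  }
  v <- as.integer(round(as.numeric(v)))
  bad <- which(!v %in% codes)
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': invalid code %s in row %d (valid codes: %s)",
                 nm, v[bad[1L]], bad[1L],
                 paste(codes, collapse = ", ")), call. = FALSE)
  }
  v
}

#' Read habitat samples from a CSV file
#'
#' Reads a comma-separated, '.'-decimal, headered CSV and validates it with
#' [as_sample_table()]. Header matching is case-insensitive; ordinal
#' variables accept either integer codes or text labels ("north", ...,
#' "west"; "vegetative", "flowering", "seed ripening"). Row order is
#' preserved.
#'
#' @param path Path to a CSV file.
#' @return A `sample_table`.
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  as_sample_table(df)
}

#' Write a sample table to CSV
#'
#' @param table A `sample_table` (or coercible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Encode a sample table as a numeric design matrix
#'
#' Produces the 13-column numeric matrix used by every model in the
#' package. Columns appear in the frozen schema order (see
#' [predictor_names()]); ordinal variables contribute their integer codes.
#'
#' @param table A `sample_table` or data.frame accepted by
#'   [as_sample_table()].
#' @return A list with `x` (n x 13 numeric matrix, named columns) and `y`
#'   (numeric target vector, or NULL when the table has no hypericin
#'   column).
#' @export
encode_features <- function(table) {
  if (!inherits(table, "sample_table")) table <- as_sample_table(table)
  x <- as.matrix(as.data.frame(table)[, predictor_names(), drop = FALSE])
  storage.mode(x) <- "double"
  y <- if (isTRUE(attr(table, "has_target"))) as.numeric(table$hypericin) else NULL
  list(x = x, y = y)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d predictors%s\n",
              nrow(x), length(predictor_names()),
              if (isTRUE(attr(x, "has_target"))) " + hypericin target" else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
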