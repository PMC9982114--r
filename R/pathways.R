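# Impact-pathway registry: definition, validation, I/O, filtering, and
# threshold-based activation.

#' Recognised urban-form typologies
#'
#' The six typologies an impact pathway may belong to. Pathways are grouped by
#' the element of urban form whose change drives the health effect.
#'
#' @format Character vector of length 6.
#' @export
haus_typologies <- c(
  "Buildings", "Natural Environment", "Climate Change",
  "Transport", "Community Infrastructure", "Socio-economics"
)

#' Recognised outcome kinds
#' @format Character vector of length 3.
#' @export
haus_outcome_kinds <- c("mortality", "morbidity", "behaviour_wellbeing")

# Exact, ordered CSV column contract for a pathway library.
pathway_columns <- c(
  "id", "typology", "characteristic", "environment_change", "outcome_id",
  "outcome_kind", "odds_ratio", "exposure_metric", "threshold_cmp",
  "threshold_value", "age_min", "age_max", "sex", "source_note"
)

#' Construct an impact-pathway table
#'
#' An impact pathway is one documented quantitative link from a specific
#' environmental change (e.g. an NDVI increase, central heating improvements)
#' to one health outcome (e.g. asthma, diabetes), carrying a multiplicative
#' effect size (odds ratio, applied as a rate ratio under the rare-outcome
#' approximation), a target population filter, and optionally an activation
#' threshold on a named scenario exposure metric.
#'
#' @param df data.frame with the columns listed in the package's CSV contract:
#'   `id`, `typology`, `characteristic`, `environment_change`, `outcome_id`,
#'   `outcome_kind`, `odds_ratio`, `exposure_metric`, `threshold_cmp`,
#'   `threshold_value`, `age_min`, `age_max`, `sex`, `source_note`.
#'   `threshold_cmp` is one of `">="`, `"<="` or `NA` (no threshold);
#'   `sex` is `"male"`, `"female"` or `NA` (both).
#' @return A validated `haus_pathways` data.frame (row order preserved).
#' @seealso [load_pathways()], [is_active()], [select_pathways()]
#' @export
impact_pathways <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(pathway_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("pathway schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, pathway_columns, drop = FALSE]
  for (col in c("odds_ratio", "threshold_value", "age_min", "age_max")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("id", "typology", "characteristic", "environment_change",
                "outcome_id", "outcome_kind", "exposure_metric",
                "threshold_cmp", "sex", "source_note")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  validate_pathways(df)
  class(df) <- c("haus_pathways", "data.frame")
  df
}

#' Validate a pathway table against the registry invariants
#'
#' Checks: positive odds ratios, known typologies and outcome kinds,
#' `age_min < age_max`, finite threshold values with a valid comparator, and
#' unique ids. Errors carry the offending row id.
#'
#' @param df data.frame with the pathway columns.
#' @return Invisibly, `df`.
#' @export
validate_pathways <- function(df) {
  bad_row <- function(i) {
    id <- df$id[i]
    if (is.na(id) || id == "") paste0("row ", i) else paste0("row id '", id, "'")
  }
  if (anyDuplicated(df$id[!is.na(df$id)]) > 0) {
    stop("pathway validation error: duplicate pathway ids", call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    or <- df$odds_ratio[i]
    if (is.na(or) || or <= 0) {
      stop("pathway validation error: non-positive odds_ratio at ",
           bad_row(i), call. = FALSE)
    }
    if (!(df$typology[i] %in% haus_typologies)) {
      stop("pathway validation error: unknown typology '", df$typology[i],
           "' at ", bad_row(i), call. = FALSE)
    }
    if (!(df$outcome_kind[i] %in% haus_outcome_kinds)) {
      stop("pathway validation error: unknown outcome_kind '",
           df$outcome_kind[i], "' at ", bad_row(i), call. = FALSE)
    }
    if (is.na(df$age_min[i]) || is.na(df$age_max[i]) ||
        df$age_min[i] >= df$age_max[i]) {
      stop("pathway validation error: require age_min < age_max at ",
           bad_row(i), call. = FALSE)
    }
    has_cmp <- !is.na(df$threshold_cmp[i])
    has_val <- !is.na(df$threshold_value[i])
    if (has_cmp != has_val) {
      stop("pathway validation error: threshold_cmp and threshold_value ",
           "must be given together at ", bad_row(i), call. = FALSE)
    }
    if (has_cmp) {
      if (!(df$threshold_cmp[i] %in% c(">=", "<="))) {
        stop("pathway validation error: threshold_cmp must be '>=' or '<=' at ",
             bad_row(i), call. = FALSE)
      }
      if (!is.finite(df$threshold_value[i])) {
        stop("pathway validation error: non-finite threshold_value at ",
             bad_row(i), call. = FALSE)
      }
      if (is.na(df$exposure_metric[i])) {
        stop("pathway validation error: thresholded pathway needs an ",
             "exposure_metric at ", bad_row(i), call. = FALSE)
      }
    }
    if (!is.na(df$sex[i]) && !(df$sex[i] %in% c("male", "female"))) {
      stop("pathway validation error: sex must be 'male', 'female' or empty at ",
           bad_row(i), call. = FALSE)
    }
  }
  invisible(df)
}

#' Load an impact-pathway library from disk
#'
#' Reads a pathway registry from CSV (primary format) or JSON (secondary),
#' validates every row, preserves row order, and logs the loaded count.
#' An empty file (header only) yields an empty library with a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return A `haus_pathways` data.frame.
#' @export
load_pathways <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) {
    stop("pathway load error: file not found: ", path, call. = FALSE)
  }
  format <- if (missing(format)) infer_format(path) else match.arg(format)
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8"),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(x) == 0) x <- empty_pathway_frame()
      as.data.frame(x, stringsAsFactors = FALSE)
    }
  )
  if (nrow(df) == 0) {
    missing_cols <- setdiff(pathway_columns, names(df))
    if (length(missing_cols) > 0) {
      stop("pathway schema error: missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    warning("pathway library at '", path, "' is empty", call. = FALSE)
    return(impact_pathways(empty_pathway_frame()))
  }
  pw <- impact_pathways(df)
  message("loaded ", nrow(pw), " impact pathway(s) from ", path)
  pw
}

#' Write an impact-pathway library to disk
#'
#' Inverse of [load_pathways()]: text fields round-trip bit-identically and
#' numeric fields at full precision (CSV numerics use 17 significant digits).
#'
#' @param pathways A `haus_pathways` table.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return Invisibly, `path`.
#' @export
write_pathways <- function(pathways, path, format = c("csv", "json")) {
  format <- if (missing(format)) infer_format(path) else match.arg(format)
  out <- as.data.frame(pathways)
  rownames(out) <- NULL
  if (format == "csv") {
    write_csv_full_precision(out, path)
  } else {
    jsonlite::write_json(out, path, na = "null", auto_unbox = FALSE,
                         digits = I(17))
  }
  invisible(path)
}

empty_pathway_frame <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(pathway_columns)),
                    pathway_columns)
  )
  for (col in c("odds_ratio", "threshold_value", "age_min", "age_max")) {
    df[[col]] <- numeric(0)
  }
  df
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json" else "csv"
}

# Full-precision CSV writer shared by the library writers: numeric columns are
# formatted with 17 significant digits so read/write round-trips exactly.
write_csv_full_precision <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 17, scientific = FALSE)
      }, character(1))
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Does a scenario activate a pathway?
#'
#' A pathway with no threshold is always active. A thresholded pathway is
#' active iff the scenario's value for its exposure metric satisfies the
#' comparator (`>=` or `<=`). Inactive pathways contribute zero attributable
#' effect and render as a dash in reports.
#'
#' @param pathway One pathway: a single-row `haus_pathways` table or a list
#'   with the pathway fields.
#' @param metrics Named numeric vector or list mapping metric names to values.
#' @return `TRUE` or `FALSE`.
#' @export
is_active <- function(pathway, metrics) {
  pw <- as.list(pathway)
  cmp <- pw$threshold_cmp
  if (is.null(cmp) || length(cmp) == 0 || is.na(cmp)) return(TRUE)
  metric <- pw$exposure_metric
  metrics <- as.list(metrics)
  if (is.null(metrics[[metric]]) || is.na(metrics[[metric]])) {
    stop("configuration error: pathway '", pw$id, "' requires scenario metric '",
         metric, "' which is missing", call. = FALSE)
  }
  x <- as.numeric(metrics[[metric]])
  thr <- as.numeric(pw$threshold_value)
  if (cmp == ">=") x >= thr else x <= thr
}

#' Filter a pathway library
#'
#' Returns the pathways matching all provided filters; with no filters the
#' input is returned unchanged. Output is always a subset of the input and
#' filters compose commutatively.
#'
#' @param pathways A `haus_pathways` table.
#' @param characteristic Optional characteristic to match exactly.
#' @param typology Optional typology (one of [haus_typologies]).
#' @param outcome_kind Optional outcome kind (one of [haus_outcome_kinds]).
#' @return A `haus_pathways` table.
#' @export
select_pathways <- function(pathways, characteristic = NULL, typology = NULL,
                            outcome_kind = NULL) {
  keep <- rep(TRUE, nrow(pathways))
  if (!is.null(characteristic)) keep <- keep & pathways$characteristic %in% characteristic
  if (!is.null(typology)) {
    if (!all(typology %in% haus_typologies)) {
      stop("unknown typology: ", paste(setdiff(typology, haus_typologies),
                                       collapse = ", "), call. = FALSE)
    }
    keep <- keep & pathways$typology %in% typology
  }
  if (!is.null(outcome_kind)) keep <- keep & pathways$outcome_kind %in% outcome_kind
  out <- pathways[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("haus_pathways", "data.frame")
  out
}

#' @export
print.haus_pathways <- function(x, ...) {
  cat("<haus_pathways> ", nrow(x), " impact pathway(s), ",
      length(unique(x$typology)), " typology(ies)\n", sep = "")
  NextMethod()
}
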