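#' Read and validate a survival table
#'
#' Expects a CSV with columns `id`, `time` (days, > 0) and `event` (0/1);
#' any further columns are carried through untouched as covariates. Times
#' run from imaging to event or censoring.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `survival_table`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival_table(df)
}

#' Validate an in-memory survival table
#'
#' @param df data.frame with columns `id`, `time`, `event`.
#' @return `df` with class `survival_table` prepended.
#' @export
validate_survival_table <- function(df) {
  need <- c("id", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("survival table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicated subject id(s): ", paste(unique(dup), collapse = ", "))
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t))
    stop("non-positive or missing times at row(s): ",
         paste(bad_t, collapse = ", "))
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_e))
    stop("non-binary event indicator at row(s): ",
         paste(bad_e, collapse = ", "))
  df$event <- as.integer(df$event)
  if (!inherits(df, "survival_table"))
    class(df) <- c("survival_table", class(df))
  df
}

#' Write a feature table to CSV
#'
#' One row per subject, an `id` column first, then one column per catalogue
#' feature in catalogue order; missingness flag columns (if any) follow with
#' a `flag_` prefix.
#'
#' @param features a data.frame of features with an `id` column, or a list of
#'   `feature_vector` objects (see [extract_features()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "feature_vector"))) {
    features <- feature_table(features)
  }
  if (!"id" %in% names(features))
    stop("feature table must carry an `id` column")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with `id` as character and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Bind per-subject feature vectors into a table
#'
#' @param fvs list of `feature_vector` objects.
#' @return data.frame: `id`, 148 feature columns, then `flag_*` columns
#'   marking imputed (degenerate-region) entries.
#' @export
feature_table <- function(fvs) {
  stopifnot(length(fvs) >= 1)
  nm <- names(fvs[[1]])
  vals <- do.call(rbind, lapply(fvs, function(v) as.numeric(v)))
  colnames(vals) <- nm
  flags <- do.call(rbind, lapply(fvs, function(v) {
    fl <- attr(v, "flags")
    as.integer(nm %in% fl)
  }))
  colnames(flags) <- paste0("flag_", nm)
  ids <- vapply(fvs, function(v) {
    s <- attr(v, "subject_id")
    if (is.null(s)) NA_character_ else s
  }, character(1))
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("S", which(is.na(ids)))
  keep_flags <- colSums(flags) > 0
  out <- data.frame(id = ids, vals, check.names = FALSE)
  if (any(keep_flags))
    out <- cbind(out, as.data.frame(flags[, keep_flags, drop = FALSE]))
  rownames(out) <- NULL
  out
}
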