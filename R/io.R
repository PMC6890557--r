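#' Read and write edge-feature tables
#'
#' The on-disk format is a TSV with a `subject_id` column followed by one
#' column per edge named `roi<i>__roi<j>` (lexicographic upper-triangle
#' order, 1-based), plus an optional JSON sidecar recording `p`, the
#' connectivity method and `rho`.
#'
#' @param path TSV path.
#' @return `read_feature_table`: a `feature_matrix`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stopf("feature table needs a subject_id column")
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) stopf("duplicate subject ids in %s", path)
  vals <- as.matrix(df[setdiff(names(df), "subject_id")])
  if (anyNA(vals)) {
    bad <- ids[rowSums(is.na(vals)) > 0]
    stopf("missing feature values for subject(s): %s", paste(bad, collapse = ", "))
  }
  E <- ncol(vals)
  p <- (1 + sqrt(1 + 8 * E)) / 2
  if (p != round(p)) stopf("%d columns is not a p(p-1)/2 edge count", E)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new_feature_matrix(unname(vals), edge_index_map(as.integer(p)), ids,
                     method = meta$method %||% NA,
                     rho = as.numeric(meta$rho %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_feature_table
#' @param fm A `feature_matrix`.
#' @export
write_feature_table <- function(fm, path) {
  if (!inherits(fm, "feature_matrix")) stopf("`fm` must be a feature_matrix")
  df <- data.frame(subject_id = fm$subject_ids, fm$values, check.names = FALSE)
  names(df)[-1] <- edge_names(fm$edge_map)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(p = attr(fm$edge_map, "p"), method = fm$method,
                            rho = fm$rho,
                            edge_order = "lexicographic upper triangle, 1-based (i < j)"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read and write label tables
#'
#' TSV with `subject_id` plus one column per label.  Subjects with any
#' missing label are rejected (`on_missing = "error"`, the default) or
#' excluded with a message (`on_missing = "exclude"`), mirroring the usual
#' practice of dropping incompletely labelled subjects before analysis.
#'
#' @param path TSV path.
#' @param kinds Per-label kinds (`"continuous"`/`"binary"`), recycled;
#'   default treats every 0/1-valued column as binary.
#' @param on_missing `"error"` or `"exclude"`.
#' @return `read_label_table`: a `label_table`; when `on_missing =
#'   "exclude"`, the excluded subject ids are attached as attribute
#'   `excluded`.
#' @export
read_label_table <- function(path, kinds = NULL,
                             on_missing = c("error", "exclude")) {
  on_missing <- match.arg(on_missing)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stopf("label table needs a subject_id column")
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) stopf("duplicate subject ids in %s", path)
  vals <- as.matrix(df[setdiff(names(df), "subject_id")])
  excluded <- character(0)
  if (anyNA(vals)) {
    bad <- rowSums(is.na(vals)) > 0
    if (on_missing == "error")
      stopf("missing label values for subject(s): %s",
            paste(ids[bad], collapse = ", "))
    excluded <- ids[bad]
    message(sprintf("excluding %d subject(s) with missing labels", sum(bad)))
    vals <- vals[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  if (is.null(kinds))
    kinds <- ifelse(apply(vals, 2L, function(v) all(v %in% c(0, 1))),
                    "binary", "continuous")
  lt <- label_table(vals, kinds, ids)
  attr(lt, "excluded") <- excluded
  lt
}

#' @rdname read_label_table
#' @param lt A `label_table`.
#' @export
write_label_table <- function(lt, path) {
  if (!inherits(lt, "label_table")) stopf("`lt` must be a label_table")
  df <- data.frame(subject_id = lt$subject_ids, lt$values, check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis object as JSON
#'
#' @param obj A list-like result object.
#' @param path Output path.
#' @export
write_results <- function(obj, path) {
  jsonlite::write_json(strip_for_json(obj), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

strip_for_json <- function(x) {
  if (is.list(x)) lapply(x, strip_for_json) else x
}
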