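#' Construct a feature table
#'
#' A feature table is the central container of the package: a features x
#' samples matrix of non-negative abundances (missing values allowed as `NA`)
#' together with an append-only provenance log recording every transforming
#' operation applied to it.
#'
#' @param abund numeric matrix, features in rows and samples in columns, with
#'   row and column names set to feature and sample ids.
#' @param provenance character vector of operations already applied.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abund, provenance = character()) {
  if (!is.matrix(abund) || !is.numeric(abund)) {
    stop("`abund` must be a numeric matrix")
  }
  if (length(abund) > 0 &&
      (is.null(rownames(abund)) || is.null(colnames(abund)))) {
    stop("`abund` must have feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(abund)) || anyDuplicated(colnames(abund))) {
    stop("feature and sample ids must be unique")
  }
  neg <- abund < 0
  if (any(neg, na.rm = TRUE)) {
    bad <- which(neg, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative abundance at feature '%s', sample '%s'",
      rownames(abund)[bad[1]], colnames(abund)[bad[2]]
    ))
  }
  structure(
    list(abund = abund, provenance = as.character(provenance)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%.1f%% missing)\n",
    nrow(x$abund), ncol(x$abund),
    100 * mean(is.na(x$abund))
  ))
  if (length(x$provenance)) {
    cat("provenance:\n")
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abund)

feature_ids <- function(table) rownames(table$abund)
sample_ids <- function(table) colnames(table$abund)

# Append one provenance entry; every transforming operation goes through this.
ft_log <- function(table, entry) {
  table$provenance <- c(table$provenance, entry)
  table
}

# Subset features and/or samples, keeping the class and provenance.
ft_subset <- function(table, features = NULL, samples = NULL) {
  m <- table$abund
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  table$abund <- m
  table
}

#' Assemble a sample metadata table
#'
#' Validates per-sample metadata: study samples (groups TKO/CTRL) carry mouse
#' id, age and lifespan (for controls, the age at last blood collection plays
#' the role of the lifespan); QC and BLANK injections carry neither. Percent
#' lifetime and disease stage are derived columns (see [percent_lifetime()]
#' and [assign_stage()]).
#'
#' @param df data.frame with columns `sample_id`, `mouse_id`, `group`
#'   (TKO/CTRL/QC/BLANK), `age_weeks`, `lifespan_weeks`, `injection_order`.
#' @return A validated data.frame with derived `pct_lifetime` and `stage`
#'   columns filled in for study samples.
#' @export
sample_records <- function(df) {
  req <- c("sample_id", "mouse_id", "group", "age_weeks", "lifespan_weeks",
           "injection_order")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  }
  df$group <- as.character(df$group)
  bad_grp <- setdiff(unique(df$group), c("TKO", "CTRL", "QC", "BLANK"))
  if (length(bad_grp)) stop("unknown group(s): ", paste(bad_grp, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if (anyDuplicated(df$injection_order)) stop("injection_order must be unique")
  study <- df$group %in% c("TKO", "CTRL")
  if (any(study)) {
    if (any(is.na(df$age_weeks[study])) || any(is.na(df$lifespan_weeks[study]))) {
      stop("study samples require age_weeks and lifespan_weeks")
    }
    if (any(df$age_weeks[study] > df$lifespan_weeks[study])) {
      stop("age_weeks exceeds lifespan_weeks for a study sample")
    }
    df$pct_lifetime <- NA_real_
    df$pct_lifetime[study] <- percent_lifetime(
      df$age_weeks[study], df$lifespan_weeks[study]
    )
    df$stage <- NA_character_
    df$stage[study] <- assign_stage(df$pct_lifetime[study])
  } else {
    df$pct_lifetime <- NA_real_
    df$stage <- NA_character_
  }
  df
}

is_study <- function(records) records$group %in% c("TKO", "CTRL")

# sample ids of a given group, in injection order
group_samples <- function(records, group) {
  r <- records[records$group %in% group, , drop = FALSE]
  r$sample_id[order(r$injection_order)]
}

#' Read a feature table and its sample metadata
#'
#' Expects two tab-separated files: a matrix file with features as rows
#' (first column `feature_id`, remaining columns one per sample) and a
#' metadata file with one row per sample. Empty cells in the matrix are read
#' as missing values. Sample ids must agree between the two files.
#'
#' @param matrix_path path to the features x samples matrix file.
#' @param metadata_path path to the sample metadata file.
#' @return list with elements `table` (a [feature_table()]) and `records`.
#' @export
read_feature_table <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              colClasses = NA, na.strings = "")
  if (!ncol(mat_df) >= 2 || names(mat_df)[1] != "feature_id") {
    stop("matrix file must have a leading feature_id column")
  }
  m <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(mat_df$feature_id)
  meta <- utils::read.delim(metadata_path, check.names = FALSE, na.strings = "")
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  }
  extra_meta <- setdiff(meta$sample_id[meta$group %in% c("TKO", "CTRL", "QC", "BLANK")],
                        colnames(m))
  if (length(extra_meta)) {
    stop("metadata samples absent from matrix: ", paste(extra_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(
    table = feature_table(m, provenance = sprintf("read:%s", basename(matrix_path))),
    records = sample_records(meta)
  )
}

#' Write a feature table and its sample metadata
#'
#' Inverse of [read_feature_table()]: writes the matrix (missing values as
#' empty cells) and the metadata as tab-separated files, so that a read of
#' the written files reproduces the objects up to numeric formatting.
#'
#' @param table a [feature_table()].
#' @param records sample metadata as returned by [sample_records()].
#' @param matrix_path,metadata_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_feature_table <- function(table, records, matrix_path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$abund) == 0 || ncol(table$abund) == 0) {
    stop("empty feature table: nothing to write")
  }
  if (!setequal(sample_ids(table), records$sample_id)) {
    stop("sample ids of table and records disagree")
  }
  df <- data.frame(feature_id = feature_ids(table),
                   table$abund, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(records, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(matrix_path, metadata_path))
}
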