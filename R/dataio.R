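#' Read pooled individual participant data from a delimited text file
#'
#' Reads a pooled IPD table in which every row is one patient from one
#' primary study. Three columns are mandatory and must carry exactly these
#' names: `Study` (study label, text or numeric code), `test.results`
#' (continuous index-test value), and `disease` (reference-standard status,
#' strictly 0 or 1). Every other column is treated as a patient-level
#' covariate and typed automatically as continuous or categorical.
#'
#' Study identifiers are assigned sequentially (1, 2, ...) in order of first
#' appearance of each study label; this assignment is stable only as long as
#' the first-appearance order of labels is preserved when rows are
#' re-sorted.
#'
#' @param path Path to the delimited file (header row mandatory).
#' @param sep Field separator: `"comma"`, `"semicolon"` or `"tab"`.
#' @param categorical_cutoff Numeric covariate columns with at most this
#'   many distinct observed values are typed categorical (default 10).
#' @param covariate_types Optional named character vector overriding the
#'   automatic typing, e.g. `c(age = "continuous", center = "categorical")`.
#' @param na_tokens Strings recognized as missing values (default empty
#'   string and `"NA"`).
#' @return An `ipd_dataset`: a `data.frame` with columns `study_label`,
#'   `study_id`, `test_result`, `disease`, followed by the covariates, and
#'   attributes `covariate_types` (named character vector) and
#'   `flagged_studies` (study ids lacking one of the two disease classes;
#'   these are flagged, not dropped).
#' @seealso [as_ipd_dataset()] to validate an in-memory data frame,
#'   [study_summary()], [complete_cases()].
#' @export
read_ipd <- function(path, sep = c("comma", "semicolon", "tab"),
                     categorical_cutoff = 10, covariate_types = NULL,
                     na_tokens = c("", "NA")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) {
    ipd_abort(sprintf("file not found: %s", path), "ipddta_io_error")
  }
  sep_char <- c(comma = ",", semicolon = ";", tab = "\t")[[sep]]
  raw <- read.table(path, header = TRUE, sep = sep_char,
                    na.strings = na_tokens, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
  if (ncol(raw) == 1L) {
    others <- setdiff(c("comma", "semicolon", "tab"), sep)
    ipd_abort(sprintf(
      "parsed a single column with separator '%s'; the file likely uses a different separator (try %s)",
      sep, paste(sQuote(others), collapse = " or ")), "ipddta_dialect_error")
  }
  as_ipd_dataset(raw, categorical_cutoff = categorical_cutoff,
                 covariate_types = covariate_types)
}

#' Validate a pooled IPD data frame
#'
#' Applies the data contract of [read_ipd()] to an in-memory `data.frame`
#' with columns `Study`, `test.results`, `disease` and optional covariates.
#'
#' @inheritParams read_ipd
#' @param df A data frame with the mandatory columns.
#' @return An `ipd_dataset` (see [read_ipd()]).
#' @export
as_ipd_dataset <- function(df, categorical_cutoff = 10,
                           covariate_types = NULL) {
  required <- c("Study", "test.results", "disease")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ipd_abort(sprintf("mandatory column%s missing: %s (column names must be exactly \"Study\", \"test.results\", \"disease\")",
                      if (length(missing_cols) > 1) "s" else "",
                      paste(missing_cols, collapse = ", ")),
              "ipddta_schema_error")
  }

  tr <- df[["test.results"]]
  if (!is.numeric(tr)) {
    parsed <- suppressWarnings(as.numeric(as.character(tr)))
    bad <- which(!is.na(as.character(tr)) & is.na(parsed) &
                   !(as.character(tr) %in% c("", "NA")))
    if (length(bad)) {
      ipd_abort(sprintf("non-numeric entry in test.results at row %s",
                        paste(head(bad, 5), collapse = ", ")),
                "ipddta_parse_error")
    }
    tr <- parsed
  }

  dis <- df[["disease"]]
  dis_num <- suppressWarnings(as.numeric(as.character(dis)))
  bad_dis <- which(!is.na(dis) & (is.na(dis_num) | !dis_num %in% c(0, 1)))
  if (length(bad_dis)) {
    ipd_abort(sprintf("disease must only contain 0 or 1; invalid value at row %s",
                      paste(head(bad_dis, 5), collapse = ", ")),
              "ipddta_validation_error")
  }

  label <- as.character(df[["Study"]])
  study_id <- match(label, unique(label))

  out <- data.frame(study_label = label, study_id = study_id,
                    test_result = tr, disease = as.integer(dis_num),
                    stringsAsFactors = FALSE, check.names = FALSE)

  cov_names <- setdiff(names(df), required)
  clash <- intersect(cov_names, names(out))
  if (length(clash)) {
    ipd_abort(sprintf("covariate name collides with a reserved name: %s",
                      paste(clash, collapse = ", ")), "ipddta_schema_error")
  }
  types <- character(0)
  for (nm in cov_names) {
    col <- df[[nm]]
    type <- if (!is.null(covariate_types) && nm %in% names(covariate_types)) {
      t <- covariate_types[[nm]]
      if (!t %in% c("continuous", "categorical")) {
        ipd_abort(sprintf("covariate_types[\"%s\"] must be 'continuous' or 'categorical'", nm),
                  "ipddta_validation_error")
      }
      t
    } else if (is.numeric(col)) {
      if (length(unique(col[!is.na(col)])) <= categorical_cutoff)
        "categorical" else "continuous"
    } else {
      "categorical"
    }
    if (type == "categorical" && !is.numeric(col)) col <- as.character(col)
    out[[nm]] <- col
    types[nm] <- type
  }

  # studies that cannot enter accuracy/ROC analyses (single disease class)
  per_study <- split(out$disease, out$study_id)
  flagged <- as.integer(names(per_study)[
    vapply(per_study, function(d) {
      d <- d[!is.na(d)]
      !(any(d == 1) && any(d == 0))
    }, logical(1))])
  if (length(flagged)) {
    ipd_warn(sprintf("study id %s lacks one of the disease classes; flagged and excluded from per-study accuracy analyses",
                     paste(flagged, collapse = ", ")),
             "ipddta_single_class_warning")
  }

  structure(out,
            covariate_types = types,
            flagged_studies = flagged,
            class = c("ipd_dataset", "data.frame"))
}

#' @export
print.ipd_dataset <- function(x, ...) {
  k <- length(unique(x$study_id))
  cat(sprintf("Pooled IPD dataset: %d patients in %d studies\n", nrow(x), k))
  types <- attr(x, "covariate_types")
  if (length(types)) {
    cat("Covariates:", paste(sprintf("%s (%s)", names(types), types),
                             collapse = ", "), "\n")
  }
  fl <- attr(x, "flagged_studies")
  if (length(fl)) cat("Flagged single-class studies:", paste(fl, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Covariate names and types of an IPD dataset
#' @param data An `ipd_dataset`.
#' @return Named character vector mapping covariate name to
#'   `"continuous"` or `"categorical"`.
#' @export
covariate_types <- function(data) attr(data, "covariate_types") %||% character(0)

#' Show the first rows or the whole dataset
#'
#' Display helper mirroring a Head/All toggle: `"head"` shows the first six
#' rows (or fewer if the dataset is smaller), `"all"` everything.
#'
#' @param data An `ipd_dataset`.
#' @param mode `"head"` or `"all"`.
#' @return A data frame view of the requested rows.
#' @export
ipd_head <- function(data, mode = c("head", "all")) {
  mode <- match.arg(mode)
  df <- as.data.frame(data)
  if (mode == "head") utils::head(df, 6L) else df
}

#' Per-study summary statistics
#'
#' Computes descriptive statistics for every primary study, in `study_id`
#' order: sample size, number diseased, prevalence, and the index-test mean
#' and SD by disease group; plus, per covariate, mean/SD/min/max for
#' continuous covariates and level counts with percentages for categorical
#' ones. Missing values are excluded per variable (not listwise) and
#' reported as a missing count.
#'
#' @param data An `ipd_dataset`.
#' @return An object of class `ipd_study_summary`: a list with `overview`
#'   (one row per study) and `covariates` (a named list of per-covariate
#'   summary tables).
#' @export
study_summary <- function(data) {
  ids <- sort(unique(data$study_id))
  ov <- do.call(rbind, lapply(ids, function(i) {
    s <- data[data$study_id == i, , drop = FALSE]
    d <- s$disease
    y <- s$test_result
    nd <- sum(d == 1, na.rm = TRUE)
    n <- sum(!is.na(d))
    grp <- function(g, f) {
      v <- y[!is.na(d) & d == g & !is.na(y)]
      if (length(v)) f(v) else NA_real_
    }
    data.frame(study_id = i, study_label = s$study_label[1],
               n_total = n, n_diseased = nd,
               prevalence = if (n > 0) nd / n else NA_real_,
               test_mean_diseased = grp(1, mean), test_sd_diseased = grp(1, sd),
               test_mean_nondiseased = grp(0, mean), test_sd_nondiseased = grp(0, sd),
               stringsAsFactors = FALSE)
  }))

  types <- covariate_types(data)
  covs <- lapply(names(types), function(nm) {
    col <- data[[nm]]
    if (types[[nm]] == "continuous") {
      do.call(rbind, lapply(ids, function(i) {
        v <- col[data$study_id == i]
        miss <- sum(is.na(v)); v <- v[!is.na(v)]
        data.frame(study_id = i,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_,
                   n_missing = miss)
      }))
    } else {
      do.call(rbind, lapply(ids, function(i) {
        v <- col[data$study_id == i]
        miss <- sum(is.na(v)); v <- v[!is.na(v)]
        if (!length(v)) {
          return(data.frame(study_id = i, level = NA_character_, count = 0L,
                            pct = NA_real_, n_missing = miss,
                            stringsAsFactors = FALSE))
        }
        tab <- table(v)
        data.frame(study_id = i, level = names(tab),
                   count = as.integer(tab),
                   pct = 100 * as.integer(tab) / length(v),
                   n_missing = miss, stringsAsFactors = FALSE,
                   row.names = NULL)
      }))
    }
  })
  names(covs) <- names(types)
  structure(list(overview = ov, covariates = covs),
            class = "ipd_study_summary")
}

#' @export
print.ipd_study_summary <- function(x, ...) {
  cat("Per-study summary\n")
  print(x$overview, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Complete-case subset with respect to selected columns
#'
#' Keeps the rows that have no missing value in any of `required` columns;
#' rows missing only in other columns are retained. This implements the
#' per-analysis complete-case rule: a record missing a covariate is removed
#' only from analyses that use that covariate and kept for all others.
#' `study_id` values are preserved (no renumbering).
#'
#' @param data An `ipd_dataset`.
#' @param required Character vector of internal column names
#'   (`"test_result"`, `"disease"`, or covariate names).
#' @return An `ipd_dataset` containing the complete-case rows.
#' @export
complete_cases <- function(data, required = c("test_result", "disease")) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    ipd_abort(sprintf("unknown column%s in 'required': %s",
                      if (length(missing_cols) > 1) "s" else "",
                      paste(missing_cols, collapse = ", ")),
              "ipddta_lookup_error")
  }
  keep <- complete.cases(as.data.frame(data)[, required, drop = FALSE])
  if (!any(keep)) {
    ipd_abort("no rows remain after complete-case filtering", "ipddta_empty_error")
  }
  lost <- setdiff(unique(data$study_id), unique(data$study_id[keep]))
  if (length(lost)) {
    ipd_warn(sprintf("complete-case filtering removed every row of study id %s",
                     paste(lost, collapse = ", ")),
             "ipddta_study_lost_warning")
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes_to_keep <- attributes(data)[c("covariate_types", "flagged_studies")]
  attr(out, "covariate_types") <- attributes_to_keep$covariate_types
  attr(out, "flagged_studies") <- attributes_to_keep$flagged_studies
  class(out) <- c("ipd_dataset", "data.frame")
  out
}

#' Write an IPD dataset back to the standard CSV contract
#'
#' @param data An `ipd_dataset`.
#' @param path Output file path.
#' @param sep `"comma"`, `"semicolon"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(data, path, sep = c("comma", "semicolon", "tab")) {
  sep <- match.arg(sep)
  sep_char <- c(comma = ",", semicolon = ";", tab = "\t")[[sep]]
  df <- data.frame(Study = data$study_label,
                   `test.results` = data$test_result,
                   disease = data$disease, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (nm in names(covariate_types(data))) df[[nm]] <- data[[nm]]
  utils::write.table(df, path, sep = sep_char, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

# Values of the index test split by disease class for one study (or pooled
# when study is NULL), complete cases on test_result + disease.
test_by_class <- function(data, study = NULL) {
  if (!is.null(study)) {
    if (!study %in% data$study_id) {
      ipd_abort(sprintf("unknown study_id: %s", study), "ipddta_lookup_error")
    }
    data <- data[data$study_id == study, , drop = FALSE]
  }
  ok <- !is.na(data$test_result) & !is.na(data$disease)
  list(diseased = data$test_result[ok & data$disease == 1],
       nondiseased = data$test_result[ok & data$disease == 0])
}

# Study ids usable for accuracy analyses: both classes present among
# complete cases of test_result + disease.
analyzable_studies <- function(data) {
  ids <- sort(unique(data$study_id))
  ids[vapply(ids, function(i) {
    v <- test_by_class(data, i)
    length(v$diseased) > 0 && length(v$nondiseased) > 0
  }, logical(1))]
}
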