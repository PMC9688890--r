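#' Read a cohort table
#'
#' The cohort table is the single input of the pipeline: one row per subject
#' with identifying and covariate columns plus the 50 absolute thalamic
#' nucleus volumes (mL). Required columns are `subject_id`, `group`
#' (`F-MS`/`NF-MS`/`HC`), `age` (years), `sex` (`female`/`male`),
#' `lesion_volume` (mL; 0 for HC), `eTIV` (mL), and all 50 nucleus columns
#' named `"Left-AV"`-style (FreeSurfer long-name aliases are accepted, see
#' [canonical_nucleus_name()]). `disease_duration` (years) is optional and may
#' be `NA` for controls. Column order is irrelevant; extra columns are dropped
#' with a warning.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; default guessed from the extension.
#' @return A validated data frame of class `"cohort_table"`.
#' @export
read_cohort_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- if (tolower(tools::file_ext(path)) == "tsv") "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- canonical_nucleus_name(names(df))
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df data frame with the columns described in [read_cohort_table()].
#' @return The validated `"cohort_table"` (extra columns removed, canonical
#'   column order).
#' @export
as_cohort_table <- function(df) {
  labs <- thalamic_nucleus_labels()
  required <- c("subject_id", "group", "age", "sex", "lesion_volume", "eTIV",
                labs)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- c(setdiff(required, labs), "disease_duration", labs)
  extra <- setdiff(names(df), keep)
  if (length(extra) > 0) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  if (!"disease_duration" %in% names(df)) df$disease_duration <- NA_real_
  df <- df[, keep, drop = FALSE]

  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  bad_group <- !df$group %in% c("F-MS", "NF-MS", "HC")
  if (any(bad_group)) {
    stop("unknown group label(s): ", paste(unique(df$group[bad_group]), collapse = ", "))
  }
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex)) {
    stop("sex must be 'female' or 'male'; offending subject(s): ",
         paste(df$subject_id[bad_sex], collapse = ", "))
  }
  # HC lesion load is defined as zero so one schema serves all groups
  df$lesion_volume[df$group == "HC" & is.na(df$lesion_volume)] <- 0
  for (col in c("age", "lesion_volume", "eTIV", labs)) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) {
      stop("missing/non-numeric values in column '", col, "' for subject(s): ",
           paste(df$subject_id[is.na(df[[col]])], collapse = ", "))
    }
  }
  if (any(df$eTIV <= 0)) {
    stop("non-positive eTIV for subject(s): ",
         paste(df$subject_id[df$eTIV <= 0], collapse = ", "))
  }
  if (any(df$lesion_volume < 0)) {
    stop("negative lesion_volume for subject(s): ",
         paste(df$subject_id[df$lesion_volume < 0], collapse = ", "))
  }
  for (col in labs) {
    if (any(df[[col]] <= 0)) {
      stop("non-positive volume in column '", col, "' for subject(s): ",
           paste(df$subject_id[df[[col]] <= 0], collapse = ", "))
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table
#'
#' @param cohort a `"cohort_table"`.
#' @param path output file; `.tsv` extension writes tab-separated, anything
#'   else comma-separated.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal rendering so written tables round-trip exactly
.format_full <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  })
  df
}

#' Write pipeline results to a directory
#'
#' Writes metric curves and nodal tables as TSV, permutation and volumetry
#' summaries as JSON, and a `manifest.json` capturing the configuration and
#' seed so any run can be replayed exactly. Recognized elements of `results`:
#' `config` (a [run_config()]), `curves` (data frame from
#' [group_metric_curves()] or a list of `metric_curve`s), `curve_summary`,
#' `volumetry` (data frame), `clinical_correlations` (data frame),
#' `permutation` (list of `perm_result`s), `nodal` (named list of data
#' frames). Unknown elements are written as JSON.
#'
#' @param results named list of pipeline outputs.
#' @param out_dir output directory (created if absent).
#' @return Manifest list (invisibly) with the files written.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  files <- character(0)
  put_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(.format_full(as.data.frame(df)), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  put_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    files <<- c(files, name)
  }
  for (nm in names(results)) {
    x <- results[[nm]]
    if (nm == "config") next
    if (inherits(x, "metric_curve")) x <- list(x)
    if (is.list(x) && length(x) > 0 && all(vapply(x, inherits, TRUE, "metric_curve"))) {
      put_tsv(do.call(rbind, lapply(x, as.data.frame)), paste0(nm, ".tsv"))
    } else if (is.list(x) && length(x) > 0 &&
               all(vapply(x, inherits, TRUE, "perm_result"))) {
      put_json(lapply(x, unclass), paste0(nm, ".json"))
    } else if (inherits(x, "perm_result")) {
      put_json(unclass(x), paste0(nm, ".json"))
    } else if (is.data.frame(x)) {
      put_tsv(x, paste0(nm, ".tsv"))
    } else if (is.list(x) && length(x) > 0 && all(vapply(x, is.data.frame, TRUE))) {
      for (sub in names(x)) put_tsv(x[[sub]], paste0(nm, "_", sub, ".tsv"))
    } else {
      put_json(x, paste0(nm, ".json"))
    }
  }
  manifest <- list(
    package = "thalnet",
    version = as.character(utils::packageVersion("thalnet")),
    config = if (!is.null(results$config)) unclass(results$config) else NULL,
    seed = if (!is.null(results$config)) results$config$rng_seed else NULL,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a metric-curve TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return Data frame with columns `metric`, `group`, `density`, `value`.
#' @export
read_metric_curve <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
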