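#' @keywords internal
"_PACKAGE"

# Column schema for gradient sample tables. `required` columns must be present
# and non-missing; `optional` may be absent or empty.
.soil_sample_required <- c(
  "sample_id", "site_id", "soil_type", "fertility_class",
  "total_organic_c", "soluble_organic_c", "total_n", "total_p",
  "mehlich_po4", "mbc", "mbp", "plfa_total", "plfa_bacterial",
  "plfa_fungal", "nlfa_c", "phb_c",
  "phosphomonoesterase", "phosphodiesterase", "glucosidase"
)
.soil_sample_optional <- c("plfa_gram_pos", "plfa_gram_neg", "trehalose_c")

.soil_types <- c("basalt", "shale", "ironstone", "sandstone")
.fertile_types <- c("basalt", "shale")

#' Validate a gradient sample table
#'
#' Checks one row per sample against the data-model invariants: all
#' concentrations non-negative, total organic C a fraction of dry mass in
#' (0, 1), bacterial + fungal PLFA not exceeding total PLFA, soil types among
#' the four parent materials, and the fertility class consistent with parent
#' material (basalt and shale are the fertile classes).
#'
#' @param df data frame following the documented sample schema.
#' @return `df` invisibly if valid; otherwise an error listing every failing
#'   row and field.
#' @export
validate_soil_samples <- function(df) {
  missing_cols <- setdiff(.soil_sample_required, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))

  problems <- character(0)
  add <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(rows), collapse = ","), ": ", msg))
    }
  }

  conc_fields <- setdiff(.soil_sample_required,
                         c("sample_id", "site_id", "soil_type",
                           "fertility_class", "total_organic_c"))
  for (f in conc_fields) {
    add(!is.na(df[[f]]) & df[[f]] < 0, paste0(f, " is negative"))
    add(is.na(df[[f]]), paste0(f, " is missing"))
  }
  for (f in intersect(.soil_sample_optional, names(df))) {
    add(!is.na(df[[f]]) & df[[f]] < 0, paste0(f, " is negative"))
  }
  add(is.na(df$total_organic_c) | df$total_organic_c <= 0 |
        df$total_organic_c >= 1,
      "total_organic_c must be a fraction in (0, 1)")
  add(!df$soil_type %in% .soil_types,
      paste0("soil_type must be one of ", paste(.soil_types, collapse = ", ")))
  expected_class <- ifelse(df$soil_type %in% .fertile_types,
                           "fertile", "infertile")
  add(df$soil_type %in% .soil_types & df$fertility_class != expected_class,
      "fertility_class inconsistent with soil_type")
  ok <- !is.na(df$plfa_total) & !is.na(df$plfa_bacterial) &
    !is.na(df$plfa_fungal)
  # small tolerance: totals and splits are printed at different precisions
  add(ok & df$plfa_bacterial + df$plfa_fungal > df$plfa_total * (1 + 1e-8),
      "plfa_bacterial + plfa_fungal exceeds plfa_total")
  if (anyDuplicated(df$sample_id)) {
    problems <- c(problems, "duplicated sample_id values")
  }

  if (length(problems) > 0L) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a gradient sample table from CSV
#'
#' Reads a tidy one-row-per-sample CSV (snake_case headers, "." decimal
#' separator, empty string for missing optional cells), validates it against
#' the sample invariants, and returns a `gradient_dataset`. A sidecar JSON
#' file with the same basename (if present) supplies dataset-level metadata.
#'
#' @param path path to the CSV file.
#' @param level `"replicate"` for field-replicate data or `"site_mean"` for
#'   site-mean tables such as the packaged fixture.
#' @return A `gradient_dataset`: a list with elements `samples` (data frame)
#'   and `level`.
#' @seealso [table1_fixture()] for the packaged site-mean table.
#' @export
load_gradient_csv <- function(path, level = c("replicate", "site_mean")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_soil_samples(df)
  if (level == "site_mean" && nrow(df) > 0L && nrow(df) != 8L) {
    warning("site_mean datasets from this gradient design normally have ",
            "8 records; got ", nrow(df))
  }
  gradient_dataset(df, level)
}

#' Construct a gradient dataset
#'
#' @param samples validated sample data frame.
#' @param level `"replicate"` or `"site_mean"`.
#' @return A `gradient_dataset` object.
#' @export
gradient_dataset <- function(samples, level = c("replicate", "site_mean")) {
  level <- match.arg(level)
  validate_soil_samples(samples)
  structure(list(samples = samples, level = level),
            class = "gradient_dataset")
}

#' @export
print.gradient_dataset <- function(x, ...) {
  cat("<gradient_dataset> ", nrow(x$samples), " samples (",
      x$level, " level), ",
      length(unique(x$samples$site_id)), " sites\n", sep = "")
  invisible(x)
}

#' Write a gradient dataset to CSV (with JSON sidecar)
#'
#' Values are written at full precision (15 significant digits) so a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param dataset a `gradient_dataset`.
#' @param path output CSV path; the metadata sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_gradient_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "gradient_dataset"))
  df <- dataset$samples
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- list(level = dataset$level, n_records = nrow(df))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load the packaged eight-site fixture of published site means
#'
#' Site-mean chemical and biological properties of surface soils (0-10 cm) at
#' the eight study sites of the eastern-Australian fertility gradient: four
#' parent materials (basalt, shale, ironstone, sandstone) with two sites
#' each. Units follow the sample schema; the `*_per_soc` columns store the
#' published storage-per-SOC values verbatim (these are means of
#' replicate-level ratios, so they differ slightly from ratios of the
#' tabulated means).
#'
#' @return A `gradient_dataset` at `site_mean` level with 8 records.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_site_means.csv",
                      package = "micstore", mustWork = TRUE)
  load_gradient_csv(path, level = "site_mean")
}
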