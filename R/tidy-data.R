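#' Two-table tidy metabolomics dataset
#'
#' Couples a `Data` table (one row per sample: metadata columns, metabolite
#' intensity columns `M_1 ... M_n`, and a binary outcome column) with a `Peak`
#' table (one row per metabolite: identifier, annotation name, optional
#' metadata). This is the standardised two-sheet convention used by curated
#' metabolomics feature tables: every metabolite column in `Data` has exactly
#' one matching row in `Peak`, and vice versa.
#'
#' @param data_table Data frame of samples. Must contain `sample_id_column`,
#'   `outcome_column`, and one numeric column per metabolite named in the
#'   peak table.
#' @param peak_table Data frame of metabolites. Must contain
#'   `peak_name_column` whose values are the metabolite column names of
#'   `data_table`.
#' @param outcome_column Name of the binary outcome column (default
#'   `"Class"`).
#' @param sample_id_column Name of the unique sample identifier column
#'   (default `"SampleID"`).
#' @param peak_name_column Column of `peak_table` holding the metabolite
#'   identifiers (default `"Name"`).
#' @param positive_label Outcome label mapped to 1 ("case"). Defaults to the
#'   lexicographically second of the two observed labels, so the mapping is
#'   explicit and reproducible.
#'
#' @return An object of class `tidy_dataset`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   SampleID = paste0("s", 1:4),
#'   Class = c(0, 1, 0, 1),
#'   M1 = c(1, 2, 3, 4), M2 = c(4, 3, 2, 1), M3 = c(1, 1, 2, 2)
#' )
#' p <- tibble::tibble(Name = c("M1", "M2", "M3"), Label = paste("met", 1:3))
#' ds <- tidy_dataset(d, p)
#' n_samples(ds)
tidy_dataset <- function(data_table, peak_table,
                         outcome_column = "Class",
                         sample_id_column = "SampleID",
                         peak_name_column = "Name",
                         positive_label = NULL) {
  data_table <- tibble::as_tibble(data_table)
  peak_table <- tibble::as_tibble(peak_table)
  x <- structure(
    list(
      data_table = data_table,
      peak_table = peak_table,
      outcome_column = outcome_column,
      sample_id_column = sample_id_column,
      peak_name_column = peak_name_column,
      positive_label = positive_label
    ),
    class = "tidy_dataset"
  )
  validate_tidy_dataset(x)
}

#' Validate a tidy dataset against its invariants
#'
#' Checks the Data/Peak linkage (every metabolite column has exactly one peak
#' row and vice versa), uniqueness of sample identifiers, that the outcome
#' takes exactly two distinct values, and that metabolite intensities are
#' non-negative or missing.
#'
#' @param x A `tidy_dataset`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error of class
#'   `metabench_format_error`, `metabench_linkage_error` or
#'   `metabench_outcome_error`.
#' @export
validate_tidy_dataset <- function(x) {
  d <- x$data_table
  p <- x$peak_table
  for (col in c(x$sample_id_column, x$outcome_column)) {
    if (!col %in% names(d)) {
      stop_metabench(
        paste0("Data table is missing required column '", col, "'."),
        "metabench_format_error"
      )
    }
  }
  if (!x$peak_name_column %in% names(p)) {
    stop_metabench(
      paste0("Peak table is missing identifier column '",
             x$peak_name_column, "'."),
      "metabench_format_error"
    )
  }
  peaks <- as.character(p[[x$peak_name_column]])
  if (anyDuplicated(peaks)) {
    stop_metabench("Peak identifiers are not unique.",
                   "metabench_linkage_error")
  }
  missing_in_data <- setdiff(peaks, names(d))
  if (length(missing_in_data)) {
    stop_metabench(
      paste0("Peak rows without a matching Data column: ",
             paste(head(missing_in_data, 5), collapse = ", ")),
      "metabench_linkage_error"
    )
  }
  meta_cols <- setdiff(names(d), c(x$sample_id_column, x$outcome_column))
  candidate <- meta_cols[vapply(d[meta_cols], is.numeric, logical(1))]
  orphan <- setdiff(candidate[grepl("^M_?\\d+$", candidate)], peaks)
  # only flag numeric M_i-style columns as orphans; free metadata is allowed
  if (length(orphan)) {
    stop_metabench(
      paste0("Data metabolite columns without a matching Peak row: ",
             paste(head(orphan, 5), collapse = ", ")),
      "metabench_linkage_error"
    )
  }
  ids <- d[[x$sample_id_column]]
  if (anyDuplicated(ids)) {
    stop_metabench("Sample identifiers are not unique.",
                   "metabench_format_error")
  }
  y <- d[[x$outcome_column]]
  if (length(unique(y[!is.na(y)])) != 2L || anyNA(y)) {
    stop_metabench("Outcome column must hold exactly two distinct labels.",
                   "metabench_outcome_error")
  }
  positive_label(x)  # errors if a declared positive label is unobserved
  intensities <- as.matrix(d[peaks])
  if (!is.numeric(intensities)) {
    stop_metabench("Metabolite columns must be numeric.",
                   "metabench_format_error")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop_metabench("Metabolite intensities must be non-negative or missing.",
                   "metabench_format_error")
  }
  invisible(x)
}

#' @export
print.tidy_dataset <- function(x, ...) {
  cat("<tidy_dataset> ", n_samples(x), " samples x ", n_features(x),
      " metabolites; outcome '", x$outcome_column, "' (positive = '",
      positive_label(x), "')\n", sep = "")
  invisible(x)
}

#' Dataset accessors
#'
#' @param x A `tidy_dataset`.
#' @return `feature_names()` the metabolite column names in Peak-table order;
#'   `n_samples()`/`n_features()` counts; `sample_ids()` the identifier
#'   vector; `positive_label()` the label mapped to 1.
#' @export
feature_names <- function(x) as.character(x$peak_table[[x$peak_name_column]])

#' @rdname feature_names
#' @export
n_samples <- function(x) nrow(x$data_table)

#' @rdname feature_names
#' @export
n_features <- function(x) length(feature_names(x))

#' @rdname feature_names
#' @export
sample_ids <- function(x) as.character(x$data_table[[x$sample_id_column]])

#' @rdname feature_names
#' @export
positive_label <- function(x) {
  labs <- sort(unique(as.character(x$data_table[[x$outcome_column]])))
  if (!is.null(x$positive_label)) {
    if (!as.character(x$positive_label) %in% labs) {
      stop_metabench("positive_label is not an observed outcome label.",
                     "metabench_outcome_error")
    }
    return(as.character(x$positive_label))
  }
  labs[2L]
}

#' Extract the intensity matrix X and 0/1 outcome vector y
#'
#' @param x A `tidy_dataset`.
#' @param rows Optional sample identifiers selecting a subset of rows.
#' @return `feature_matrix()` an N x M numeric matrix with sample identifiers
#'   as row names; `outcome_vector()` a named 0/1 vector (1 = positive label).
#' @export
feature_matrix <- function(x, rows = NULL) {
  m <- as.matrix(x$data_table[feature_names(x)])
  rownames(m) <- sample_ids(x)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' @rdname feature_matrix
#' @export
outcome_vector <- function(x, rows = NULL) {
  y <- as.integer(as.character(x$data_table[[x$outcome_column]]) ==
                    positive_label(x))
  names(y) <- sample_ids(x)
  if (!is.null(rows)) y <- y[rows]
  y
}

#' Read a two-table tidy dataset from disk
#'
#' Accepts either an Excel workbook (`.xlsx`) with sheets named `"Data"` and
#' `"Peak"`, or a pair of CSV files written by [write_tidy_tables()] (a path
#' prefix expanded to `<prefix>_Data.csv` and `<prefix>_Peak.csv`).
#'
#' @param path Path to the `.xlsx` workbook, or the CSV path prefix.
#' @inheritParams tidy_dataset
#' @return A validated `tidy_dataset`; metabolite column order is preserved.
#' @export
read_tidy_tables <- function(path,
                             outcome_column = "Class",
                             sample_id_column = "SampleID",
                             peak_name_column = "Name",
                             positive_label = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) {
      stop_metabench(paste0("File not found: ", path), "metabench_io_error")
    }
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_metabench("Reading .xlsx requires the 'readxl' package.",
                     "metabench_io_error")
    }
    sheets <- readxl::excel_sheets(path)
    for (s in c("Data", "Peak")) {
      if (!s %in% sheets) {
        stop_metabench(paste0("Workbook has no sheet named '", s, "'."),
                       "metabench_format_error")
      }
    }
    d <- readxl::read_excel(path, sheet = "Data")
    p <- readxl::read_excel(path, sheet = "Peak")
  } else {
    files <- paste0(path, c("_Data.csv", "_Peak.csv"))
    if (!all(file.exists(files))) {
      stop_metabench(
        paste0("Expected CSV pair not found: ",
               paste(files[!file.exists(files)], collapse = ", ")),
        "metabench_format_error"
      )
    }
    d <- readr::read_csv(files[1], show_col_types = FALSE, progress = FALSE)
    p <- readr::read_csv(files[2], show_col_types = FALSE, progress = FALSE)
  }
  tidy_dataset(d, p,
               outcome_column = outcome_column,
               sample_id_column = sample_id_column,
               peak_name_column = peak_name_column,
               positive_label = positive_label)
}

#' Write a tidy dataset to a CSV pair
#'
#' Serialises the Data and Peak tables to `<prefix>_Data.csv` and
#' `<prefix>_Peak.csv` such that [read_tidy_tables()] on the same prefix
#' returns an identical dataset.
#'
#' @param dataset A valid `tidy_dataset`.
#' @param path Output path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_tidy_tables <- function(dataset, path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    stop_metabench(
      "Writing .xlsx is not supported; write the CSV pair instead (pass a path prefix without extension).",
      "metabench_io_error"
    )
  }
  validate_tidy_dataset(dataset)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_metabench(paste0("Directory does not exist: ", dir),
                   "metabench_io_error")
  }
  readr::write_csv(dataset$data_table, paste0(path, "_Data.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$peak_table, paste0(path, "_Peak.csv"),
                   progress = FALSE)
  invisible(path)
}
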