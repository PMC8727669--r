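#' Construct and validate a tidy concentration table
#'
#' The canonical input of the framework is a long table with one row per
#' measured concentration: a donor, an experimental arm (optional grouping of
#' contexts, e.g. a cell-culture system), a context in which the stimulus
#' acts, whether the stimulus was present or absent, the analyte measured,
#' and its concentration in pg/mL. Missing supernatants are recorded as `NA`
#' concentrations, never as zero.
#'
#' @param x A data frame with columns `donor`, `context`, `stimulus_state`,
#'   `analyte`, `concentration`, and optionally `arm` (defaults to a single
#'   arm `"arm1"`).
#' @return A validated tibble of class `ctx_table` with the canonical column
#'   order.
#' @export
concentration_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"arm" %in% names(x)) x$arm <- "arm1"
  missing_cols <- setdiff(CTX_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[CTX_COLUMNS]
  x$donor <- as.character(x$donor)
  x$arm <- as.character(x$arm)
  x$context <- as.character(x$context)
  x$stimulus_state <- as.character(x$stimulus_state)
  x$analyte <- as.character(x$analyte)
  x$concentration <- suppressWarnings(as.numeric(x$concentration))
  validate_concentration_table(x)
  structure(x, class = c("ctx_table", class(x)))
}

validate_concentration_table <- function(x) {
  bad_state <- setdiff(unique(x$stimulus_state), CTX_STATES)
  if (length(bad_state) > 0) {
    stop("stimulus_state must be one of ",
         paste(CTX_STATES, collapse = "/"), "; found: ",
         paste(bad_state, collapse = ", "), call. = FALSE)
  }
  neg <- !is.na(x$concentration) & x$concentration < 0
  if (any(neg)) {
    stop("negative concentrations in ", sum(neg), " record(s)", call. = FALSE)
  }
  key <- paste(x$donor, x$arm, x$context, x$analyte, x$stimulus_state,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(key[dup])
    stop("duplicate (donor, context, analyte, stimulus_state) key(s): ",
         paste(head(gsub("\r", "/", offenders), 5), collapse = "; "),
         if (length(offenders) > 5) " ..." else "",
         call. = FALSE)
  }
  invisible(x)
}

#' Read a concentration table from CSV/TSV
#'
#' Accepts either the tidy long layout or a wide-by-analyte layout (one
#' column per analyte) which is melted to long form. Column names can be
#' remapped through a dialect: a named list (or YAML file) mapping canonical
#' field names (`donor`, `arm`, `context`, `stimulus_state`, `analyte`,
#' `concentration`) to the names used in the file, plus optional entries
#' `analyte_columns` (character vector marking a wide layout), `delimiter`,
#' and `state_labels` (named character vector translating the file's
#' stimulus-state labels to `present`/`absent`).
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Optional dialect: a named list or the path to a YAML file.
#' @return A validated [concentration_table()].
#' @export
read_concentration_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- yaml::read_yaml(dialect)
  }
  dialect <- dialect %||% list()

  delim <- dialect$delimiter %||%
    (if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else
       detect_delimiter(path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"))

  rename_map <- dialect[intersect(names(dialect), CTX_COLUMNS)]
  for (canon in names(rename_map)) {
    user <- rename_map[[canon]]
    if (!user %in% names(raw)) {
      stop("dialect maps '", canon, "' to column '", user,
           "' which is absent from the file", call. = FALSE)
    }
    names(raw)[names(raw) == user] <- canon
  }

  wide_cols <- dialect$analyte_columns
  if (!is.null(wide_cols)) {
    absent <- setdiff(wide_cols, names(raw))
    if (length(absent) > 0) {
      stop("analyte column(s) not in file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    raw <- tidyr::pivot_longer(raw, cols = dplyr::all_of(wide_cols),
                               names_to = "analyte",
                               values_to = "concentration")
  }

  if (!is.null(dialect$state_labels)) {
    labels <- unlist(dialect$state_labels)
    raw$stimulus_state <- ifelse(raw$stimulus_state %in% names(labels),
                                 labels[raw$stimulus_state],
                                 raw$stimulus_state)
  }

  needed <- setdiff(CTX_COLUMNS, "arm")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  concentration_table(raw)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"), function(d)
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
    integer(1))
  names(counts)[which.max(counts)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize an experimental design
#'
#' Counts donors, contexts, analytes and stimulus states; reports the
#' expected number of measurements under a fully crossed design, how many
#' were observed, and whether every donor appears in every context-by-state
#' cell. Counts are computed per arm and pooled: the expected total is the
#' sum over arms of donors x contexts x analytes x states within each arm.
#'
#' @param table A [concentration_table()].
#' @return A one-row tibble with fields `n_donors`, `n_contexts`,
#'   `n_analytes`, `n_stimulus_states`, `n_expected_measurements`,
#'   `n_observed`, `n_missing`, `n_condition_observations` (distinct
#'   (donor, context, state) triples, pooled over arms) and `is_balanced`.
#' @export
summarize_design <- function(table) {
  if (nrow(table) == 0) stop("empty concentration table", call. = FALSE)
  per_arm <- dplyr::summarise(
    dplyr::group_by(table, .data$arm),
    n_donors = dplyr::n_distinct(.data$donor),
    n_contexts = dplyr::n_distinct(.data$context),
    n_analytes = dplyr::n_distinct(.data$analyte),
    n_states = dplyr::n_distinct(.data$stimulus_state),
    expected = .data$n_donors * .data$n_contexts * .data$n_analytes *
      .data$n_states,
    .groups = "drop")

  cells <- dplyr::distinct(table, .data$arm, .data$donor, .data$context,
                           .data$stimulus_state)
  cell_counts <- dplyr::count(cells, .data$arm, .data$context,
                              .data$stimulus_state)
  balanced <- all(vapply(split(cell_counts, cell_counts$arm), function(cc) {
    nd <- per_arm$n_donors[match(cc$arm[1], per_arm$arm)]
    all(cc$n == nd) &&
      nrow(cc) == per_arm$n_contexts[match(cc$arm[1], per_arm$arm)] *
        per_arm$n_states[match(cc$arm[1], per_arm$arm)]
  }, logical(1)))

  n_expected <- sum(per_arm$expected)
  n_observed <- sum(!is.na(table$concentration))
  tibble::tibble(
    n_donors = dplyr::n_distinct(table$donor),
    n_contexts = dplyr::n_distinct(paste(table$arm, table$context)),
    n_analytes = dplyr::n_distinct(table$analyte),
    n_stimulus_states = dplyr::n_distinct(table$stimulus_state),
    n_expected_measurements = n_expected,
    n_observed = n_observed,
    n_missing = n_expected - n_observed,
    n_condition_observations = nrow(cells),
    is_balanced = balanced)
}

#' Write a results table to CSV
#'
#' Writes any flat tabular result with a stable column order so that
#' rereading the file reproduces the table.
#'
#' @param results A data frame.
#' @param path Output file path.
#' @export
write_results_table <- function(results, path) {
  results <- as.data.frame(results)
  ok <- tryCatch({
    readr::write_csv(results, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
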