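#' Long-format response panels
#'
#' A response panel holds repeated binary symptom indicators for one or two
#' processes (soiling, constipation) in long format: one row per child,
#' process and wave, with `value` 0, 1 or `NA` (missing). Wave indices are
#' 0-based; age labels are display metadata only.
#'
#' `validate_panel()` checks the contract and returns the panel invisibly;
#' `panel_matrix()` extracts one process as a children-by-waves 0/1/NA matrix
#' with `child_id` rownames, the shape the model fitters consume.
#'
#' @param panel A data frame with columns `child_id`, `process`, `wave`,
#'   `value`.
#' @param process Which process to extract (`"soiling"` or `"constipation"`).
#' @name response_panel
NULL

#' @rdname response_panel
#' @export
validate_panel <- function(panel) {
  need <- c("child_id", "process", "wave", "value")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(panel$value %in% c(0L, 1L) | is.na(panel$value)))
  if (length(bad)) {
    abort(paste0(
      "panel values must be 0, 1 or NA; first offending row: ", bad[1],
      " (value ", panel$value[bad[1]], ")"
    ))
  }
  dup <- duplicated(panel[c("child_id", "process", "wave")])
  if (any(dup)) {
    abort(paste0(
      "duplicate (child_id, process, wave) rows; first duplicate row: ",
      which(dup)[1]
    ))
  }
  invisible(panel)
}

#' @rdname response_panel
#' @export
panel_matrix <- function(panel, process) {
  stopifnot(is.character(process), length(process) == 1)
  sub <- dplyr::filter(panel, .data$process == !!process)
  if (nrow(sub) == 0) {
    abort(paste0("panel contains no rows for process '", process, "'"))
  }
  wide <- tidyr::pivot_wider(
    sub[c("child_id", "wave", "value")],
    names_from = "wave", values_from = "value", names_sort = TRUE
  )
  Y <- as.matrix(wide[-1])
  storage.mode(Y) <- "double"
  rownames(Y) <- as.character(wide$child_id)
  colnames(Y) <- paste0("w", colnames(Y))
  Y
}

# Inverse of panel_matrix: matrix -> long tibble rows for one process.
matrix_panel <- function(Y, process) {
  tibble::tibble(
    child_id = rep(rownames(Y), each = ncol(Y)),
    process = process,
    wave = rep(seq_len(ncol(Y)) - 1L, times = nrow(Y)),
    value = as.double(as.vector(t(Y)))
  )
}

#' Restrict a panel to children with enough observed waves
#'
#' Reproduces the published inclusion rule: keep children with at least
#' `min_waves` non-missing waves. With `process = "both"` (the analytic-sample
#' rule, max n = 8435 in the source cohort) the rule must hold for soiling and
#' constipation simultaneously; with `process = "soiling"` or
#' `"constipation"` it is applied to that process only (e.g. the n = 8979
#' constipation-only sample) and rows for the other process are dropped for
#' excluded children too.
#'
#' @param panel long-format panel (see [response_panel]).
#' @param min_waves minimum number of non-missing waves (default 3).
#' @param process `"both"`, `"soiling"` or `"constipation"`.
#' @return the filtered panel (same columns, fewer children).
#' @export
apply_inclusion_filter <- function(panel, min_waves = 3, process = c("both", "soiling", "constipation")) {
  process <- match.arg(process)
  validate_panel(panel)
  n_waves <- panel %>%
    dplyr::group_by(.data$process) %>%
    dplyr::summarise(n = dplyr::n_distinct(.data$wave), .groups = "drop")
  check <- if (process == "both") n_waves$n else n_waves$n[n_waves$process == process]
  if (any(min_waves > check)) {
    abort("min_waves exceeds the number of waves in the panel")
  }
  counts <- panel %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::count(.data$child_id, .data$process, name = "n_obs")
  keep <- if (process == "both") {
    procs <- unique(panel$process)
    counts %>%
      dplyr::filter(.data$n_obs >= min_waves) %>%
      dplyr::count(.data$child_id, name = "n_proc") %>%
      dplyr::filter(.data$n_proc == length(procs)) %>%
      dplyr::pull(.data$child_id)
  } else {
    counts %>%
      dplyr::filter(.data$process == !!process, .data$n_obs >= min_waves) %>%
      dplyr::pull(.data$child_id)
  }
  dplyr::filter(panel, .data$child_id %in% keep)
}

#' Read and write response panels
#'
#' Panels are stored as plain comma-separated text. The long format has
#' columns `child_id,process,wave,value`; the wide format one row per child
#' and process with columns `w0`, `w1`, ... Missing values are empty fields.
#' `read_panel()` validates values and rejects duplicate keys with the
#' offending row number; a write/read round trip reproduces the panel
#' including its missingness pattern.
#'
#' @param path file path.
#' @param format `"long"` or `"wide"`.
#' @param panel a long-format panel tibble.
#' @return `read_panel()` returns a long-format panel tibble sorted by
#'   (process, child_id, wave); `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             child_id = readr::col_character(),
                             process = readr::col_character(),
                             wave = readr::col_integer(),
                             value = readr::col_double()
                           ))
  } else {
    wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    raw <- tidyr::pivot_longer(wide, dplyr::starts_with("w"),
                               names_to = "wave", values_to = "value") %>%
      dplyr::mutate(
        wave = as.integer(sub("^w", "", .data$wave)),
        child_id = as.character(.data$child_id)
      ) %>%
      dplyr::select("child_id", "process", "wave", "value")
    # a single wide file shares one column set across processes, so a wave a
    # process never administered shows up as an all-missing column: drop it
    raw <- raw %>%
      dplyr::group_by(.data$process, .data$wave) %>%
      dplyr::filter(!all(is.na(.data$value))) %>%
      dplyr::ungroup()
  }
  validate_panel(raw)
  dplyr::arrange(raw, .data$process, .data$child_id, .data$wave)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path, format = c("long", "wide")) {
  format <- match.arg(format)
  validate_panel(panel)
  out <- dplyr::arrange(panel, .data$process, .data$child_id, .data$wave)
  if (format == "wide") {
    out <- tidyr::pivot_wider(out, names_from = "wave", values_from = "value",
                              names_prefix = "w", names_sort = TRUE)
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
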