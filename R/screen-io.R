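#' Coerce and validate a long-format screen table
#'
#' Checks the screen dialect: columns `experiment_id`, `ligands`, `replicate`,
#' `time_min`, `protein`, `fold_change`; strictly positive fold changes; a
#' t = 0 baseline equal to 1 for every (experiment, replicate, protein)
#' series; a common time grid across experiments.
#'
#' @param x A data frame in the screen dialect.
#' @return `x` as a tibble of class `phos_screen`.
#' @export
as_screen <- function(x) {
  required <- c("experiment_id", "ligands", "replicate", "time_min",
                "protein", "fold_change")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Screen table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x <- tibble::as_tibble(x)

  bad <- which(!is.finite(x$fold_change) | x$fold_change <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive or non-finite fold_change in row(s) %s.",
      paste(head(bad, 10), collapse = ", ")
    ))
  }

  base <- x |>
    dplyr::group_by(.data$experiment_id, .data$replicate, .data$protein) |>
    dplyr::summarise(
      has_t0 = any(.data$time_min == 0),
      t0_ok = all(abs(.data$fold_change[.data$time_min == 0] - 1) < 1e-9),
      .groups = "drop"
    )
  if (any(!base$has_t0)) {
    miss <- base[!base$has_t0, ]
    abort(sprintf(
      "Missing t = 0 baseline for %d series (first: %s / rep %s / %s).",
      nrow(miss), miss$experiment_id[1], miss$replicate[1], miss$protein[1]
    ))
  }
  if (any(!base$t0_ok)) {
    off <- base[!base$t0_ok, ]
    abort(sprintf(
      "t = 0 fold_change differs from 1 for %d series (first: %s / rep %s / %s).",
      nrow(off), off$experiment_id[1], off$replicate[1], off$protein[1]
    ))
  }

  grids <- x |>
    dplyr::distinct(.data$experiment_id, .data$time_min) |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(grid = paste(sort(.data$time_min), collapse = ","),
                     .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1) {
    abort("Experiments do not share a common time grid.")
  }

  class(x) <- unique(c("phos_screen", class(x)))
  x
}

#' Read a screen CSV
#'
#' Reads the UTF-8, comma-separated screen dialect (header
#' `experiment_id,ligands,replicate,time_min,protein,fold_change`; `ligands`
#' is a `+`-joined set of 1-2 ligand codes) and validates it with
#' [as_screen()]. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated `phos_screen` tibble.
#' @export
read_screen <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      experiment_id = readr::col_character(),
      ligands = readr::col_character(),
      replicate = readr::col_integer(),
      time_min = readr::col_double(),
      protein = readr::col_character(),
      fold_change = readr::col_double()
    )
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed screen rows at line(s) %s of %s.",
      paste(head(unique(probs$row), 10), collapse = ", "), path
    ))
  }
  as_screen(x)
}

#' Write a screen CSV
#' @param screen A screen tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  screen <- as_screen(screen)
  readr::write_csv(screen, path)
  invisible(path)
}

#' Proteins and ligands present in a screen
#' @param screen A screen tibble.
#' @return Character vector of names, sorted.
#' @export
screen_proteins <- function(screen) sort(unique(screen$protein))

#' @rdname screen_proteins
#' @export
screen_ligands <- function(screen) {
  sort(unique(unlist(strsplit(unique(screen$ligands), "+", fixed = TRUE))))
}
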