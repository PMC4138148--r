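#' Read and write survey CSV files
#'
#' Surveys are exchanged as UTF-8 CSV with a header row, one child per row
#' and missing values as empty cells. Numeric fields are written with full
#' precision, so `read_survey_csv(write_survey_csv(x))` reproduces `x`
#' exactly for legal datasets.
#'
#' @param dataset a `bll_survey`.
#' @param path file path.
#' @param codebook a `bll_codebook` used to type and validate columns;
#'   defaults to the dataset attribute (writing) and [default_codebook()]
#'   (reading).
#' @return `read_survey_csv()` returns a `bll_survey`; `write_survey_csv()`
#'   returns `path` invisibly.
#' @export
write_survey_csv <- function(dataset, path,
                             codebook = attr(dataset, "codebook")) {
  out <- dataset
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    } else {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, codebook = default_codebook()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", na.strings = "")
  known_numeric <- c("age", "bll")
  cat_entries <- Filter(function(e) e$kind != "continuous", codebook$entries)
  cont_names <- vapply(Filter(function(e) e$kind == "continuous",
                              codebook$entries), function(e) e$name, "")
  known <- c("id", "area", known_numeric, cont_names,
             vapply(cat_entries, function(e) e$name, ""))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid("unknown column(s): %s", paste(unknown, collapse = ", "))
  }

  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      stop_invalid("row %d, column '%s': non-numeric value '%s'",
                   bad[1], col, raw[[col]][bad[1]])
    }
    v
  }
  out <- raw
  for (col in intersect(c(known_numeric, cont_names), names(raw))) {
    out[[col]] <- parse_num(col)
  }
  if ("bll" %in% names(out) && any(!is.na(out$bll) & out$bll <= 0)) {
    stop_invalid("row %d, column 'bll': must be > 0",
                 which(!is.na(out$bll) & out$bll <= 0)[1])
  }
  if ("area" %in% names(out)) {
    bad <- which(!is.na(out$area) & !out$area %in% c("exposed", "reference"))
    if (length(bad)) {
      stop_invalid("row %d, column 'area': illegal value '%s'", bad[1],
                   out$area[bad[1]])
    }
    out$area <- factor(out$area, levels = c("exposed", "reference"))
  }
  for (e in cat_entries) {
    if (!e$name %in% names(out)) next
    v <- out[[e$name]]
    bad <- which(!is.na(v) & !v %in% e$categories)
    if (length(bad)) {
      stop_invalid("row %d, column '%s': illegal category '%s'", bad[1],
                   e$name, v[bad[1]])
    }
    out[[e$name]] <- factor(v, levels = e$categories)
  }
  structure(out, codebook = codebook, class = c("bll_survey", "data.frame"))
}

#' Export an encoded design for debugging
#'
#' Writes the binary response and the dense dummy-expanded design matrix
#' (current scale) as one CSV.
#'
#' @param encoded a `bll_encoded`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_encoded_csv <- function(encoded, path) {
  out <- data.frame(y = encoded$y, encoded$X, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write a simulation configuration as JSON
#'
#' Round-trips every field of a [sim_config()], including the codebook, so
#' a synthetic cohort is reproducible from the file alone.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$codebook <- x$codebook$entries
  # named atomic vectors serialize as bare arrays; lists keep their names
  veclist <- function(z) lapply(z, function(v) {
    if (is.list(v)) lapply(v, as.list) else as.list(v)
  })
  x$category_probs <- veclist(x$category_probs)
  x$true_log_odds <- veclist(x$true_log_odds)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- read_config_file(path)
  cb <- codebook(lapply(raw$codebook, function(e) {
    codebook_entry(e$name, e$kind, unlist(e$categories))
  }))
  # named vectors come back as (possibly nested) named lists of scalars
  listify <- function(x) lapply(x, function(v) {
    if (is.list(v) && any(vapply(v, is.list, NA))) {
      lapply(v, function(w) unlist(w))
    } else {
      unlist(v)
    }
  })
  sim_config(n_children = raw$n_children, area_split = raw$area_split,
             codebook = cb,
             category_probs = listify(raw$category_probs),
             bll_median_exposed = raw$bll_median_exposed,
             bll_median_reference = raw$bll_median_reference,
             bll_iqr_exposed = raw$bll_iqr_exposed,
             bll_iqr_reference = raw$bll_iqr_reference,
             true_log_odds = listify(raw$true_log_odds),
             outcome_intercept = raw$outcome_intercept %||% NA_real_,
             threshold = raw$threshold,
             missing_rates = raw$missing_rates %||% list(),
             seed = raw$seed)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
}
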