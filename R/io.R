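#' Read and validate a delimited measurement table
#'
#' Shared reader for the pipeline's tabular inputs. The delimiter is
#' sniffed from the file extension (`.csv` = comma, anything else = tab),
#' headers are matched case-insensitively against the schema, cells are
#' type-checked, and errors carry row/column context. Both LF and CRLF
#' line endings are accepted; files must be UTF-8 with decimal points.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"` or `"character"`).
#' @param optional Character vector of schema columns that may be absent.
#' @return A tibble with the schema's (canonical, lower-case) column names.
#' @export
read_tabular <- function(path, schema, optional = character()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, trim_ws = TRUE)
  if (nrow(raw) == 0) abort(paste0("Empty table: ", path))
  names(raw) <- tolower(names(raw))
  need <- setdiff(names(schema), optional)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("Missing column(s) in ", basename(path), ": ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (col in intersect(names(schema), names(raw))) {
    vals <- raw[[col]]
    if (schema[[col]] == "numeric") {
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(num) & !is.na(vals) & vals != "")
      if (length(bad)) {
        abort(sprintf("Non-numeric value '%s' in column '%s', row %d of %s.",
                      vals[bad[1]], col, bad[1], basename(path)))
      }
      out[[col]] <- num
    } else {
      out[[col]] <- vals
    }
  }
  out
}

#' @rdname read_tabular
#' @details `read_degradation()` expects `time_days`,
#'   `concentration_mg_per_L` and optional `replicate`, `compound_id`;
#'   `read_dose_response()` expects `concentration_mg_per_L` plus either
#'   `viability_pct` or `od600_treated`/`od600_control`;
#'   `read_luminescence()` expects `role`, `dilution_pct`, `i0`, `i15`,
#'   optional `replicate`; `read_analytes()` expects `analyte_id`, `mode`,
#'   `time_days`, `value`, optional `loq`.
#' @export
read_degradation <- function(path) {
  out <- read_tabular(path, c(time_days = "numeric",
                              concentration_mg_per_l = "numeric",
                              replicate = "character",
                              compound_id = "character"),
                      optional = c("replicate", "compound_id"))
  dplyr::rename(out, concentration_mg_per_L = "concentration_mg_per_l")
}

#' @rdname read_tabular
#' @export
read_dose_response <- function(path) {
  out <- read_tabular(path, c(concentration_mg_per_l = "numeric",
                              viability_pct = "numeric",
                              od600_treated = "numeric",
                              od600_control = "numeric"),
                      optional = c("viability_pct", "od600_treated",
                                   "od600_control"))
  if (!"viability_pct" %in% names(out) &&
      !all(c("od600_treated", "od600_control") %in% names(out))) {
    abort("Need `viability_pct` or `od600_treated` + `od600_control`.")
  }
  dplyr::rename(out, concentration_mg_per_L = "concentration_mg_per_l")
}

#' @rdname read_tabular
#' @export
read_luminescence <- function(path) {
  read_tabular(path, c(role = "character", dilution_pct = "numeric",
                       i0 = "numeric", i15 = "numeric",
                       replicate = "character"),
               optional = "replicate")
}

#' @rdname read_tabular
#' @export
read_analytes <- function(path) {
  read_tabular(path, c(analyte_id = "character", mode = "character",
                       time_days = "numeric", value = "numeric",
                       loq = "numeric"),
               optional = "loq")
}

#' Read a feature (ASV) count table
#'
#' Reads a TSV feature table in either orientation. The QIIME2 export
#' convention (first column `#OTU ID` or `Feature ID`, samples as columns)
#' is detected from the header and transposed to the samples-by-ASV layout
#' used throughout; otherwise the first column is taken as the sample id.
#'
#' @param path Path to a TSV feature table.
#' @return A samples-by-ASV count matrix.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "# Constructed")]  # biom TSV preamble
  raw <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(), progress = FALSE)
  first <- names(raw)[1]
  m <- as.matrix(raw[-1])
  rownames(m) <- as.character(raw[[1]])
  if (tolower(first) %in% c("#otu id", "feature id", "asv_id")) {
    m <- t(m)  # ASVs were rows
  }
  as_asv_matrix(m)
}

#' Read a QIIME2-style taxonomy table
#'
#' @param path TSV with columns `Feature ID` and `Taxon`.
#' @return A tibble with `asv_id`, parsed ranks and `genus`.
#' @export
read_taxonomy <- function(path) {
  raw <- read_tabular(path, c(`feature id` = "character",
                              taxon = "character"))
  ranks <- parse_qiime2_taxonomy(raw$taxon)
  dplyr::bind_cols(tibble::tibble(asv_id = raw[["feature id"]]), ranks)
}

#' Write a deterministic JSON analysis report
#'
#' Serialises a named list of results to JSON with alphabetically sorted
#' keys, echoing the package version, the seed and any configuration so
#' that identical inputs produce byte-identical reports.
#'
#' @param results Named list of serialisable results (tibbles become
#'   arrays of records).
#' @param path Output path.
#' @param seed Seed used for any stochastic step (echoed; may be `NULL`).
#' @param config Named list of configuration values (echoed).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = list()) {
  if (!is.list(results) || is.null(names(results)) ||
      any(names(results) == "")) {
    abort("`results` must be a fully named list.")
  }
  payload <- c(
    list(package = "dcfbiodeg",
         version = as.character(utils::packageVersion("dcfbiodeg")),
         seed = seed, config = config),
    results
  )
  sort_keys <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(names(x))) {
      x <- lapply(x, sort_keys)
      x[order(names(x))]
    } else x
  }
  json <- jsonlite::toJSON(sort_keys(payload), auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", pretty = TRUE)
  con <- file(path, open = "wb")  # byte-stable across platforms
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}
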