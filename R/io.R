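# Documented CSV schemas: column name -> class; `key` columns must be
# jointly unique; iso3 columns are validated as three uppercase letters.
table_schemas <- list(
  surveys = list(
    cols = c(iso3 = "character", year = "integer", prevalence = "numeric",
             sample_size = "numeric"),
    key = c("iso3", "year", "prevalence", "sample_size")
  ),
  hierarchy = list(
    cols = c(iso3 = "character", region = "character"),
    key = "iso3"
  ),
  envelopes = list(
    cols = c(cause = "character", iso3 = "character", year = "integer",
             sex = "character", age_group = "character",
             measure = "character", value = "numeric"),
    key = c("cause", "iso3", "year", "sex", "age_group", "measure")
  ),
  population = list(
    cols = c(iso3 = "character", year = "integer", sex = "character",
             age_group = "character", pop = "numeric"),
    key = c("iso3", "year", "sex", "age_group")
  ),
  transfer_paf = list(
    cols = c(pair_id = "character", iso3 = "character", year = "integer",
             paf = "numeric"),
    key = c("pair_id", "iso3", "year")
  ),
  pairs = list(
    cols = c(pair_id = "character", risk_factor = "character",
             outcome = "character", paf_mode = "character",
             rr_point = "numeric", rr_lo = "numeric", rr_hi = "numeric",
             measures = "character"),
    key = "pair_id"
  ),
  exposure_surface = list(
    cols = c(iso3 = "character", year = "integer", prevalence = "numeric",
             se_logit = "numeric", extrapolated = "logical"),
    key = c("iso3", "year")
  ),
  burden = list(
    cols = c(pair_id = "character", iso3 = "character", year = "integer",
             sex = "character", age_group = "character",
             measure = "character", value = "numeric"),
    key = c("pair_id", "iso3", "year", "sex", "age_group", "measure")
  )
)

#' Read a documented tidy-CSV table
#'
#' Reads one of the package's CSV interfaces with strict schema checking:
#' the header must contain exactly the documented columns, key columns
#' must be jointly unique, and `iso3` codes must be three uppercase
#' letters. A file with valid headers and no rows is an empty table, not
#' an error.
#'
#' @param path CSV path.
#' @param schema one of `r paste(names(table_schemas), collapse = ", ")`.
#' @return data.frame with the documented column types.
#' @export
read_table <- function(path, schema) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(df), names(sch$cols))
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing) || length(extra)) {
    stop(sprintf("%s: schema mismatch (missing: %s; unexpected: %s)",
                 basename(path),
                 paste(c(missing, "-")[1:max(1, length(missing))], collapse = ","),
                 paste(c(extra, "-")[1:max(1, length(extra))], collapse = ",")),
         call. = FALSE)
  }
  df <- df[names(sch$cols)]
  for (cl in names(sch$cols)) {
    df[[cl]] <- switch(sch$cols[[cl]],
                       character = as.character(df[[cl]]),
                       integer = as.integer(df[[cl]]),
                       numeric = as.numeric(df[[cl]]),
                       logical = as.logical(df[[cl]]))
  }
  if ("iso3" %in% names(df) && nrow(df)) {
    bad <- !grepl("^[A-Z]{3}$", df$iso3)
    if (any(bad)) {
      stop(sprintf("%s: non-ISO3 country code '%s' (row %d)", basename(path),
                   df$iso3[which(bad)[1]], which(bad)[1]), call. = FALSE)
    }
  }
  if (nrow(df) && anyDuplicated(df[sch$key])) {
    i <- anyDuplicated(df[sch$key])
    stop(sprintf("%s: duplicated key (%s) at row %d", basename(path),
                 paste(sch$key, collapse = ","), i), call. = FALSE)
  }
  df
}

#' Write a table as tidy CSV
#'
#' Plain UTF-8 CSV with "." decimal separator; numeric columns are
#' serialised at full precision (17 significant digits) so a write/read
#' round trip is lossless. Rounding is applied only when formatting
#' reports, never in data files.
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      out[[cl]] <- sub("^((-?\\d+)(\\.\\d*[1-9])?)0*$", "\\1",
                       sprintf("%.17g", out[[cl]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# md5 of the packaged global-estimates fixture, pinned at build time
TABLE1_MD5 <- "bce2eab3e26834ebcb5879a0a77ce42a"

#' Load the packaged table of published global estimates
#'
#' A transcription of the published global totals of attributable deaths
#' and DALY (and per-100 000 working-age rates) for the 41 occupational
#' risk-factor/health-outcome pairs in 2000, 2010 and 2016. The file's
#' checksum and shape (41 rows, non-negative counts, zero deaths for the
#' non-fatal hearing-loss and back/neck-pain outcomes) are verified on
#' load.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @param verify_checksum verify the packaged file's md5 (disable when
#'   pointing at a modified copy).
#' @return data.frame with columns `pair_id, risk_factor, outcome`,
#'   `deaths_<year>`, `deaths_rate_<year>`, `daly_<year>`,
#'   `daly_rate_<year>` for years 2000, 2010, 2016.
#' @export
load_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "attribwork"),
                        verify_checksum = TRUE) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("fixture file not found", call. = FALSE)
  }
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE1_MD5)) {
      stop("fixture integrity error: checksum mismatch", call. = FALSE)
    }
  }
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  count_cols <- c(outer(c("deaths_", "daly_"), c(2000, 2010, 2016), paste0))
  rate_cols <- c(outer(c("deaths_rate_", "daly_rate_"), c(2000, 2010, 2016),
                       paste0))
  check_columns(df, c("pair_id", "risk_factor", "outcome", count_cols,
                      rate_cols), "table1")
  if (nrow(df) != 41L) {
    stop(sprintf("fixture integrity error: %d rows, expected 41", nrow(df)),
         call. = FALSE)
  }
  if (any(as.matrix(df[count_cols]) < 0) || any(as.matrix(df[rate_cols]) < 0)) {
    stop("fixture integrity error: negative value", call. = FALSE)
  }
  nonfatal <- df$outcome %in% c("Other hearing loss", "Back and neck pain")
  if (any(df[nonfatal, paste0("deaths_", c(2000, 2010, 2016))] != 0)) {
    stop("fixture integrity error: non-fatal outcome with deaths > 0",
         call. = FALSE)
  }
  df
}

#' Reshape the fixture to long attributable-burden format
#'
#' Convenience for feeding the packaged estimates table into
#' [aggregate_burden()] / [top_pair()]: one row per pair, measure and
#' year with the attributable count in `value`.
#'
#' @param table1 output of [load_table1()].
#' @return data.frame `pair_id, risk_factor, outcome, measure, year, value`.
#' @export
table1_long <- function(table1 = load_table1()) {
  years <- c(2000, 2010, 2016)
  blocks <- lapply(c(deaths = "deaths_", daly = "daly_"), function(prefix) {
    do.call(rbind, lapply(years, function(y) {
      data.frame(pair_id = table1$pair_id, risk_factor = table1$risk_factor,
                 outcome = table1$outcome,
                 measure = sub("_$", "", prefix), year = y,
                 value = table1[[paste0(prefix, y)]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
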