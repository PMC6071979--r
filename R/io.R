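#' Write a clustered allometric dataset to CSV
#'
#' Writes one row per tree with the canonical header
#' `stand_id,tree_id,D_mm,H_cm,ST_g,BR_g,ND_g,RT_g,TB_g` (any extra
#' columns are appended). Numeric fields are written with 17 significant
#' digits so a write/read round trip reproduces them exactly.
#'
#' @param data An `alloc_data` data frame (or any data frame accepted by
#'   [as_alloc_data()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(data, path) {
  stopifnot(is.data.frame(data))
  canonical <- c("stand_id", "tree_id", "D_mm", "H_cm",
                 "ST_g", "BR_g", "ND_g", "RT_g", "TB_g")
  cols <- c(intersect(canonical, names(data)),
            setdiff(names(data), canonical))
  out <- as.data.frame(data, stringsAsFactors = FALSE)[, cols,
                                                       drop = FALSE]
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
      out[[col]][out[[col]] %in% c("nan", "NA", "na")] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a clustered allometric dataset from CSV
#'
#' Expects a header row naming at least `stand_id`, `D_mm` and one
#' response column (`ST_g`, `BR_g`, `ND_g`, `RT_g` or `TB_g`). Stand
#' labels are treated as opaque strings. All measurement columns must be
#' numeric and strictly positive (logs must be defined); violations raise
#' a validation error naming the offending rows. Unknown columns are
#' preserved.
#'
#' @param path CSV file path.
#' @return An `alloc_data` data frame with provenance `"file"`.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = c("", "NA"))
  meas <- intersect(c("D_mm", "H_cm", "ST_g", "BR_g", "ND_g", "RT_g",
                      "TB_g"), names(raw))
  for (col in meas) {
    if (is.character(raw[[col]])) {
      suppressWarnings(num <- as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(num))
      if (length(bad) > 0) {
        stop("validation error: non-numeric values in `", col,
             "` at rows ", paste(utils::head(bad, 10), collapse = ", "),
             call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  if ("stand_id" %in% names(raw)) {
    raw$stand_id <- as.character(raw$stand_id)
  }
  as_alloc_data(raw, provenance = "file")
}
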