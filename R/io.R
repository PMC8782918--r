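#' Write an event table with its acquisition metadata
#'
#' Events are stored as plain CSV or TSV with a commented metadata
#' header: lines of the form `#platefdc key=<json>` precede the column
#' header, carrying everything needed to re-run gating bit-identically
#' (pixel size, gate configuration, generator preset and seed for
#' synthetic data, column units, schema tag and package version).
#'
#' @param events Event tibble (see [as_event_records()]).
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param metadata Named list of metadata to record; entries are
#'   serialised as JSON. Reserved keys `schema` and `package_version` are
#'   added automatically.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("csv", "tsv"),
                         metadata = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(events))
  meta <- c(list(schema = "platefdc-events-v1",
                 package_version =
                   as.character(utils::packageVersion("platefdc")),
                 columns = names(events),
                 units = event_units(names(events))),
            metadata)
  hdr <- vapply(names(meta), function(k) {
    paste0("#platefdc ", k, "=",
           as.character(jsonlite::toJSON(meta[[k]], auto_unbox = TRUE,
                                         digits = NA)))
  }, "")
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(events, con, sep = sep, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

# units of the standard event columns, recorded in the file header;
# unknown columns are rejected so every stored column has a unit
event_units <- function(cols) {
  known <- c(area_um2 = "um^2", perimeter_um = "um",
             deformation = "dimensionless", area_ratio = "dimensionless",
             cd61 = "AU", cd62p = "AU", pac1 = "AU", timestamp = "s",
             true_area = "um^2", true_perimeter = "um",
             true_deformation = "dimensionless",
             aspect_ratio = "dimensionless", orientation = "rad",
             center_x = "um", center_y = "um",
             donor_id = "label", condition_label = "label",
             gate_cd61 = "flag", gate_area_ratio = "flag",
             gate_size = "flag", gate_all = "flag")
  u <- known[cols]
  names(u) <- cols
  if (any(is.na(u))) {
    stop("unknown event column(s) without units: ",
         paste(cols[is.na(u)], collapse = ", "), call. = FALSE)
  }
  as.list(u)
}

#' Read an event table written by [write_events()]
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, or `"auto"` (by file extension).
#' @param required_columns Character vector of columns that must be
#'   present; a clear schema error names any missing one.
#' @return The event tibble with a `metadata` attribute (named list,
#'   parsed from the header).
#' @export
read_events <- function(path, format = c("auto", "csv", "tsv"),
                        required_columns = c("area_um2", "perimeter_um",
                                             "deformation")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv"
              else "csv"
  }
  lines <- readLines(path)
  is_meta <- grepl("^#platefdc ", lines)
  meta_lines <- lines[is_meta]
  meta <- list()
  for (ln in meta_lines) {
    body <- sub("^#platefdc ", "", ln)
    key <- sub("=.*$", "", body)
    meta[[key]] <- jsonlite::fromJSON(sub("^[^=]*=", "", body))
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.csv(text = paste(body, collapse = "\n"), sep = sep,
                        stringsAsFactors = FALSE)
  miss <- setdiff(required_columns, names(df))
  if (length(miss) > 0) {
    stop("event file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "metadata") <- meta
  out
}

#' Read a grayscale image from TIFF or PNG
#'
#' Convenience loader for user-supplied bright-field frames or confocal
#' channels. Multi-channel images are averaged to grayscale unless
#' `channel` selects one.
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param channel Optional channel index for colour images.
#' @return Numeric matrix (rows = y, columns = x) in `[0, 1]`.
#' @export
read_image <- function(path, channel = NULL) {
  lower <- tolower(path)
  arr <- if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the `png` package", call. = FALSE)
    }
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3) {
    arr <- if (is.null(channel)) apply(arr, c(1, 2), mean)
           else arr[, , channel]
  }
  arr
}
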