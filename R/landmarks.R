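#' Construct a landmark table
#'
#' Landmarks are detected anatomical points on a bitewing radiograph: the
#' alveolar bone crestal level (`"ABCL"`, the most coronal point of the
#' alveolar bone next to a tooth) or the cemento-enamel junction (`"CEJ"`,
#' the enamel-cementum boundary used as the fixed reference for bone-loss
#' measurement). They are represented as a plain `data.frame` with columns
#' `x`, `y` (0-based pixel coordinates), `cls` (`"ABCL"` or `"CEJ"`),
#' `confidence` (in `[0, 1]`) and `source` (`"net_a"`, `"net_b"`, `"fused"`
#' or `"oracle"`).
#'
#' @param x,y numeric pixel coordinates (column / row, 0-based).
#' @param cls character, `"ABCL"` or `"CEJ"` (recycled).
#' @param confidence numeric in `[0, 1]` (recycled, default 1).
#' @param source detector provenance (recycled, default `"oracle"`).
#' @return a validated landmark `data.frame`.
#' @examples
#' landmarks(x = c(100, 100), y = c(250, 200), cls = c("ABCL", "CEJ"))
#' @export
landmarks <- function(x = numeric(), y = numeric(), cls = character(),
                      confidence = 1, source = "oracle") {
  n <- length(x)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   cls = rep_len(as.character(cls), n),
                   confidence = rep_len(as.numeric(confidence), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  validate_landmarks(df)
}

#' @rdname landmarks
#' @param df a data frame to validate as a landmark table.
#' @export
validate_landmarks <- function(df) {
  need <- c("x", "y", "cls", "confidence", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_achr("landmark table lacks column(s): ", paste(miss, collapse = ", "),
              class = "achr_parse_error")
  df <- df[need]
  if (nrow(df) == 0) return(df)
  bad <- which(!(df$cls %in% ACH_CLASSES))
  if (length(bad))
    stop_achr("row ", bad[1], ": unknown landmark class '", df$cls[bad[1]],
              "' (expected ABCL or CEJ)", class = "achr_parse_error")
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop_achr("row ", bad[1], ": non-finite coordinates",
              class = "achr_parse_error")
  bad <- which(!is.finite(df$confidence) | df$confidence < 0 | df$confidence > 1)
  if (length(bad))
    stop_achr("row ", bad[1], ": confidence outside [0, 1]",
              class = "achr_parse_error")
  bad <- which(!(df$source %in% ACH_SOURCES))
  if (length(bad))
    stop_achr("row ", bad[1], ": unknown source '", df$source[bad[1]], "'",
              class = "achr_parse_error")
  df
}

#' Read landmark detections from CSV or JSON
#'
#' @param path file path. CSV needs a header row with columns
#'   `x, y, cls, confidence, source`; JSON is an array of objects with the
#'   same keys.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   missing.
#' @return a landmark `data.frame` (see [landmarks()]), record order
#'   preserved.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_achr("landmark file not found: ", path, class = "achr_io_error")
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(cls = "character", source = "character"))
  } else {
    out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(out) == 0) {
      data.frame(x = numeric(), y = numeric(), cls = character(),
                 confidence = numeric(), source = character())
    } else as.data.frame(out, stringsAsFactors = FALSE)
  }
  validate_landmarks(df)
}

#' Write landmarks to CSV or JSON
#'
#' Inverse of [read_landmarks()]; `read_landmarks(write_landmarks(l, p))`
#' reproduces `l`.
#'
#' @param lm landmark `data.frame`.
#' @param path output file path.
#' @inheritParams read_landmarks
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  lm <- validate_landmarks(lm)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    ok <- tryCatch({ write.csv(lm, path, row.names = FALSE, quote = FALSE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_achr("cannot write landmark file: ", path, class = "achr_io_error")
  } else {
    jsonlite::write_json(lm, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write ACH measurements to CSV
#'
#' One row per measured tooth site with columns `image_id, tooth_id, site,
#' cej_x, cej_y, abcl_x, abcl_y, ach_px, ach_mm, severe`. Numeric fields are
#' written with six decimals so that a write/read round trip reproduces the
#' values; `severe` is written as lowercase `true` / `false`.
#'
#' @param measurements measurement `data.frame` (as produced by
#'   [ach_measure()], or empty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("image_id", "tooth_id", "site", "cej_x", "cej_y",
            "abcl_x", "abcl_y", "ach_px", "ach_mm", "severe")
  if (is.null(measurements) || nrow(measurements) == 0) {
    out <- data.frame(matrix(ncol = length(cols), nrow = 0,
                             dimnames = list(NULL, cols)))
  } else {
    miss <- setdiff(cols, names(measurements))
    if (length(miss))
      stop_achr("measurement table lacks column(s): ",
                paste(miss, collapse = ", "), class = "achr_parse_error")
    out <- measurements[cols]
    for (cc in c("cej_x", "cej_y", "abcl_x", "abcl_y", "ach_px", "ach_mm"))
      out[[cc]] <- sprintf("%.6f", out[[cc]])
    out$severe <- ifelse(out$severe, "true", "false")
  }
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_achr("cannot write measurement file: ", path,
                     class = "achr_io_error")
  invisible(path)
}

#' Read an ACH measurement CSV
#'
#' @param path CSV written by [write_measurements()] (or a gold-standard
#'   table in the same schema).
#' @return measurement `data.frame` with logical `severe`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop_achr("measurement file not found: ", path, class = "achr_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(severe = "character"))
  if (nrow(df)) df$severe <- tolower(df$severe) %in% c("true", "1", "t")
  else df$severe <- logical(0)
  df
}
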