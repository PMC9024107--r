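# Localization tables: the currency of every dSTORM stage. Internally a
# plain data.frame with nm coordinates (origin at the field corner, x right,
# y down, matching the row-column convention of rendered images).

#' Construct a localization table
#'
#' A localization table is a `data.frame` with one row per single-molecule
#' localization and the columns `id`, `frame`, `x`, `y` (nm), `sigma` (nm,
#' fitted PSF width), `intensity` (photons), `offset` (photons), `bkgstd`
#' (photons), `uncertainty` (nm, lateral localization precision), `channel`
#' (label) and `detections_merged` (number of raw detections combined into
#' the record, `>= 1`).
#'
#' @param x,y Numeric, coordinates in nm.
#' @param frame Integer frame index, `>= 1`.
#' @param sigma Fitted PSF standard deviation in nm.
#' @param intensity Integrated spot intensity in photons.
#' @param uncertainty Lateral localization precision in nm.
#' @param offset,bkgstd Local background level and noise in photons.
#' @param channel Channel label (e.g. `"A647"`, `"CF568"`).
#' @param id Record ids; defaults to `seq_along(x)`.
#' @param detections_merged Detections combined per record (default 1).
#' @return A `data.frame` of class `loc_table`.
#' @export
loc_table <- function(x, y, frame = 1L, sigma = 120, intensity = 1000,
                      uncertainty = 10, offset = 0, bkgstd = 0,
                      channel = "ch1", id = NULL,
                      detections_merged = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(id)) id <- seq_len(n)
  tab <- data.frame(
    id = as.integer(id),
    frame = as.integer(rep_len(frame, n)),
    x = as.numeric(x), y = as.numeric(y),
    sigma = as.numeric(rep_len(sigma, n)),
    intensity = as.numeric(rep_len(intensity, n)),
    offset = as.numeric(rep_len(offset, n)),
    bkgstd = as.numeric(rep_len(bkgstd, n)),
    uncertainty = as.numeric(rep_len(uncertainty, n)),
    channel = as.character(rep_len(channel, n)),
    detections_merged = as.integer(rep_len(detections_merged, n)),
    stringsAsFactors = FALSE
  )
  validate_loc_table(tab)
  class(tab) <- c("loc_table", "data.frame")
  tab
}

validate_loc_table <- function(tab) {
  need <- c("id", "frame", "x", "y", "sigma", "intensity", "uncertainty")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("localization table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab)) {
    if (!all(is.finite(tab$x)) || !all(is.finite(tab$y)))
      stop("non-finite coordinates in localization table")
    if (any(tab$frame < 1L))
      stop("frame indices must be >= 1")
    if (anyDuplicated(tab$id))
      stop("localization ids must be unique within a table")
    if (!is.null(tab$detections_merged) && any(tab$detections_merged < 1L))
      stop("detections_merged must be >= 1")
  }
  invisible(tab)
}

as_loc_table <- function(tab) {
  if (is.null(tab$channel)) tab$channel <- "ch1"
  if (is.null(tab$detections_merged)) tab$detections_merged <- 1L
  if (is.null(tab$offset)) tab$offset <- 0
  if (is.null(tab$bkgstd)) tab$bkgstd <- 0
  validate_loc_table(tab)
  class(tab) <- c("loc_table", "data.frame")
  tab
}

# ThunderSTORM-style CSV schema (units in the header, as the plugin writes)
.ts_cols <- c(id = "id", frame = "frame", x = "x [nm]", y = "y [nm]",
              sigma = "sigma [nm]", intensity = "intensity [photon]",
              offset = "offset [photon]", bkgstd = "bkgstd [photon]",
              uncertainty = "uncertainty [nm]")

#' Read / write ThunderSTORM-style localization CSV
#'
#' The CSV schema carries units in the column headers
#' (`"x [nm]"`, `"intensity [photon]"`, ...). `channel` and
#' `detections_merged` columns are round-tripped when present.
#'
#' @param path File path.
#' @param channel Channel label to assign on read when the file has no
#'   `channel` column.
#' @return `read_thunderstorm()` returns a [loc_table()];
#'   `write_thunderstorm()` returns `path` invisibly.
#' @export
read_thunderstorm <- function(path, channel = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(.ts_cols)) {
    col <- .ts_cols[[nm]]
    if (col %in% names(raw)) out[[nm]] <- raw[[col]]
    else if (nm %in% names(raw)) out[[nm]] <- raw[[nm]]
  }
  if (is.null(out$id)) out$id <- seq_len(nrow(raw))
  if ("channel" %in% names(raw)) out$channel <- raw$channel
  if (!is.null(channel)) out$channel <- channel
  if ("detections_merged" %in% names(raw))
    out$detections_merged <- as.integer(raw$detections_merged)
  as_loc_table(out)
}

#' @rdname read_thunderstorm
#' @param tab A localization table.
#' @export
write_thunderstorm <- function(tab, path) {
  validate_loc_table(tab)
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (nm in names(.ts_cols))
    out[[.ts_cols[[nm]]]] <- if (!is.null(tab[[nm]])) tab[[nm]] else NA
  out[["channel"]] <- tab$channel
  out[["detections_merged"]] <- tab$detections_merged
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: %d records, %s channel(s), frames %s\n",
              nrow(x),
              length(unique(x$channel)),
              if (nrow(x)) paste(range(x$frame), collapse = "-") else "-"))
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}
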