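## Delimited-text volume format, in the spirit of columnar ASCII PIV
## exports: comment-prefixed header (format version, shape, spacings,
## z-coordinates, optional reconstruction targets) followed by CSV
## columns i,j,k,x,y,z,vx,vy,vz in row-major slice order.  i is the row
## (y) index, j the column (x) index, k the slice index, all 1-based.

#' Write a velocity volume to a delimited-text file
#'
#' @param volume A [velocity_volume].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "velocity_volume"))
    stop_divflow("'volume' must be a velocity_volume")
  ny <- nrow(volume$slices[[1]]$vx); nx <- ncol(volume$slices[[1]]$vx)
  zs <- slice_z(volume)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = " ")
  writeLines(c("# divflow-volume v1",
               sprintf("# shape: %d %d %d", ny, nx, length(zs)),
               sprintf("# spacing: %s", fmt(c(volume$dx, volume$dy,
                                              volume$dz))),
               sprintf("# z: %s", fmt(zs))), con)
  tg <- attr(volume, "targets")
  if (!is.null(tg))
    writeLines(sprintf("# targets: %s", paste(tg, collapse = " ")), con)
  if (!is.null(attr(volume, "method")))
    writeLines(sprintf("# method: %s", attr(volume, "method")), con)
  writeLines("i,j,k,x,y,z,vx,vy,vz", con)
  i <- rep(seq_len(ny), nx)
  j <- rep(seq_len(nx), each = ny)
  for (k in seq_along(zs)) {
    s <- volume$slices[[k]]
    df <- data.frame(i = i, j = j, k = k,
                     x = (j - 1) * volume$dx, y = (i - 1) * volume$dy,
                     z = zs[k],
                     vx = as.vector(s$vx), vy = as.vector(s$vy),
                     vz = as.vector(s$vz))
    utils::write.table(format(df, digits = 17, scientific = NA,
                              trim = TRUE),
                       con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

parse_header_line <- function(lines, key, path, numeric = TRUE) {
  pat <- sprintf("^# %s: *", key)
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  fields <- strsplit(sub(pat, "", hit[1L]), " +")[[1L]]
  if (numeric) as.numeric(fields) else fields
}

#' Read a velocity volume written by [write_volume()]
#'
#' Malformed headers, ragged rows, missing columns and non-finite
#' values raise descriptive parse errors.
#'
#' @param path File path.
#' @return A [velocity_volume]; a `"targets"` attribute is restored if
#'   present in the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_divflow(sprintf("no such file: %s", path))
  head_lines <- grep("^#", readLines(path, n = 50L), value = TRUE)
  if (length(head_lines) == 0L || !grepl("divflow-volume", head_lines[1L]))
    stop_divflow(sprintf("%s: missing 'divflow-volume' header", path))
  shape <- parse_header_line(head_lines, "shape", path)
  spacing <- parse_header_line(head_lines, "spacing", path)
  zs <- parse_header_line(head_lines, "z", path)
  targets <- parse_header_line(head_lines, "targets", path)
  method <- parse_header_line(head_lines, "method", path, numeric = FALSE)
  if (is.null(shape) || length(shape) != 3L || any(is.na(shape)))
    stop_divflow(sprintf("%s: malformed '# shape:' header", path))
  if (is.null(spacing) || length(spacing) != 3L || any(is.na(spacing)))
    stop_divflow(sprintf("%s: malformed '# spacing:' header", path))
  if (is.null(zs) || length(zs) != shape[3L] || any(is.na(zs)))
    stop_divflow(sprintf("%s: malformed '# z:' header", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", header = TRUE,
                    colClasses = "numeric"),
    error = function(e)
      stop_divflow(sprintf("%s: parse error: %s", path, conditionMessage(e))))
  need <- c("i", "j", "k", "vx", "vy", "vz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_divflow(sprintf("%s: missing column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  ny <- shape[1L]; nx <- shape[2L]; nz <- shape[3L]
  if (nrow(df) != ny * nx * nz)
    stop_divflow(sprintf("%s: expected %d data rows, found %d", path,
                         ny * nx * nz, nrow(df)))
  for (cl in need)
    if (any(!is.finite(df[[cl]]))) {
      bad <- which(!is.finite(df[[cl]]))[1L]
      stop_divflow(sprintf("%s: non-finite value in column '%s' (data row %d)",
                           path, cl, bad))
    }
  ord <- order(df$k, df$j, df$i)
  df <- df[ord, , drop = FALSE]
  slices <- lapply(seq_len(nz), function(k) {
    rows <- df[df$k == k, , drop = FALSE]
    if (nrow(rows) != ny * nx)
      stop_divflow(sprintf("%s: slice %d has %d rows, expected %d", path,
                           k, nrow(rows), ny * nx))
    velocity_slice(matrix(rows$vx, ny, nx), matrix(rows$vy, ny, nx),
                   matrix(rows$vz, ny, nx), z = zs[k])
  })
  vol <- velocity_volume(slices, dx = spacing[1L], dy = spacing[2L],
                         dz = spacing[3L])
  if (!is.null(targets)) attr(vol, "targets") <- as.integer(targets)
  if (!is.null(method)) attr(vol, "method") <- method
  vol
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report` from [evaluate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  agg <- attr(report, "aggregate")
  obj <- list(method = attr(report, "method"),
              slices = as.data.frame(report),
              aggregate = as.list(agg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
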