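# Plain-text I/O: umbrella time series (whitespace-delimited, `#` metadata
# headers, time in the first column — the dialect of common biasing-engine
# outputs), TSV profiles and surfaces.

.parse_hash_headers <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write an umbrella time series to a plain-text file
#'
#' Whitespace-delimited columns (time first), with window metadata in `#
#' key: value` header lines.  The round trip through [read_timeseries()] is
#' lossless to full double precision.
#'
#' @param ts a `us_timeseries`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "us_timeseries"))
  meta <- attr(ts, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  writeLines(paste("# columns:", paste(names(ts), collapse = " ")), con)
  writeLines(vapply(seq_len(nrow(ts)), function(i)
    paste(formatC(as.numeric(ts[i, ]), format = "g", digits = 17),
          collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an umbrella time series
#'
#' @param path file written by [write_timeseries()] (or any
#'   whitespace-delimited file with a leading time column and `# key:
#'   value` headers; header order is irrelevant).
#' @return A `us_timeseries`; malformed lines raise an error naming the
#'   line number.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- .parse_hash_headers(lines)
  cols <- strsplit(meta[["columns"]] %||% "time xi theta", "\\s+")[[1]]
  meta[["columns"]] <- NULL
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  vals <- lapply(lines[body_idx], function(l) suppressWarnings(
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric token at line ", body_idx[bad[1]], " of ", path)
  nc <- lengths(vals)
  if (length(unique(nc)) != 1)
    stop("inconsistent column count at line ",
         body_idx[which(nc != nc[1])[1]], " of ", path)
  m <- do.call(rbind, vals)
  if (ncol(m) != length(cols)) cols <- c("time", "xi", "theta")[seq_len(ncol(m))]
  num <- suppressWarnings(lapply(meta, function(v) {
    x <- as.numeric(v)
    if (is.na(x)) v else x
  }))
  if (is.unsorted(m[, 1], strictly = TRUE))
    stop("time column must be strictly increasing in ", path)
  .new_timeseries(time = m[, 1],
                  xi = if ("xi" %in% cols) m[, which(cols == "xi")],
                  theta = if ("theta" %in% cols) m[, which(cols == "theta")],
                  meta = num)
}

#' Write / read a 1D free-energy profile as TSV
#'
#' Columns `xi`, `G` and optionally `counts`, with the zero convention in
#' `#` header lines.
#'
#' @param profile an [fe_profile()].
#' @param path file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   [fe_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# zero: %s", attr(profile, "zero")),
               sprintf("# plateau_from: %g", attr(profile, "plateau_from")),
               paste0("# columns: ", paste(names(profile), collapse = "\t"))),
             con)
  write.table(as.data.frame(profile), con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- .parse_hash_headers(lines)
  cols <- strsplit(meta[["columns"]] %||% "xi\tG", "\t|\\s+")[[1]]
  df <- read.table(text = lines[!grepl("^\\s*#", lines)], sep = "\t",
                   col.names = cols)
  fe_profile(df$xi, df$G, counts = df$counts,
             zero = meta[["zero"]] %||% "plateau",
             plateau_from = as.numeric(meta[["plateau_from"]] %||% 20))
}

#' Write a 2D free-energy surface as long-format TSV
#'
#' Columns xi, angle, G, weight, counts, masked; masked bins carry NA G.
#'
#' @param surface2d an `fe_surface2d`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_surface2d <- function(surface2d, path) {
  stopifnot(inherits(surface2d, "fe_surface2d"))
  long <- expand.grid(xi = surface2d$xi_mid, angle = surface2d$angle_mid)
  long$G <- as.vector(surface2d$G)
  long$weight <- as.vector(surface2d$weight)
  long$counts <- as.vector(surface2d$counts)
  long$masked <- as.integer(as.vector(surface2d$mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# angle_coordinate: %s", surface2d$angle), con)
  writeLines(paste0("# columns: ", paste(names(long), collapse = "\t")), con)
  write.table(long, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
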