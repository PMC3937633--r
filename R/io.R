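#' Read single-cell traces from CSV
#'
#' Expects a comma-separated file with a header containing at least
#' `cell_id`, `time_min` and `value` (optional extra columns such as
#' `division_time_min` or `channel` are kept). Rows with non-numeric times or
#' values, and cells with non-increasing or duplicated times, are rejected
#' with the offending cell and line numbers.
#'
#' @param path Path to the CSV file.
#' @return A long data frame (`cell_id`, `time_min`, `value`, ...). An empty
#'   file yields a zero-row data frame with a warning.
#' @seealso [write_traces()], [split_traces()]
#' @export
read_traces <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trace file: ", path)
    return(df)
  }
  tnum <- suppressWarnings(as.numeric(df$time_min))
  vnum <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(tnum) | !is.finite(vnum))
  if (length(bad))
    stop(sprintf("non-numeric time/value at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path))  # +1 for header
  df$time_min <- tnum; df$value <- vnum
  for (cell in unique(df$cell_id)) {
    rows <- which(df$cell_id == cell)
    t <- df$time_min[rows]
    if (any(diff(t) <= 0)) {
      off <- rows[which(diff(t) <= 0)[1L] + 1L]
      stop(sprintf("non-increasing or duplicated time for cell '%s' at line %d",
                   cell, off + 1L))
    }
  }
  df
}

#' Write single-cell traces to CSV
#'
#' @param traces Long data frame with `cell_id`, `time_min`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("cell_id", "time_min", "value") %in% names(traces)))
  utils::write.csv(format(traces, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a long trace table into per-cell traces
#'
#' @param traces Long data frame with `cell_id`, `time_min` (or `time`) and
#'   `value`.
#' @return Named list of per-cell data frames with columns `time`, `value`.
#' @export
split_traces <- function(traces) {
  stopifnot("cell_id" %in% names(traces))
  tn <- intersect(c("time", "time_min"), names(traces))[1L]
  if (is.na(tn)) stop("no time column")
  lapply(split(traces, factor(traces$cell_id,
                              levels = unique(traces$cell_id))),
         function(d) data.frame(time = d[[tn]], value = d$value))
}

#' Write a trajectory in long format
#'
#' Serializes a [hif_simulate()] result as long-format CSV with columns
#' `time_min`, `variable` (`x`, `y` or `y1`-`y3`), `value`.
#'
#' @param trajectory A `"hif_trajectory"` (or any wide data frame whose first
#'   column is time).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  vars <- names(df)[-1L]
  long <- data.frame(
    time_min = rep(df[[1L]], times = length(vars)),
    variable = rep(vars, each = nrow(df)),
    value = unlist(df[vars], use.names = FALSE))
  utils::write.csv(format(long, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format trajectory
#'
#' @param path CSV written by [write_trajectory()].
#' @return Wide data frame with a `time` column and one column per variable.
#' @export
read_trajectory <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_min", "variable", "value") %in% names(long)))
  vars <- unique(long$variable)
  out <- data.frame(time = unique(long$time_min))
  for (v in vars)
    out[[v]] <- long$value[long$variable == v]
  out
}

#' Write / read a parameter set as structured text
#'
#' Parameter sets are stored as plain `key = value` lines (full double
#' precision), with a `class` line recording the parameter type, so that
#' `read_params(write_params(p)) ` reconstructs `p` exactly.
#'
#' @param params An [hif_params()], [hif_params4()] or [p53_params()] object.
#' @param path Output path.
#' @return `path` invisibly (`write_params`); the reconstructed object
#'   (`read_params`).
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, c("hif_params", "hif_params4", "p53_params")))
  vals <- unclass(params)
  lines <- c(paste0("class = ", class(params)[1L]),
             unlist(lapply(names(vals), function(n) {
               paste0(n, " = ",
                      paste(formatC(vals[[n]], digits = 17, format = "g"),
                            collapse = ", "))
             })))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  cls <- sub("^class\\s*=\\s*", "", lines[keys == "class"][1L])
  kv <- kv[keys != "class"]
  vals <- lapply(kv, function(p) {
    if (length(p) < 2L) return(NA_real_)
    as.numeric(strsplit(p[[2L]], ",\\s*")[[1L]])
  })
  names(vals) <- keys[keys != "class"]
  switch(cls,
    hif_params = hif_params(S = vals$S, gamma = vals$gamma, k = vals$k,
                            d = vals$d, h = vals$h),
    hif_params4 = {
      p <- hif_params4(S = vals$S, gamma = vals$gamma,
                       S1 = vals$S_basal[1L], S2 = vals$S_basal[2L],
                       S3 = vals$S_basal[3L],
                       k2 = vals$k[2L], k3 = vals$k[3L],
                       half_life_h = vals$half_life_h, h = vals$h,
                       oxygen_ratio = vals$oxygen_ratio)
      p
    },
    p53_params = do.call(p53_params, vals),
    stop("unknown parameter class in file: ", cls))
}
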