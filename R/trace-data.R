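#' Per-position four-channel Sanger trace data
#'
#' A `trace_data` object is a data frame with one row per trace position and
#' columns `pos` (1-based, contiguous), `A`, `C`, `G`, `T` (non-negative
#' channel intensities) and `called_base` (the argmax channel, or `"N"` on
#' ties or an all-zero position).  It captures the quantitative content of a
#' chromatogram after base calling; phred qualities and reverse-strand
#' handling are out of scope.
#'
#' @param channels numeric matrix or data frame with columns `A`, `C`, `G`,
#'   `T`; one row per position, intensities >= 0.
#' @param pos optional integer vector of 1-based positions; defaults to
#'   `seq_len(nrow(channels))`.  Must be contiguous and strictly increasing.
#' @return A `trace_data` data frame; `called_base` is always recomputed from
#'   the intensities so the argmax invariant holds by construction.
#' @examples
#' tr <- trace_data(cbind(A = c(1, 0, 0), C = c(0, 1, 0),
#'                        G = c(0, 0, 1), T = c(0, 0, 0)))
#' tr$called_base  # "A" "C" "G"
#' @export
trace_data <- function(channels, pos = NULL) {
  channels <- as.data.frame(channels)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(channels)))
    stop("channel columns A, C, G, T are required", call. = FALSE)
  m <- as.matrix(channels[, need])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("channel intensities must not be NA", call. = FALSE)
  if (any(m < 0)) stop("channel intensities must be >= 0", call. = FALSE)
  n <- nrow(m)
  if (is.null(pos)) pos <- seq_len(n)
  pos <- as.integer(pos)
  if (n > 0 && (pos[1] < 1 || (n > 1 && any(diff(pos) != 1L))))
    stop("positions must be 1-based, contiguous and strictly increasing",
         call. = FALSE)
  out <- data.frame(pos = pos, A = m[, "A"], C = m[, "C"], G = m[, "G"],
                    T = m[, "T"], called_base = call_bases(m),
                    stringsAsFactors = FALSE)
  class(out) <- c("trace_data", "data.frame")
  out
}

#' @param x object to test or validate.
#' @rdname trace_data
#' @export
is_trace_data <- function(x) inherits(x, "trace_data")

# argmax base call; ties and all-zero positions give N
call_bases <- function(m) {
  if (nrow(m) == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  apply(m, 1, function(row) {
    mx <- max(row)
    if (mx <= 0) return("N")
    hit <- which(row == mx)
    if (length(hit) > 1) "N" else bases[hit]
  })
}

# 4 x n intensity matrix accessor (positions as columns)
trace_matrix <- function(trace) {
  t(as.matrix(as.data.frame(trace)[, c("A", "C", "G", "T")]))
}

#' Read and write trace tables
#'
#' The on-disk dialect is a UTF-8, LF-terminated TSV with header
#' `pos\tA\tC\tG\tT\tcalled_base`, one row per position and intensities as
#' decimal floats.  `read_trace_table()` enforces every `trace_data`
#' invariant and reports the offending line on failure;
#' `write_trace_table()` emits a byte-deterministic file that re-parses to an
#' equal object.
#'
#' @param path file path.
#' @return `read_trace_table()` returns a [trace_data] object;
#'   `write_trace_table()` returns `path` invisibly.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("trace table not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  want <- paste(c("pos", "A", "C", "G", "T", "called_base"), collapse = "\t")
  if (!identical(hdr, want))
    stop("malformed trace-table header at line 1 of ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses =
                            c("integer", rep("numeric", 4), "character"),
                          check.names = FALSE)
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  bad <- which(!stats::complete.cases(m) | apply(m, 1, function(r) any(r < 0)))
  if (length(bad))
    stop("negative or missing intensity at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  if (nrow(df) > 1) {
    jump <- which(diff(df$pos) != 1L)
    if (length(jump))
      stop("non-contiguous positions at line ", jump[1] + 2L, " of ", path,
           call. = FALSE)
  }
  tr <- trace_data(df[, c("A", "C", "G", "T")], pos = df$pos)
  mism <- which(df$called_base != tr$called_base)
  if (length(mism))
    stop("called_base disagrees with channel argmax at line ", mism[1] + 1L,
         " of ", path, call. = FALSE)
  tr
}

#' @param trace a [trace_data] object.
#' @rdname read_trace_table
#' @export
write_trace_table <- function(trace, path) {
  stopifnot(is_trace_data(trace))
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(c("pos", "A", "C", "G", "T", "called_base"),
                   collapse = "\t"),
             sprintf("%d\t%s\t%s\t%s\t%s\t%s", trace$pos,
                     format(trace$A, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     format(trace$C, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     format(trace$G, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     format(trace$T, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     trace$called_base))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
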