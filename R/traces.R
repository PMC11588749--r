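#' Write voltage traces to disk
#'
#' Two formats: `"text"` (tab-delimited; one header line `time` + node
#' labels, one row per sample, values printed with full round-trippable
#' precision) and `"binary"` (an R serialization of the whole record, which
#' round-trips bit-exactly and is the default for large runs).
#'
#' @param traces An `"hh_traces"` object.
#' @param path Output file path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(traces, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("time", traces$labels), collapse = "\t"), con)
    m <- cbind(traces$time, traces$V)
    txt <- apply(m, 1L, function(r)
      paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = "\t"))
    writeLines(txt, con)
    meta_path <- paste0(path, ".meta.json")
    jsonlite::write_json(traces$meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read voltage traces written by [write_traces()]
#'
#' @param path File path. Binary files are detected by content; text files
#'   by their header line.
#' @return An `"hh_traces"` object.
#' @export
read_traces <- function(path) {
  is_rds <- tryCatch({ x <- readRDS(path); inherits(x, "hh_traces") },
                     error = function(e) FALSE)
  if (is_rds) return(readRDS(path))
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (hdr[1L] != "time") stop("not a trace file (header must start with 'time'): ", path)
  body <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  if (!is.null(body) && ncol(body) != length(hdr))
    stop("header/payload column mismatch in ", path)
  meta <- list()
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  structure(list(time = body[, 1L], V = body[, -1L, drop = FALSE],
                 labels = hdr[-1L], meta = meta),
            class = "hh_traces")
}

#' Count spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold` with a refractory lockout:
#' after a crossing, further crossings within `refractory` ms are ignored.
#' This detector is for reporting only; the solver never uses it.
#'
#' @param v Voltage samples, mV.
#' @param dt Sample interval, ms.
#' @param threshold Crossing threshold, mV (default 0).
#' @param refractory Lockout, ms (default 1).
#' @return Integer spike count.
#' @export
count_spikes <- function(v, dt, threshold = 0, refractory = 1) {
  up <- which(v[-1L] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(0L)
  lock <- max(1L, as.integer(round(refractory / dt)))
  count <- 1L
  last <- up[1L]
  for (i in up[-1L]) {
    if (i - last >= lock) { count <- count + 1L; last <- i }
  }
  count
}

#' Compare two trace records
#'
#' Per-node RMS voltage difference and spike counts (threshold 0 mV, 1 ms
#' lockout). Symmetric in its arguments; all differences are zero iff the
#' payloads are identical.
#'
#' @param a,b `"hh_traces"` objects with matching shapes.
#' @return A data.frame with columns `label`, `rms_mV`, `max_abs_mV`,
#'   `spikes_a`, `spikes_b`.
#' @export
compare_traces <- function(a, b) {
  if (!identical(dim(a$V), dim(b$V)))
    stop("trace shapes differ: ", paste(dim(a$V), collapse = "x"), " vs ",
         paste(dim(b$V), collapse = "x"))
  dt_a <- if (length(a$time) > 1L) a$time[2L] - a$time[1L] else 1
  d <- a$V - b$V
  data.frame(
    label = a$labels,
    rms_mV = sqrt(colMeans(d^2)),
    max_abs_mV = apply(abs(d), 2L, max),
    spikes_a = apply(a$V, 2L, count_spikes, dt = dt_a),
    spikes_b = apply(b$V, 2L, count_spikes, dt = dt_a),
    row.names = NULL)
}
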