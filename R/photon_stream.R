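#' Construct a photon stream
#'
#' A photon stream is the primary data container: one row per detected photon,
#' with an integer arrival time in sync-clock ticks and a stream index giving
#' the excitation-period/detection-channel class under pulsed interleaved
#' excitation (PIE/ALEX). The three streams are `DexDem` (donor excitation,
#' donor emission, code 0), `DexAem` (donor excitation, acceptor emission,
#' code 1) and `AexAem` (acceptor excitation, acceptor emission, code 2).
#'
#' Timestamps are stored as doubles holding exact integers (tick counts exceed
#' 2^31 within minutes at a 40 MHz sync clock). The default clock period of
#' 25 ns corresponds to that 40 MHz laser pulse rate.
#'
#' @param timestamps Non-negative, non-decreasing photon arrival times in
#'   clock ticks.
#' @param stream Integer stream codes in `{0, 1, 2}` (see above), one per
#'   photon. Code 3 (acceptor excitation, donor emission) is accepted and
#'   dropped with a message; it carries no FRET information.
#' @param clock_period Seconds per clock tick. Default `25e-9` (40 MHz).
#' @param duration_s Acquisition length in seconds. Defaults to the time of
#'   the last photon; must not be shorter than it.
#' @param meta Named list of free-form condition labels (buffer, KCl, ...).
#'
#' @return A tibble of class `photon_stream` with columns `timestamp` and
#'   `stream`, and attributes `clock_period`, `duration_s`, `meta`.
#' @examples
#' ps <- photon_stream(c(0, 40, 80), c(0L, 1L, 2L))
#' ps
#' @export
photon_stream <- function(timestamps, stream,
                          clock_period = 25e-9,
                          duration_s = NULL,
                          meta = list()) {
  timestamps <- as.double(timestamps)
  stream <- as.integer(stream)
  if (length(timestamps) != length(stream)) {
    stop("`timestamps` and `stream` must have the same length", call. = FALSE)
  }
  if (length(timestamps) && any(timestamps < 0)) {
    stop("timestamps must be non-negative", call. = FALSE)
  }
  if (is.unsorted(timestamps)) {
    bad <- which(diff(timestamps) < 0)[1] + 1L
    stop("timestamps must be non-decreasing (first violation at photon ",
         bad, ")", call. = FALSE)
  }
  if (any(stream == STREAM_AEXDEM)) {
    keep <- stream != STREAM_AEXDEM
    message("dropping ", sum(!keep), " AexDem photons (stream code 3)")
    timestamps <- timestamps[keep]
    stream <- stream[keep]
  }
  if (length(stream) && !all(stream %in% STREAM_CODES)) {
    stop("unknown stream code(s): ",
         paste(unique(stream[!stream %in% STREAM_CODES]), collapse = ", "),
         call. = FALSE)
  }
  t_last <- if (length(timestamps)) timestamps[length(timestamps)] * clock_period else 0
  if (is.null(duration_s)) duration_s <- t_last
  if (duration_s < t_last) {
    stop("duration_s (", duration_s, ") is shorter than the last photon time (",
         t_last, ")", call. = FALSE)
  }
  out <- tibble::tibble(timestamp = timestamps, stream = stream)
  attr(out, "clock_period") <- clock_period
  attr(out, "duration_s") <- duration_s
  attr(out, "meta") <- meta
  class(out) <- c("photon_stream", class(out))
  out
}

#' @export
print.photon_stream <- function(x, ...) {
  cat("<photon_stream> ", nrow(x), " photons, ",
      format(attr(x, "duration_s"), digits = 4), " s @ ",
      format(attr(x, "clock_period") * 1e9, digits = 4), " ns/tick\n", sep = "")
  tab <- table(factor(x$stream, levels = STREAM_CODES, labels = names(STREAM_CODES)))
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n", sep = "")
  m <- attr(x, "meta")
  if (length(m)) {
    cat("  meta: ", paste(names(m), unlist(m), sep = "=", collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' @rdname photon_stream
#' @param x Object to query.
#' @export
clock_period <- function(x) attr(x, "clock_period")

#' @rdname photon_stream
#' @export
stream_duration <- function(x) attr(x, "duration_s")

#' @rdname photon_stream
#' @export
stream_meta <- function(x) attr(x, "meta")

#' Read a photon stream from the plain-text photon table
#'
#' The on-disk dialect is a whitespace-separated two-column table
#' (`timestamp_tick stream_code`), preceded by a `#`-prefixed header carrying
#' `clock_period`, `duration_s` and `meta.<key>` entries so that
#' [write_photons()] / `read_photons()` round-trips are lossless.
#'
#' @param path Path to the file.
#' @return A [photon_stream()].
#' @export
read_photons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  body <- body[nzchar(trimws(body))]

  clock_period <- 25e-9
  duration_s <- NULL
  meta <- list()
  for (h in header) {
    h <- sub("^#\\s*", "", h)
    if (!grepl(":", h, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", h))
    val <- trimws(sub("^[^:]*:", "", h))
    if (key == "clock_period") {
      clock_period <- as.double(val)
    } else if (key == "duration_s") {
      duration_s <- as.double(val)
    } else if (startsWith(key, "meta.")) {
      mkey <- sub("^meta\\.", "", key)
      num <- suppressWarnings(as.double(val))
      meta[[mkey]] <- if (!is.na(num)) num else val
    }
  }

  if (length(body)) {
    con <- textConnection(body)
    on.exit(close(con))
    dat <- scan(con, what = list(double(), integer()), quiet = TRUE)
    ts <- dat[[1]]
    st <- dat[[2]]
  } else {
    ts <- double()
    st <- integer()
  }
  photon_stream(ts, st, clock_period = clock_period,
                duration_s = duration_s, meta = meta)
}

#' Write a photon stream to the plain-text photon table
#'
#' @param stream A [photon_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_photons <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  header <- c(
    "# fretburst photon stream v1",
    paste0("# clock_period: ", format(clock_period(stream), digits = 17)),
    paste0("# duration_s: ", format(stream_duration(stream), digits = 17))
  )
  meta <- stream_meta(stream)
  for (k in names(meta)) {
    header <- c(header, paste0("# meta.", k, ": ",
                               format(meta[[k]], digits = 17)))
  }
  body <- if (nrow(stream)) {
    paste(format(stream$timestamp, scientific = FALSE, trim = TRUE),
          stream$stream)
  } else {
    character()
  }
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}
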