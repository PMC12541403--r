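# The trace container (time/potential/current series for CV and CA
# experiments) and its CSV dialect.

#' Construct an electrochemical trace
#'
#' A trace is a data frame with columns `time` (s), `potential` (V vs SHE)
#' and `current` (A m^-2, or dimensionless once normalized), tagged with
#' the experiment kind (CV or CA) and metadata.
#'
#' @param time time in s, strictly increasing, length >= 2.
#' @param potential electrode potential in volts vs SHE.
#' @param current current (A m^-2 unless `normalized`).
#' @param kind `"CV"` or `"CA"`.
#' @param pH,temperature,scan_rate,gas_feed metadata; `scan_rate` in
#'   V s^-1 (CV only).
#' @param normalized logical: currents divided by the maximal positive
#'   current.
#' @return a data frame of class `ec_trace`.
#' @export
ec_trace <- function(time, potential, current, kind = c("CV", "CA"),
                     pH = NA_real_, temperature = 298.15,
                     scan_rate = NA_real_, gas_feed = "",
                     normalized = FALSE) {
  kind <- match.arg(kind)
  n <- length(time)
  if (n < 2 || length(potential) != n || length(current) != n)
    stop("time, potential and current must have equal length >= 2",
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  tr <- data.frame(time = time, potential = potential, current = current)
  attr(tr, "kind") <- kind
  attr(tr, "pH") <- pH
  attr(tr, "temperature") <- temperature
  attr(tr, "scan_rate") <- scan_rate
  attr(tr, "gas_feed") <- gas_feed
  attr(tr, "normalized") <- isTRUE(normalized)
  class(tr) <- c("ec_trace", "data.frame")
  tr
}

.trace_meta <- function(trace) {
  list(kind = attr(trace, "kind"), pH = attr(trace, "pH"),
       temperature = attr(trace, "temperature"),
       scan_rate = attr(trace, "scan_rate"),
       gas_feed = attr(trace, "gas_feed"),
       normalized = attr(trace, "normalized"))
}

#' @export
print.ec_trace <- function(x, ...) {
  m <- .trace_meta(x)
  cat(sprintf("%s trace: %d points, t = [%g, %g] s, E = [%.3f, %.3f] V vs SHE\n",
              m$kind, nrow(x), min(x$time), max(x$time),
              min(x$potential), max(x$potential)))
  if (!is.na(m$pH)) cat(sprintf("  pH %.1f", m$pH))
  if (!is.na(m$scan_rate)) cat(sprintf(", scan rate %g V/s", m$scan_rate))
  if (isTRUE(m$normalized)) cat(", normalized")
  cat("\n")
  invisible(x)
}

#' Write a trace to CSV
#'
#' Columns `time_s`, `potential_V_SHE`, `current`; metadata in
#' `#`-prefixed header lines.
#'
#' @param trace an [ec_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  m <- .trace_meta(trace)
  unit <- if (isTRUE(m$normalized)) "normalized" else "A_per_m2"
  hdr <- c(sprintf("# kind: %s", m$kind),
           sprintf("# pH: %s", m$pH),
           sprintf("# temperature_K: %s", m$temperature),
           sprintf("# scan_rate_V_per_s: %s", m$scan_rate),
           sprintf("# gas_feed: %s", m$gas_feed),
           sprintf("# current_unit: %s", unit))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,potential_V_SHE,current", con)
  writeLines(sprintf("%.10g,%.10g,%.10g",
                     trace$time, trace$potential, trace$current), con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV file path.
#' @return an [ec_trace].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  num <- function(x) suppressWarnings(as.numeric(x))
  ec_trace(dat$time_s, dat$potential_V_SHE, dat$current,
           kind = if (identical(meta$kind, "CA")) "CA" else "CV",
           pH = num(meta$pH), temperature = num(meta$temperature_K),
           scan_rate = num(meta$scan_rate_V_per_s),
           gas_feed = if (is.null(meta$gas_feed)) "" else meta$gas_feed,
           normalized = identical(meta$current_unit, "normalized"))
}
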