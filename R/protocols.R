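#' Gas challenge protocols
#'
#' A gas challenge protocol is an ordered list of timed segments, each holding
#' the gas exchange chamber at fixed oxygen and carbon dioxide fractions (the
#' balance being nitrogen). The nine built-in protocols mirror the intravital
#' experiment design: four O2 challenges run at a constant 5% CO2, four CO2
#' challenges at a constant 7% O2, and one combined challenge that lowers O2
#' first and raises CO2 one minute later. Single-gas challenges last 180 s
#' (60 s baseline + 120 s step); the combined challenge lasts 240 s
#' (60 s baseline + 60 s low O2 + 120 s high CO2).
#'
#' @param name One of the nine built-in protocol names (see Details), or an
#'   arbitrary identifier when `segments` is supplied.
#' @param segments Optional data frame with columns `duration` (s), `o2` (%),
#'   `co2` (%) defining a custom protocol.
#'
#' @details Built-in names: `"O2_7to12"`, `"O2_12to7"`, `"O2_7to2"`,
#'   `"O2_2to7"`, `"CO2_5to0"`, `"CO2_0to5"`, `"CO2_5to10"`, `"CO2_10to5"`,
#'   `"combined"`.
#'
#' @return An object of class `gas_protocol`: a list with elements `name` and
#'   `segments` (a data frame with columns `duration`, `o2`, `co2`).
#' @examples
#' make_protocol("O2_7to2")
#' make_protocol("custom", segments = data.frame(duration = c(60, 120),
#'                                               o2 = c(7, 7), co2 = c(5, 5)))
#' @export
make_protocol <- function(name, segments = NULL) {
  if (!is.null(segments)) {
    return(new_gas_protocol(name, segments))
  }
  builtin <- builtin_protocols()
  if (!name %in% names(builtin)) {
    stop("unknown protocol '", name, "'; built-in protocols are: ",
         paste(names(builtin), collapse = ", "),
         " (or supply `segments` for a custom protocol)", call. = FALSE)
  }
  seg <- builtin[[name]]
  new_gas_protocol(name, seg)
}

builtin_protocols <- function() {
  o2 <- function(from, to) data.frame(duration = c(60, 120), o2 = c(from, to), co2 = c(5, 5))
  co2 <- function(from, to) data.frame(duration = c(60, 120), o2 = c(7, 7), co2 = c(from, to))
  list(
    O2_7to12  = o2(7, 12),
    O2_12to7  = o2(12, 7),
    O2_7to2   = o2(7, 2),
    O2_2to7   = o2(2, 7),
    CO2_5to0  = co2(5, 0),
    CO2_0to5  = co2(0, 5),
    CO2_5to10 = co2(5, 10),
    CO2_10to5 = co2(10, 5),
    combined  = data.frame(duration = c(60, 60, 120),
                           o2 = c(7, 2, 2), co2 = c(5, 5, 10))
  )
}

new_gas_protocol <- function(name, segments) {
  segments <- as.data.frame(segments)
  required <- c("duration", "o2", "co2")
  if (!all(required %in% names(segments))) {
    stop("protocol segments need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  segments <- segments[, required]
  segments[] <- lapply(segments, as.numeric)
  if (nrow(segments) < 1) stop("protocol needs at least one segment", call. = FALSE)
  if (any(!is.finite(as.matrix(segments)))) {
    stop("protocol segments contain non-finite values", call. = FALSE)
  }
  if (any(segments$duration <= 0)) {
    stop("every segment duration must be > 0 s", call. = FALSE)
  }
  if (any(segments$o2 < 0 | segments$o2 > 100) ||
      any(segments$co2 < 0 | segments$co2 > 100) ||
      any(segments$o2 + segments$co2 > 100)) {
    stop("gas fractions must satisfy 0 <= o2, co2 and o2 + co2 <= 100",
         call. = FALSE)
  }
  structure(list(name = name, segments = segments), class = "gas_protocol")
}

#' @export
print.gas_protocol <- function(x, ...) {
  cat("<gas_protocol> ", x$name, " (", protocol_duration(x), " s)\n", sep = "")
  seg <- x$segments
  t0 <- cumsum(c(0, seg$duration[-nrow(seg)]))
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  t = %3d-%3d s: %4.1f%% O2, %4.1f%% CO2 (balance N2)\n",
                t0[i], t0[i] + seg$duration[i], seg$o2[i], seg$co2[i]))
  }
  invisible(x)
}

#' Total protocol duration in seconds
#' @param protocol A `gas_protocol`.
#' @return Numeric scalar, seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "gas_protocol"))
  sum(protocol$segments$duration)
}

#' Times of gas composition changes within a protocol
#'
#' @param protocol A `gas_protocol`.
#' @return Numeric vector of step-change times (s from protocol start);
#'   empty for a single-segment protocol.
#' @export
protocol_step_times <- function(protocol) {
  stopifnot(inherits(protocol, "gas_protocol"))
  d <- protocol$segments$duration
  if (length(d) < 2) return(numeric(0))
  cumsum(d)[-length(d)]
}

#' Read / write gas challenge protocols
#'
#' Protocols serialize to YAML (`.yml`/`.yaml`) or JSON (`.json`), chosen by
#' file extension. A round trip reproduces the segment table exactly.
#'
#' @param protocol A `gas_protocol`.
#' @param path File path ending in `.yml`, `.yaml` or `.json`.
#' @return `write_protocol` returns `path` invisibly; `read_protocol` returns
#'   a `gas_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "gas_protocol"))
  obj <- list(name = protocol$name,
              segments = lapply(seq_len(nrow(protocol$segments)), function(i)
                as.list(protocol$segments[i, ])))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(obj, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported protocol file extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported protocol file extension: .", ext, call. = FALSE)
  }
  seg <- do.call(rbind, lapply(obj$segments, function(s)
    data.frame(duration = s$duration, o2 = s$o2, co2 = s$co2)))
  new_gas_protocol(obj$name, seg)
}
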