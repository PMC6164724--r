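#' Read and write dissipation traces, spectra, results and pair tables
#'
#' Plain-text CSV interchange for every pipeline stage. Traces use the
#' header `time_s,dissipation,frequency_hz` with reagent events embedded
#' as comment lines `# event,<label>,<time_s>` before the header; writers
#' format numbers with 15 significant digits so that write -> read ->
#' write is byte-identical.
#'
#' @param trace A [dissipation_trace()].
#' @param path File path.
#' @return `read_trace()` returns a [dissipation_trace()]; writers return
#'   `path` invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dissipation_trace"))
  ev <- sprintf("# event,%s,%s", trace$events$label, fmt_num(trace$events$time))
  freq <- if (is.null(trace$frequency)) rep("", length(trace$times))
          else fmt_num(trace$frequency)
  rows <- paste(fmt_num(trace$times), fmt_num(trace$dissipation), freq,
                sep = ",")
  writeLines(c(ev, "time_s,dissipation,frequency_hz", rows), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  ev_lines <- lines[is_comment]
  events <- data.frame(label = character(), time = numeric(),
                       stringsAsFactors = FALSE)
  for (k in seq_along(ev_lines)) {
    parts <- strsplit(sub("^#\\s*", "", ev_lines[k]), ",")[[1L]]
    tm <- suppressWarnings(as.numeric(parts[3L]))
    if (length(parts) != 3L || parts[1L] != "event" || is.na(tm)) {
      stop(sprintf("unparseable event line %d in %s",
                   which(is_comment)[k], path), call. = FALSE)
    }
    events <- rbind(events, data.frame(label = parts[2L], time = tm,
                                       stringsAsFactors = FALSE))
  }
  body <- lines[!is_comment]
  if (length(body) < 2L || body[1L] != "time_s,dissipation,frequency_hz") {
    stop(sprintf("malformed header at line %d in %s: expected 'time_s,dissipation,frequency_hz'",
                 which(!is_comment)[1L], path), call. = FALSE)
  }
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    stop(sprintf("non-monotone time at data row %d in %s", bad, path),
         call. = FALSE)
  }
  freq <- if (all(is.na(df$frequency_hz))) NULL else df$frequency_hz
  dissipation_trace(times = df$time_s, dissipation = df$dissipation,
                    frequency = freq, events = events)
}

#' @rdname trace_io
#' @param spectrum A [magnitude_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  rows <- paste(fmt_num(spectrum$freq_hz), fmt_num(spectrum$magnitude_db),
                sep = ",")
  writeLines(c("freq_hz,magnitude_db", rows), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "freq_hz,magnitude_db") {
    stop(sprintf("malformed header at line 1 in %s: expected 'freq_hz,magnitude_db'",
                 path), call. = FALSE)
  }
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  magnitude_spectrum(df$freq_hz, df$magnitude_db)
}

#' @rdname trace_io
#' @param fit A `"resonance_fit"`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "resonance_fit"))
  writeLines(c("fs_hz,bw_hz,dissipation,peak_db,rms_residual",
               paste(fmt_num(fit$fs), fmt_num(fit$bw),
                     fmt_num(fit$dissipation), fmt_num(fit$peak_db),
                     fmt_num(fit$rms_residual), sep = ",")), path)
  invisible(path)
}

#' @rdname trace_io
#' @param result A `"clot_result"` from [detect_endpoint()].
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "clot_result"))
  flags <- paste(result$qc_flags, collapse = ";")
  writeLines(c("start_time_s,end_time_s,clot_time_s,peak_slope,flags",
               paste(fmt_num(result$start_time), fmt_num(result$end_time),
                     fmt_num(result$clot_time), fmt_num(result$peak_slope),
                     flags, sep = ",")), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) != 2L ||
      lines[1L] != "start_time_s,end_time_s,clot_time_s,peak_slope,flags") {
    stop(sprintf("malformed clot-result file: %s", path), call. = FALSE)
  }
  parts <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  flags <- if (length(parts) >= 5L && nzchar(parts[5L])) {
    strsplit(parts[5L], ";", fixed = TRUE)[[1L]]
  } else {
    character()
  }
  structure(list(start_time = as.numeric(parts[1L]),
                 end_time = as.numeric(parts[2L]),
                 clot_time = as.numeric(parts[3L]),
                 peak_slope = as.numeric(parts[4L]),
                 blanking_used = NA_real_,
                 qc_flags = flags,
                 start_convention = "start-event-addition"),
            class = "clot_result")
}

#' @rdname trace_io
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1L] != "device_time_s,reference_time_s") {
    stop(sprintf("malformed header at line 1 in %s: expected 'device_time_s,reference_time_s'",
                 path), call. = FALSE)
  }
  if (length(lines) < 2L) {
    stop(sprintf("no clot-time pairs in %s", path), call. = FALSE)
  }
  utils::read.csv(text = lines, stringsAsFactors = FALSE)
}

#' @rdname trace_io
#' @param pairs Data frame with columns `device_time_s`, `reference_time_s`.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(c("device_time_s", "reference_time_s") %in% names(pairs)))
  rows <- paste(fmt_num(pairs$device_time_s), fmt_num(pairs$reference_time_s),
                sep = ",")
  writeLines(c("device_time_s,reference_time_s", rows), path)
  invisible(path)
}

#' Read and write trace scenarios as flat key/value files
#'
#' One scenario per file, `key = value` per line; events are encoded as
#' `events = label:time;label:time`. Unknown keys are an error, so typos
#' fail loudly.
#'
#' @param scenario A [trace_scenario()].
#' @param path File path.
#' @return `read_scenario()` returns a [trace_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "trace_scenario"))
  ev <- paste(sprintf("%s:%s", names(scenario$event_times),
                      fmt_num(scenario$event_times)), collapse = ";")
  scalar <- setdiff(names(scenario), "event_times")
  lines <- c(vapply(scalar, function(k) {
    sprintf("%s = %s", k, fmt_num(scenario[[k]]))
  }, character(1L)), sprintf("events = %s", ev))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", lines))
  bad <- which(vapply(kv, length, 0L) != 3L)
  if (length(bad)) {
    stop(sprintf("unparseable scenario line %d in %s", bad[1L], path),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  args <- list()
  for (j in seq_along(keys)) {
    if (keys[j] == "events") {
      items <- strsplit(vals[j], ";", fixed = TRUE)[[1L]]
      pieces <- strsplit(items, ":", fixed = TRUE)
      ev <- vapply(pieces, function(p) as.numeric(p[2L]), numeric(1L))
      names(ev) <- vapply(pieces, `[`, character(1L), 1L)
      args$event_times <- ev
    } else if (keys[j] %in% names(formals(trace_scenario))) {
      args[[keys[j]]] <- as.numeric(vals[j])
    } else {
      stop(sprintf("unknown scenario key '%s' in %s", keys[j], path),
           call. = FALSE)
    }
  }
  do.call(trace_scenario, args)
}
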