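#' Write a recording to CSV
#'
#' Serializes a `pegs_recording` to the package's plain-text dialect: `#`
#' header lines carrying `sample_rate`, `seed` and the protocol description,
#' then a `time_s` column and one column per channel (siemens), written with
#' 17 significant digits so a write/read round trip is lossless to better
#' than 1e-12 relative.  Channel metadata (id, functionalization, molarity)
#' goes to a sidecar `channels.csv` next to the recording.
#'
#' @param recording A `pegs_recording`.
#' @param path Output CSV path.
#' @param channels_path Sidecar metadata path (default `channels.csv` in the
#'   same directory).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            channels_path = file.path(dirname(path),
                                                      "channels.csv")) {
  stop_if_not(inherits(recording, "pegs_recording"),
              "recording must be a pegs_recording")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate: %.17g", recording$sample_rate),
    sprintf("# seed: %s", recording$meta$seed),
    sprintf("# protocol: %s", recording$meta$protocol)
  ), con)
  header <- paste(c("time_s", colnames(recording$traces)), collapse = ",")
  writeLines(header, con)
  m <- cbind(recording$time, recording$traces)
  rows <- apply(formatC(m, format = "g", digits = 17), 1, paste,
                collapse = ",")
  writeLines(rows, con)
  utils::write.csv(recording$channels, channels_path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the dialect written by [write_recording()], restoring the header
#' metadata and the channel table.  Malformed inputs fail with specific
#' errors: a missing time column, a non-uniform time grid or non-positive
#' conductances (reported with row numbers), and a missing sidecar
#' `channels.csv`.
#'
#' @param path Recording CSV path.
#' @param channels_path Sidecar metadata path (default `channels.csv` next
#'   to the recording).
#' @return A `pegs_recording`.
#' @export
read_recording <- function(path,
                           channels_path = file.path(dirname(path),
                                                     "channels.csv")) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path),
              class = "pegs_io_error")
  if (!file.exists(channels_path)) {
    pegs_error(sprintf("missing channel metadata file: %s", channels_path),
               "pegs_missing_metadata")
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(seed = NA_integer_, protocol = "")
  sample_rate <- NA_real_
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    if (key == "sample_rate") sample_rate <- as.numeric(val)
    if (key == "seed") meta$seed <- suppressWarnings(as.integer(val))
    if (key == "protocol") meta$protocol <- val
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  stop_if_not(length(body) >= 3, "recording has fewer than two data rows",
              class = "pegs_format_error")
  cols <- strsplit(body[1], ",")[[1]]
  if (cols[1] != "time_s") {
    pegs_error("first column must be time_s: missing time column",
               "pegs_format_error")
  }
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  time <- dat[[1]]
  dtv <- diff(time)
  bad <- which(dtv <= 0 | abs(dtv - dtv[1]) > 1e-9 * max(abs(dtv)))
  if (length(bad)) {
    pegs_error(sprintf("non-uniform time grid at data row(s) %s",
                       paste(utils::head(bad + 1, 5), collapse = ", ")),
               "pegs_format_error")
  }
  traces <- as.matrix(dat[-1])
  badv <- which(apply(traces <= 0 | !is.finite(traces), 1, any))
  if (length(badv)) {
    pegs_error(sprintf("non-positive conductance at data row(s) %s",
                       paste(utils::head(badv, 5), collapse = ", ")),
               "pegs_format_error")
  }
  channels <- utils::read.csv(channels_path, stringsAsFactors = FALSE)
  stop_if_not(all(c("id", "functionalization", "molarity") %in% names(channels)),
              "channels.csv must have id, functionalization, molarity",
              class = "pegs_format_error")
  keep <- channels$id %in% colnames(traces)
  channels <- channels[keep, , drop = FALSE]
  stop_if_not(nrow(channels) == ncol(traces),
              "channels.csv does not describe every trace column",
              class = "pegs_format_error")
  channels <- channels[match(colnames(traces), channels$id), , drop = FALSE]
  rownames(channels) <- NULL
  meta$noise <- !is.na(meta$seed)
  rec <- list(time = time, traces = traces, channels = channels,
              sample_rate = sample_rate, meta = meta, final_states = NULL)
  class(rec) <- "pegs_recording"
  rec
}

# Default configuration tree (every key has a default).
config_defaults <- function() {
  list(
    physics = unclass(physics_params()),
    noise = unclass(noise_params()),
    pipeline = list(window_points = 1000, hi = 0.90, lo = 0.20,
                    skip_after_peak_s = 30, baseline_s = 120),
    stats = list(alpha = 0.05, lod_multiplier = 3),
    seed = 1L
  )
}

merge_config <- function(defaults, override, path = character(0)) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      pegs_error(sprintf("unknown config key: %s", full), "pegs_config_error")
    }
    dv <- defaults[[key]]
    ov <- override[[key]]
    if (is.list(dv)) {
      if (!is.list(ov)) {
        pegs_error(sprintf("config key %s must be a mapping", full),
                   "pegs_config_error")
      }
      defaults[[key]] <- merge_config(dv, ov, c(path, key))
    } else {
      if (!is.numeric(ov) || length(ov) != 1) {
        pegs_error(sprintf("config key %s must be a single number", full),
                   "pegs_config_error")
      }
      defaults[[key]] <- ov
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file with optional `physics`, `noise`, `pipeline`, `stats`
#' and `seed` sections, merges it over the package defaults and validates
#' it.  Unknown keys and non-numeric values are rejected with an error
#' naming the offending key; an empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return An object of class `pegs_config`: a list with `physics` (a
#'   [physics_params()] object), `noise` (a [noise_params()] object),
#'   `pipeline`, `stats` and `seed`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    stop_if_not(file.exists(path), sprintf("no such config file: %s", path),
                class = "pegs_config_error")
    override <- tryCatch(yaml::read_yaml(path), error = function(e) {
      pegs_error(sprintf("cannot parse config %s: %s", path,
                         conditionMessage(e)), "pegs_config_error")
    })
    if (!is.null(override)) {
      if (!is.list(override)) {
        pegs_error("config must be a YAML mapping", "pegs_config_error")
      }
      cfg <- merge_config(cfg, override)
    }
  }
  cfg$physics <- do.call(physics_params, cfg$physics)
  cfg$noise <- do.call(noise_params, cfg$noise)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pegs_config"
  cfg
}
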