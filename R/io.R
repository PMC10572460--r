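# Shared readers/writers and run configuration.

# lightweight provenance hash (not cryptographic)
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  sprintf("%08x", sum(b * (seq_along(b) %% 251L + 1L)) %% 2147483647L)
}

#' Default analysis configuration
#'
#' One nested list carrying every module's tunable parameters, with
#' defaults mirroring the reference protocol's printed constants:
#' detection at 2 baseline SDs for >= 5 frames, >= 30-frame baseline
#' window, 23.1 s FT/ST cut-off from the 75th percentile, 100 ms
#' paired-pulse interval, 4000 ms spectral segments with 500 ms overlap at
#' time-bandwidth 5 with 9 tapers, and the 1-3 Hz ictal band. Unknown
#' keys are rejected.
#'
#' @param ... Named overrides, e.g. `calcium = list(k_sd = 2.5)`.
#' @param seed Integer seed driving every stochastic stage.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(..., seed = 1) {
  defaults <- list(
    calcium = list(k_sd = 2, min_frames = 5, min_quiet_frames = 30,
                   cutoff_s = 23.1, percentile = 75,
                   split_mode = "relative"),
    psc = list(threshold_sd = 3, min_interval_ms = 10, isi_ms = 100,
               decay_correction = TRUE),
    fepsp = list(blank_ms = 2, ps_criterion = 0.1,
                 slope_span = c(0.2, 0.8)),
    lfp = list(segment_ms = 4000, overlap_ms = 500, time_bandwidth = 5,
               n_tapers = 9, band_hz = c(1, 3),
               envelope_threshold_sd = 2, min_duration_s = 2),
    stats = list(alpha = 0.05),
    seed = seed)
  overrides <- list(...)
  merge_block <- function(base, over, path) {
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste0(path, bad, collapse = ", "))
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides))
    defaults[[nm]] <- if (nm == "seed") overrides[[nm]] else
      merge_block(defaults[[nm]], overrides[[nm]], paste0(nm, "$"))
  structure(defaults, class = "run_config")
}

#' Write a signal or metric table as CSV with a provenance header
#'
#' The header is a YAML comment block (`# key: value`) carrying at least
#' the configuration hash and seed, so outputs are traceable to the run
#' that made them. [read_signal_csv()] round-trips the values and the
#' metadata.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param meta Named list of scalar metadata.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
    writeLines(paste("#", hdr), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_signal_csv()]
#'
#' @param path File to read.
#' @return Data frame with attribute `meta` (parsed YAML header, or an
#'   empty list).
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- if (length(hdr))
    yaml::yaml.load(paste(sub("^# ?", "", lines[hdr]), collapse = "\n"))
  else list()
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Read a fluorescence trace table
#'
#' Accepts either a two-column file (frame/time, value) for one cell, or a
#' wide table (`frame, cell_1, ..., cell_n`).
#'
#' @param path Delimited text file (CSV, `#` comments allowed).
#' @param frame_period_s Seconds per frame.
#' @param background Scalar background fluorescence, AU.
#' @return List of [fluor_trace()] objects.
#' @export
read_traces_csv <- function(path, frame_period_s = 1, background = 0) {
  df <- read_signal_csv(path)
  cols <- names(df)[-1]
  lapply(seq_along(cols), function(i)
    fluor_trace(df[[cols[i]]], frame_period_s, cols[i], background))
}

#' Write per-event and per-cell calcium tables
#'
#' @param analyses List of `ca_analysis` objects from [analyze_trace()].
#' @param dir Output directory (created if needed).
#' @param meta Provenance metadata for the header.
#' @return Paths of the two files, invisibly.
#' @export
write_calcium_results <- function(analyses, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- do.call(rbind, lapply(analyses, function(a) {
    if (!nrow(a$events)) return(NULL)
    data.frame(cell_id = a$trace$cell_id,
               onset_s = a$events$onset_frame * a$trace$frame_period_s,
               duration_s = a$events$duration_s,
               peak_dff = a$events$peak_dff, label = a$events$label)
  }))
  if (is.null(ev))
    ev <- data.frame(cell_id = character(), onset_s = numeric(),
                     duration_s = numeric(), peak_dff = numeric(),
                     label = character())
  cells <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  p1 <- file.path(dir, "calcium_events.csv")
  p2 <- file.path(dir, "calcium_cells.csv")
  write_signal_csv(ev, p1, meta)
  write_signal_csv(cells, p2, meta)
  invisible(c(p1, p2))
}
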