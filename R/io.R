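#' Write a sensor stream to CSV or NDJSON
#'
#' CSV: a `#`-prefixed unit header line, then a header row
#' `t,hf,cf,ax,ay,az` and one row per sample. NDJSON: one JSON object per
#' sample with the same keys. When the stream carries ground truth, a sibling
#' file with suffix `.truth` is written (CSV with per-sample truth channels
#' and a `# onsets:` comment line listing the beat-onset sample indices).
#'
#' @param stream a `sensor_stream`.
#' @param path output path.
#' @param format `"csv"` or `"ndjson"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("csv", "ndjson")) {
  format <- match.arg(format)
  df <- data.frame(t = stream$t, hf = stream$hf, cf = stream$cf,
                   ax = stream$acc[, 1L], ay = stream$acc[, 2L],
                   az = stream$acc[, 3L])
  if (format == "csv") {
    con <- file(path, "w")
    writeLines(c(
      sprintf("# sensor_stream fs=%.10g Hz; t s, hf a.u., cf V, ax/ay/az m/s^2",
              stream$fs)), con)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA)
    }, "")
    writeLines(lines, path)
  }
  if (!is.null(stream$truth)) {
    tr <- stream$truth
    tdf <- data.frame(t = stream$t, heart_rate = tr$heart_rate,
                      metabolic_rate = tr$metabolic_rate,
                      core_temp = tr$core_temp, clean_pulse = tr$clean_pulse,
                      artifact = tr$artifact, baseline = tr$baseline,
                      intensity = tr$intensity, label = tr$label)
    con <- file(paste0(path, ".truth"), "w")
    writeLines(sprintf("# onsets: %s", paste(tr$onsets, collapse = " ")), con)
    if (!is.null(tr$params)) {
      writeLines(sprintf("# params: %s", write_artifact_params(tr$params)), con)
    }
    utils::write.table(format(tdf, digits = 17, trim = TRUE, scientific = FALSE),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read a sensor stream from CSV or NDJSON
#'
#' Validates that the time grid is uniform at the declared sampling rate (no
#' gaps, no duplicate timestamps); on violation the error names the first
#' offending sample index. A `.truth` sibling file, when present, populates
#' the ground-truth side-channels.
#'
#' @param path file path.
#' @param format `"csv"` or `"ndjson"`; default inferred from the extension.
#' @param fs expected sampling rate in Hz; inferred from the median time step
#'   when `NULL`.
#' @return A `sensor_stream`.
#' @export
read_stream <- function(path, format = NULL, fs = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.ndjson$|\\.jsonl$", path)) "ndjson" else "csv"
  }
  format <- match.arg(format, c("csv", "ndjson"))
  if (format == "csv") {
    df <- utils::read.csv(path, comment.char = "#")
  } else {
    df <- do.call(rbind, lapply(readLines(path), function(l) {
      as.data.frame(jsonlite::fromJSON(l))
    }))
  }
  required <- c("t", "hf", "cf", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("stream file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dt <- diff(df$t)
  if (is.null(fs)) fs <- round(1 / stats::median(dt), 6) # snap parsing jitter
  bad <- which(abs(dt - 1 / fs) > 1e-6)
  if (length(bad)) {
    stop(sprintf("non-uniform time grid: first gap/duplicate at sample index %d",
                 bad[1L] + 1L))
  }
  stream <- structure(list(
    t = df$t, hf = df$hf, cf = df$cf,
    acc = cbind(ax = df$ax, ay = df$ay, az = df$az),
    fs = fs, truth = NULL), class = "sensor_stream")
  truth_path <- paste0(path, ".truth")
  if (file.exists(truth_path)) {
    header <- readLines(truth_path, n = 2L)
    onsets <- integer(0)
    params <- NULL
    for (h in header[startsWith(header, "#")]) {
      if (grepl("^# onsets:", h)) {
        onsets <- as.integer(strsplit(sub("^# onsets: *", "", h), " ")[[1L]])
      } else if (grepl("^# params:", h)) {
        pj <- jsonlite::fromJSON(sub("^# params: *", "", h))
        params <- artifact_params(pj$K, pj$zeta, pj$omega_n, pj$fs)
      }
    }
    tdf <- utils::read.csv(truth_path, comment.char = "#")
    stream$truth <- list(heart_rate = tdf$heart_rate,
                         metabolic_rate = tdf$metabolic_rate,
                         core_temp = tdf$core_temp,
                         clean_pulse = tdf$clean_pulse,
                         artifact = tdf$artifact, baseline = tdf$baseline,
                         intensity = tdf$intensity, label = tdf$label,
                         onsets = onsets, params = params)
  }
  stream
}

#' Read a run configuration file
#'
#' Flat key-value configuration in YAML (or JSON). Unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param path configuration file path.
#' @return A named list of configuration values merged over the defaults of
#'   [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}

#' Default run configuration
#'
#' @return Named list: sampling rate, pulse band, normalized beat length,
#'   Bayesian-optimization settings (8 initial points, 40 iterations), STFT
#'   settings (10/2/1 s), training settings and output paths.
#' @export
default_run_config <- function() {
  list(
    sampling_rate = 100,
    band = c(0.5, 5),
    beat_n = 100L,
    bo_inits = 8L,
    bo_max_iters = 40L,
    bo_ei_tol = 1e-9,
    seed = 1L,
    stft = c(window_s = 10, stft_window_s = 2, step_s = 1),
    train_lr = 2e-3,
    train_epochs = 60L,
    simulate = TRUE,
    calibration_duration = 120,
    protocol_segment_duration = 120,
    true_K = 0.25, true_zeta = 0.7, true_f_n = 3,
    stream_path = NULL,
    calibration_path = NULL,
    model_path = NULL,
    out_dir = "thermopulse_out"
  )
}

# Stable hash of a configuration (MD5 of its canonical JSON).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
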