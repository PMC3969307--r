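# I/O: event files (delimited text and Praat TextGrid tiers), tidy-table
# writers with reproducible numeric formatting, run configuration and the
# pipeline driver.

# fixed 12-significant-digit formatting for byte-stable output tables
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write a tidy table as delimited text
#'
#' Numeric columns are formatted to 12 significant digits so repeated runs
#' produce byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_table_txt <- function(x, path, sep = "\t") {
  y <- as.data.frame(x)
  for (j in seq_along(y)) if (is.numeric(y[[j]])) y[[j]] <- fmt_num(y[[j]])
  utils::write.table(y, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read event times from a file
#'
#' Two dialects are supported: delimited text with a time column (seconds)
#' and optional label columns, and Praat TextGrid tiers (point tiers give
#' point times; interval tiers give interval start times, the onset
#' convention).
#'
#' @param path File path.
#' @param dialect `"csv"` (any `sep`-delimited text) or
#'   `"praat_point_tier"`.
#' @param kind Event kind stamped on the result.
#' @param time_col Name of the time column for the delimited dialect.
#' @param sep Separator for the delimited dialect (`""` sniffs comma/tab).
#' @param tier For TextGrids: tier name or index (default: first tier).
#' @param max_bad_frac Fail if more than this fraction of rows is
#'   malformed.
#' @return An [event_series()]. Unsorted input is sorted with a warning;
#'   duplicate times are dropped with a message.
#' @export
read_events <- function(path, dialect = c("csv", "praat_point_tier"),
                        kind = "vowel_onset", time_col = "time_s", sep = "",
                        tier = NULL, max_bad_frac = 0.05) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- list(participant = NA_character_, group = NA_character_,
               sentence = NA_character_, metre = NA_character_)
  if (dialect == "praat_point_tier") {
    times <- parse_textgrid_times(path, tier)
  } else {
    if (sep == "") {
      first <- readLines(path, n = 1)
      sep <- if (grepl("\t", first)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!time_col %in% names(df)) {
      stop("no '", time_col, "' column in ", path, call. = FALSE)
    }
    times <- suppressWarnings(as.numeric(df[[time_col]]))
    bad <- !is.finite(times)
    if (mean(bad) > max_bad_frac) {
      stop(sum(bad), " malformed rows (> ", 100 * max_bad_frac, "%) in ",
           path, call. = FALSE)
    }
    if (any(bad)) message("dropping ", sum(bad), " malformed row(s)")
    for (cn in names(meta)) {
      if (cn %in% names(df)) meta[[cn]] <- as.character(df[[cn]][!bad][1])
    }
    times <- times[!bad]
  }
  if (is.unsorted(times)) {
    warning("event times were unsorted; sorting")
    times <- sort(times)
  }
  if (anyDuplicated(times)) {
    message("dropping ", sum(duplicated(times)), " duplicate timestamp(s)")
    times <- unique(times)
  }
  event_series(times, kind, participant = meta$participant,
               group = meta$group, sentence = meta$sentence,
               metre = meta$metre)
}

# Praat TextGrid parser (long text format): returns point times for point
# tiers, interval xmin for non-empty intervals of interval tiers.
parse_textgrid_times <- function(path, tier = NULL) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(l) sub("^[^=]*=\\s*", "", l)
  item_starts <- grep("^\\s*item\\s*\\[\\d+\\]", lines)
  if (length(item_starts) == 0) stop("no tiers found in ", path, call. = FALSE)
  item_ends <- c(item_starts[-1] - 1, length(lines))
  tiers <- lapply(seq_along(item_starts), function(i) {
    block <- lines[item_starts[i]:item_ends[i]]
    nm <- gsub('"', "", getv(block[grep("^\\s*name\\s*=", block)[1]]))
    cls <- gsub('"', "", getv(block[grep("^\\s*class\\s*=", block)[1]]))
    list(name = trimws(nm), class = trimws(cls), block = block)
  })
  sel <- if (is.null(tier)) tiers[[1]]
    else if (is.numeric(tier)) tiers[[tier]]
    else {
      hit <- which(vapply(tiers, function(x) x$name == tier, logical(1)))
      if (!length(hit)) stop("no tier named '", tier, "' in ", path, call. = FALSE)
      tiers[[hit[1]]]
    }
  b <- sel$block
  if (grepl("TextTier", sel$class)) {
    num_lines <- grep("^\\s*(number|time)\\s*=", b, value = TRUE)
    as.numeric(trimws(vapply(num_lines, getv, character(1))))
  } else {
    xmin <- as.numeric(trimws(vapply(grep("^\\s*xmin\\s*=", b, value = TRUE),
                                     getv, character(1))))
    txt <- gsub('"', "", trimws(vapply(grep("^\\s*text\\s*=", b, value = TRUE),
                                       getv, character(1))))
    # first xmin is the tier's own extent; intervals follow
    xmin <- xmin[-1]
    xmin[nzchar(txt)]
  }
}

#' Write an event series as delimited text
#' @param ev An [event_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "event_series"))
  df <- data.frame(participant = ev$participant, group = ev$group,
                   sentence = ev$sentence, metre = ev$metre, kind = ev$kind,
                   time_s = ev$times)
  write_table_txt(df, path)
}

#' Run configuration
#'
#' Validated configuration for the pipeline driver. Invalid configurations
#' fail before any data are touched.
#'
#' @param band_config An [am_band_config()] or list of band edges.
#' @param env_rate Envelope sampling rate, samples/s.
#' @param spectral_band Acoustic front-end mode: `"broadband"` or a band
#'   index (1-5).
#' @param energy_threshold_db Silence threshold for PSI sample selection.
#' @param alpha Rayleigh gate level.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param paths Named list of input paths (mode-dependent).
#' @return A `run_config` object.
#' @export
run_config <- function(band_config = am_band_config(), env_rate = 1000,
                       spectral_band = "broadband",
                       energy_threshold_db = -40, alpha = 0.05, seed = 1,
                       out_dir = "results", paths = list()) {
  if (!inherits(band_config, "am_band_config")) {
    band_config <- do.call(am_band_config, band_config)
  }
  stopifnot(env_rate >= 2 * band_config$phoneme[2],
            is.numeric(alpha), alpha > 0, alpha < 1,
            identical(spectral_band, "broadband") ||
              (is.numeric(spectral_band) && spectral_band >= 1))
  structure(list(band_config = band_config, env_rate = env_rate,
                 spectral_band = spectral_band,
                 energy_threshold_db = energy_threshold_db, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir, paths = paths),
            class = "run_config")
}

#' Load a run configuration from JSON
#' @param path JSON file with `run_config` fields.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg),
                        c("env_rate", "spectral_band", "energy_threshold_db",
                          "alpha", "seed", "out_dir"))]
  if (!is.null(cfg$band_config)) args$band_config <- cfg$band_config
  if (!is.null(cfg$paths)) args$paths <- as.list(cfg$paths)
  do.call(run_config, args)
}

#' Run an analysis pipeline
#'
#' Drives one of the three analysis modes and writes tidy result tables, a
#' log and a machine-readable manifest into `cfg$out_dir`. Output is
#' deterministic given the seed; numeric formatting is fixed at 12
#' significant digits.
#'
#' `"simulate"` synthesises a cohort and writes its stimuli, taps and
#' behaviour. `"perception"` scores taps against stimulus AM tiers
#' (inputs: either the simulated bundle or WAV + tap tables via
#' `cfg$paths`). `"production"` analyses produced utterances (VOI + PSI).
#'
#' @param cfg A [run_config()].
#' @param mode `"perception"`, `"production"` or `"simulate"`.
#' @return Invisible list of result objects (also written to disk).
#' @export
run_pipeline <- function(cfg, mode = c("perception", "production", "simulate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = mode, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("samphr")),
                   config = cfg[c("env_rate", "spectral_band",
                                  "energy_threshold_db", "alpha")],
                   status = "running", outputs = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(write_manifest())
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_table_txt(x, p)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  res <- list()
  tryCatch({
    if (mode == "simulate") {
      co <- synth_cohort(cohort_spec(seed = cfg$seed),
                         stimulus_spec(seed = cfg$seed))
      emit(co$participants, "participants.tsv")
      emit(co$behaviour, "behaviour.tsv")
      tap_rows <- do.call(rbind, lapply(co$taps, function(tp) {
        data.frame(participant = tp$participant, group = tp$group,
                   sentence = tp$sentence, metre = tp$metre,
                   time_s = tp$times)
      }))
      emit(tap_rows, "taps.tsv")
      for (sn in names(co$stimuli)) {
        write_wav(co$stimuli[[sn]]$waveform,
                  file.path(cfg$out_dir, paste0("stimulus_", sn, ".wav")))
        manifest$outputs <- c(manifest$outputs, paste0("stimulus_", sn, ".wav"))
      }
      res$cohort <- co
    } else if (mode == "perception") {
      co <- load_or_simulate_cohort(cfg)
      scores <- cohort_phase_scores(co)
      emit(scores, "phase_scores.tsv")
      gt <- group_entrainment_tests(scores, alpha = cfg$alpha)
      emit(gt, "group_tests.tsv")
      itis <- do.call(rbind, lapply(co$taps, function(tp) {
        sel <- select_analysis_taps(tp, co$timing)
        inter_tap_intervals(sel)
      }))
      emit(itis, "itis.tsv")
      corr <- phase_literacy_correlations(scores, co$behaviour)
      emit(corr, "phase_literacy_correlations.tsv")
      ch <- compass_histogram(scores[scores$tier == "syllable" &
                                       scores$metre == "trochaic", ])
      emit(data.frame(bin_lo = utils::head(ch$bin_edges, -1),
                      bin_hi = ch$bin_edges[-1], count = ch$counts),
           "compass_syllable_trochaic.tsv")
      res <- list(scores = scores, group_tests = gt, correlations = corr)
    } else {
      pr <- load_or_simulate_production(cfg)
      vois <- do.call(rbind, lapply(pr, function(p) {
        do.call(rbind, lapply(split(p$onsets_by_repetition,
                                    p$onsets_by_repetition$repetition),
                              function(rr) {
          keep <- rr$repetition[1] >= 3
          if (!keep) return(NULL)
          ev <- event_series(rr$onset_s, "vowel_onset",
                             participant = p$participant, group = p$group)
          v <- vowel_onset_intervals(ev)
          v$repetition <- rr$repetition[1]
          v
        }))
      }))
      emit(vois, "vois.tsv")
      utts <- list()
      for (p in pr) {
        for (r in 3:5) {
          win <- p$repetition_windows[p$repetition_windows$repetition == r, ]
          i0 <- max(1, floor(win$start_s * p$waveform$rate))
          i1 <- min(length(p$waveform$samples), ceiling(win$end_s * p$waveform$rate))
          utts[[length(utts) + 1]] <- list(
            waveform = waveform(p$waveform$samples[i0:i1], p$waveform$rate),
            participant = p$participant, group = p$group,
            sentence = "s1", metre = p$metre, repetition = r, included = TRUE)
        }
      }
      cb <- crossband_phase_analysis(utts,
                                     energy_threshold_db = cfg$energy_threshold_db,
                                     alpha = cfg$alpha)
      emit(cb$per_participant, "psi_per_participant.tsv")
      if (!is.null(cb$group_tests)) emit(cb$group_tests, "psi_group_tests.tsv")
      res <- list(vois = vois, crossband = cb)
    }
    manifest$status <- "ok"
  }, error = function(e) {
    manifest$status <<- paste("failed:", conditionMessage(e))
    write_manifest()
    stop(e)
  })
  write_manifest()
  invisible(res)
}

# perception inputs: simulated unless cfg$paths supplies taps + stimuli
load_or_simulate_cohort <- function(cfg) {
  if (!is.null(cfg$paths$taps)) {
    stop("external tap-log loading requires paths$taps, paths$audio_dir and ",
         "a sentence->metre map; supply them or use mode='simulate' first",
         call. = FALSE)
  }
  synth_cohort(cohort_spec(seed = cfg$seed), stimulus_spec(seed = cfg$seed))
}

load_or_simulate_production <- function(cfg, n_per_group = 6) {
  # simulated production cohort: identical coupling in both groups unless
  # configured otherwise
  out <- list()
  k <- 0
  for (g in c("control", "dyslexic")) {
    ang <- if (g == "control") 0.94 * pi else 0.88 * pi
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      p <- synth_production(stimulus_spec(seed = cfg$seed + k),
                            coupling_angle = ang, jitter_sd_ms = 5,
                            seed = cfg$seed + 1000 + k,
                            participant = sprintf("%s%02d", substr(g, 1, 1), i),
                            group = g)
      p$participant <- sprintf("%s%02d", substr(g, 1, 1), i)
      p$group <- g
      p$metre <- "trochaic"
      out[[k]] <- p
    }
  }
  out
}

#' Command-line interface
#'
#' Subcommands: `analyze-perception`, `analyze-production`, `simulate`.
#' Common options: `--config <json>`, `--seed <int>`, `--out <dir>`.
#' Invoke via `Rscript -e 'samphr::samphr_cli()' <subcommand> ...` or the
#' wrapper script in `inst/cli/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
samphr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: samphr <analyze-perception|analyze-production|simulate>",
    "[--config cfg.json] [--seed N] [--out DIR]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  mode <- switch(args[1], `analyze-perception` = "perception",
                 `analyze-production` = "production",
                 simulate = "simulate", NULL)
  if (is.null(mode)) { message(usage); return(invisible(1L)) }
  opt <- list(seed = 1L, out = "results", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% c("seed", "out", "config") || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else run_config()
  cfg$seed <- as.integer(opt$seed)
  cfg$out_dir <- opt$out
  run_pipeline(cfg, mode)
  invisible(0L)
}
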