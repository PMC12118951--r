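# Session artifact I/O and pipeline orchestration. All tabular artifacts are
# TSV with floats at 9 significant digits and NA serialized as "NA"; LFP is a
# flat little-endian float32 binary (channel-major) with a JSON sidecar; the
# manifest is JSON.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.9g", x))
  out
}

#' Write result tables as TSV
#'
#' Deterministic column order (as given), floats at 9 significant digits,
#' `NA` written as the literal string `NA`. Re-reading with [read_table()]
#' reproduces the serialized values exactly.
#'
#' @param tables named list of data.frames; each is written to
#'   `<out_dir>/<name>.tsv`.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
save_tables <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    df <- as.data.frame(tables[[nm]])
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
      else if (is.logical(df[[j]])) df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                                                      ifelse(df[[j]], "TRUE", "FALSE"))
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
    path
  }, character(1))
  invisible(paths)
}

#' Read a TSV table written by [save_tables()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write an LFP set as float32 binary plus JSON sidecar
#' @param lfp an `lfp_set` (list with `data` matrix samples x channels, `fs`,
#'   `channels` table).
#' @param bin_path,meta_path output paths.
#' @return invisibly, `bin_path`.
#' @export
write_lfp <- function(lfp, bin_path, meta_path) {
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp$data), con, size = 4, endian = "little")
  meta <- list(fs = lfp$fs, n_channels = ncol(lfp$data),
               n_samples = nrow(lfp$data), dtype = "float32",
               order = "channel-major", channels = lfp$channels)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), meta_path)
  invisible(bin_path)
}

#' Read an LFP set written by [write_lfp()]
#' @param bin_path,meta_path paths to binary and sidecar.
#' @return an `lfp_set`.
#' @export
read_lfp <- function(bin_path, meta_path) {
  if (!file.exists(bin_path)) stop("missing file: ", bin_path)
  meta <- jsonlite::fromJSON(meta_path)
  n <- meta$n_samples * meta$n_channels
  x <- readBin(bin_path, numeric(), n = n, size = 4, endian = "little")
  structure(list(data = matrix(x, nrow = meta$n_samples, ncol = meta$n_channels),
                 fs = meta$fs, channels = as.data.frame(meta$channels)),
            class = "lfp_set")
}

#' Load and validate a session from its manifest
#'
#' Reads all artifacts referenced by the manifest and validates them: every
#' referenced file must exist, spike times must be sorted within each unit
#' (the offending row is named otherwise), and hypnogram intervals must be
#' non-overlapping (the offending pair is named).
#'
#' @param manifest_path path to `manifest.json`.
#' @return a `session_bundle` list: `manifest`, `units`, `spikes`,
#'   `hypnogram`, `lfp`, `truth_events`, `truth_gains`, `waveforms`,
#'   `features`, `shocks`, `shock_pulses`, `cs`, `dir`.
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("missing manifest: ", manifest_path)
  man <- jsonlite::fromJSON(manifest_path)
  dir <- dirname(manifest_path)
  p <- function(key) {
    f <- man$files[[key]]
    if (is.null(f)) return(NULL)
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("manifest references missing file: ", f)
    path
  }
  spikes <- read_table(p("spikes"))
  ord <- order(match(spikes$unit_id, unique(spikes$unit_id)))
  spikes <- spikes[ord, , drop = FALSE] # keep unit blocks contiguous
  bad <- which(c(FALSE, diff(spikes$t) < 0) &
                 spikes$unit_id == c("", head(spikes$unit_id, -1)))
  if (length(bad) > 0)
    stop(sprintf("unsorted spike times for unit %s at row %d",
                 spikes$unit_id[bad[1]], bad[1]))
  hyp <- read_table(p("hypnogram"))
  if (nrow(hyp) > 1) {
    hyp <- hyp[order(hyp$start), , drop = FALSE]
    ov <- which(head(hyp$end, -1) > tail(hyp$start, -1))
    if (length(ov) > 0)
      stop(sprintf("overlapping hypnogram intervals at rows %d and %d",
                   ov[1], ov[1] + 1))
  }
  lfp <- if (!is.null(man$files$lfp)) read_lfp(p("lfp"), p("lfp_meta")) else NULL
  opt <- function(key) if (!is.null(man$files[[key]])) read_table(p(key)) else NULL
  structure(list(manifest = man, units = read_table(p("units")), spikes = spikes,
                 hypnogram = hyp, lfp = lfp,
                 truth_events = opt("truth_events"), truth_gains = opt("truth_gains"),
                 waveforms = opt("waveforms"), features = opt("features"),
                 shocks = opt("shocks"), shock_pulses = opt("shock_pulses"),
                 cs = opt("cs"), dir = dir),
            class = "session_bundle")
}

#' Select state time within session windows
#'
#' Intersects the hypnogram intervals of one state with a set of session
#' windows (e.g. a single home-cage session, or all sessions pooled).
#'
#' @param hypnogram hypnogram interval table with a `state` column.
#' @param state one of `"NREM"`, `"REM"`, `"WAKE"`.
#' @param session_windows interval table of windows; `NULL` selects all time.
#' @return interval table of the clipped state intervals.
#' @export
select_state_time <- function(hypnogram, state, session_windows = NULL) {
  if (!state %in% c("NREM", "REM", "WAKE"))
    stop("unknown state label: ", state)
  iv <- hypnogram[hypnogram$state == state, c("start", "end"), drop = FALSE]
  if (is.null(session_windows)) return(iv_union(iv, merge_touching = FALSE))
  iv_intersect(iv, session_windows)
}

#' Run the full analysis pipeline on a session
#'
#' Executes the analysis stages in dependency order -- unit quality, cell
#' typing, sleep structure, oscillation detection, state preference, event
#' modulation, coactivity, statistics -- and writes one TSV per result table
#' under `out_dir`, plus a JSON report with parameters, seed and stage
#' summaries. Given the same inputs and seed, outputs are bit-identical
#' across runs.
#'
#' @param session a `session_bundle` (or path to a manifest).
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all, in order);
#'   a requested stage whose dependency is not requested fails before any
#'   computation.
#' @param params list of stage parameter overrides: `n_shuffles`,
#'   `n_surrogates`, `alpha`, `detector_params`.
#' @param seed integer seed controlling all stochastic stages.
#' @return report list (stage summaries + file paths), invisibly.
#' @export
run_pipeline <- function(session, out_dir,
                         stages = c("quality", "typing", "sleep", "detection",
                                    "preference", "modulation", "coactivity", "stats"),
                         params = list(), seed = 1L) {
  if (is.character(session)) session <- load_session(session)
  order_all <- c("quality", "typing", "sleep", "detection", "preference",
                 "modulation", "coactivity", "stats")
  stages <- intersect(order_all, stages)
  deps <- list(typing = "quality", detection = "sleep",
               preference = "sleep", modulation = c("sleep", "detection", "preference"),
               coactivity = c("detection", "preference", "typing"),
               stats = c("modulation", "coactivity"))
  for (st in stages) {
    miss <- setdiff(deps[[st]], stages)
    if (length(miss) > 0)
      stop(sprintf("stage '%s' requires stage(s): %s", st, paste(miss, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n_shuffles <- params$n_shuffles %||% 1000L
  n_surrogates <- params$n_surrogates %||% 1000L
  alpha <- params$alpha %||% 0.05
  spl <- split(session$spikes$t, session$spikes$unit_id)
  spl <- spl[session$units$unit_id]
  names(spl) <- session$units$unit_id
  report <- list(seed = seed, stages = stages,
                 params = list(n_shuffles = n_shuffles,
                               n_surrogates = n_surrogates, alpha = alpha))
  res <- list()

  if ("quality" %in% stages) {
    res$quality <- quality_table(session)
    report$quality <- list(n_units = nrow(res$quality),
                           n_included = sum(res$quality$included, na.rm = TRUE))
  }
  included <- if (!is.null(res$quality))
    res$quality$unit_id[res$quality$included %in% TRUE] else session$units$unit_id

  if ("typing" %in% stages) {
    ct <- type_units(spl[included],
                     session$units[match(included, session$units$unit_id), ],
                     widths = res$quality$spike_width_ms[match(included, res$quality$unit_id)],
                     n_surrogates = n_surrogates)
    res$cell_types <- ct$types
    res$pair_calls <- ct$pairs
    report$typing <- list(n_excitatory = sum(ct$types$label == "excitatory"),
                          n_inhibitory = sum(ct$types$label == "inhibitory"))
  }

  if ("sleep" %in% stages) {
    hyp <- normalize_hypnogram(session$hypnogram)
    ext <- find_extended_sleep(hyp)
    trip <- find_triplets(hyp)
    res$epochs <- hyp
    res$extended_sleep <- ext
    res$triplets <- trip
    report$sleep <- list(n_epochs = nrow(hyp), n_extended = nrow(ext),
                         n_triplets = nrow(trip))
  }

  if ("detection" %in% stages) {
    ev <- detect_all_oscillations(session$lfp, res$epochs,
                                  params = params$detector_params)
    res$events <- ev
    summ <- lapply(split(ev, ev$kind), function(e)
      event_summary(e, select_state_time(res$epochs, "NREM")))
    res$event_summary <- do.call(rbind, lapply(names(summ), function(k)
      cbind(kind = k, as.data.frame(summ[[k]]))))
    report$detection <- as.list(table(ev$kind))
  }

  if ("preference" %in% stages) {
    res$preference <- preference_table(spl[included], res$epochs,
                                       n_shuffles = n_shuffles, alpha = alpha)
    report$preference <- as.list(table(res$preference$label))
  }

  if ("modulation" %in% stages) {
    res$gains <- gain_table(spl[included], res$events, res$epochs)
    report$modulation <- list(n_rows = nrow(res$gains))
  }

  if ("coactivity" %in% stages) {
    exc <- if (!is.null(res$cell_types))
      res$cell_types$unit_id[res$cell_types$label == "excitatory"] else included
    res$coactivity <- coactivity_table(spl[exc],
                                       session$units[match(exc, session$units$unit_id), ],
                                       res$events, res$preference)
    report$coactivity <- list(n_pairs = nrow(res$coactivity))
  }

  if ("stats" %in% stages) {
    res$stats <- pipeline_stats(res)
    report$stats <- list(n_tests = nrow(res$stats))
  }

  save_tables(res[!vapply(res, is.null, logical(1))], out_dir)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
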