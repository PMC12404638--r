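#' Write a session to a plain-text directory container
#'
#' Serializes a `sim_session` to a directory: JSON for the schedule, unit
#' table, and metadata; one CSV per stimulus per layer for the features;
#' one CSV per presentation for the counts. Everything round-trips through
#' [read_session()].
#'
#' @param session A `sim_session`.
#' @param path Directory to create (must not exist unless `overwrite`).
#' @param overwrite Replace an existing directory.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  stopifnot(inherits(session, "sim_session"))
  if (dir.exists(path)) {
    if (!overwrite) abort("path exists; use overwrite = TRUE")
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  meta <- list(
    bin_width = session$bin_width, seed = session$seed,
    L = session$stacks[[1]]$L, strides = session$stacks[[1]]$strides,
    mode = session$stacks[[1]]$mode,
    kernel_width = session$stacks[[1]]$kernel_width,
    layer_rates = vapply(session$stacks[[1]]$layers, sampling_rate,
                         numeric(1)),
    base_rate = sampling_rate(session$stacks[[1]]$base)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(stimuli = session$schedule$stimuli,
                            order = session$schedule$order),
                       file.path(path, "schedule.json"),
                       auto_unbox = TRUE, digits = NA)
  units <- session$units
  units$true_trf <- lapply(units$true_trf, function(m) as.data.frame(m))
  jsonlite::write_json(units, file.path(path, "units.json"),
                       auto_unbox = TRUE, digits = NA)

  dir.create(file.path(path, "features"))
  for (sid in names(session$stacks)) {
    st <- session$stacks[[sid]]
    utils::write.csv(fm_values(st$base),
                     file.path(path, "features", paste0(sid, "_base.csv")),
                     row.names = FALSE)
    for (l in seq_len(st$L)) {
      utils::write.csv(fm_values(st$layers[[l]]),
                       file.path(path, "features",
                                 sprintf("%s_L%d.csv", sid, l)),
                       row.names = FALSE)
    }
  }
  dir.create(file.path(path, "counts"))
  for (p in seq_along(session$responses$counts)) {
    utils::write.csv(session$responses$counts[[p]],
                     file.path(path, "counts", sprintf("pres%04d.csv", p)),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a session written by [write_session()]
#' @param path Directory written by [write_session()].
#' @return A `sim_session` (without stored hierarchy weights, which are
#'   not needed to re-run the analyses; perturbation variants require the
#'   original object).
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sch_raw <- jsonlite::read_json(file.path(path, "schedule.json"),
                                 simplifyVector = TRUE)
  schedule <- structure(list(stimuli = tibble::as_tibble(sch_raw$stimuli),
                             order = tibble::as_tibble(sch_raw$order)),
                        class = "stim_schedule")
  units_raw <- jsonlite::read_json(file.path(path, "units.json"),
                                   simplifyVector = TRUE)
  units <- tibble::as_tibble(units_raw)
  units$true_trf <- lapply(units$true_trf, function(d) as.matrix(as.data.frame(d)))
  ids <- schedule$stimuli$stimulus_id
  stacks <- lapply(ids, function(sid) {
    base <- feature_matrix(as.matrix(utils::read.csv(
      file.path(path, "features", paste0(sid, "_base.csv")))),
      meta$base_rate)
    layers <- lapply(seq_len(meta$L), function(l) {
      feature_matrix(as.matrix(utils::read.csv(
        file.path(path, "features", sprintf("%s_L%d.csv", sid, l)))),
        meta$layer_rates[l])
    })
    structure(list(layers = layers, weights = NULL,
                   strides = as.integer(meta$strides),
                   L = as.integer(meta$L), base = base, mode = meta$mode,
                   kernel_width = as.integer(meta$kernel_width)),
              class = "feature_stack")
  })
  names(stacks) <- ids
  files <- sort(list.files(file.path(path, "counts"), full.names = TRUE))
  counts <- lapply(files, function(f) {
    m <- as.matrix(utils::read.csv(f, check.names = FALSE))
    rownames(m) <- units$unit_id
    m
  })
  responses <- structure(list(counts = counts, schedule = schedule,
                              bin_width = meta$bin_width,
                              unit_ids = units$unit_id),
                         class = "response_set")
  structure(list(schedule = schedule, stacks = stacks, units = units,
                 responses = responses, bin_width = meta$bin_width,
                 seed = meta$seed),
            class = "sim_session")
}

#' Minimal 16-bit PCM WAV I/O
#'
#' Reads and writes single-channel 16-bit PCM WAV files; amplitudes are in
#' (-1, 1).
#'
#' @param wave Numeric vector in (-1, 1).
#' @param sample_rate Hz.
#' @param path File path.
#' @return `write_wav`: `path` invisibly. `read_wav`: list with `wave` and
#'   `sample_rate`.
#' @export
write_wav <- function(wave, sample_rate, path) {
  stopifnot(is.numeric(wave), sample_rate > 0)
  pcm <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAV file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave_tag <- readChar(con, 4)
  if (!identical(wave_tag, "WAVE")) abort("not a WAV file")
  sample_rate <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) abort("no data chunk found")
    len <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        abort("only mono 16-bit PCM WAV is supported")
      }
      sample_rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, raw(), len - 8))
    } else if (identical(tag, "data")) {
      pcm <- readBin(con, integer(), len %/% 2, size = 2, endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, raw(), len))
    }
  }
}
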