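#' Session container on disk
#'
#' A recording session (layout, raw blocks, events, footprints,
#' segmentations, ground truth) is stored as a plain directory:
#'
#' ```
#' session/
#'   meta.json                  format tag and content listing
#'   layout.csv                 id,x_um,y_um
#'   config.json                pipeline configuration (optional)
#'   events.csv                 electrode_id,time_ms,amplitude_uV (optional)
#'   blocks/<k>/meta.json       config_id, fs_khz, electrode ids, dims
#'   blocks/<k>/traces.f64      column-major float64 (uV)
#'   neurons/<id>/footprint.json   t_ms, electrode ids, n_spikes, AIS
#'   neurons/<id>/waveforms.f64    column-major float64 (uV)
#'   neurons/<id>/segmentation_<method>.json
#'   ground_truth/<id>.csv      x_um,y_um
#' ```
#'
#' Arrays are raw little-endian doubles, so the round trip is bit-exact;
#' everything else is JSON/CSV. `read_session()` raises a format error
#' naming the offending path when a required file is missing or an array
#' file does not match its declared dimensions.
#'
#' @param session A list with any of the elements `layout`, `config`,
#'   `blocks` (list of `recording_block`), `events` (data frame),
#'   `footprints` (named list of [footprint()]), `segmentations` (named
#'   list of lists of `axon_segmentation`), `ground_truth` (named list of
#'   point matrices).
#' @param path Session directory.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session list.
#' @name session_io
NULL

write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8, endian = "little")
}

read_f64 <- function(path, n) {
  if (!file.exists(path)) stop("missing array file: ", path)
  expect_bytes <- n * 8
  if (file.info(path)$size != expect_bytes)
    stop("array file ", path, " has ", file.info(path)$size,
         " bytes, expected ", expect_bytes, " (truncated or corrupt)")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8, endian = "little")
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

read_json <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname session_io
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "axonmap-session", version = 1L,
               contents = names(session)[!vapply(session, is.null,
                                                 logical(1))])
  write_json(meta, file.path(path, "meta.json"))
  if (!is.null(session$layout))
    write_layout(session$layout, file.path(path, "layout.csv"))
  if (!is.null(session$config))
    write_json(session$config, file.path(path, "config.json"))
  if (!is.null(session$events))
    utils::write.csv(session$events, file.path(path, "events.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(session$fixed_ids))
    write_json(list(fixed_ids = session$fixed_ids),
               file.path(path, "fixed_electrodes.json"))
  if (!is.null(session$configurations))
    write_json(session$configurations,
               file.path(path, "configurations.json"))
  if (!is.null(session$arbors))
    write_json(lapply(session$arbors, function(a)
      list(soma = a$soma, branches = lapply(a$branches, function(b)
        list(points = unname(b$points), pathlen = b$pathlen,
             amp_uV = b$amp_uV, parent = b$parent)))),
      file.path(path, "arbors.json"))
  for (b in session$blocks %||% list()) {
    bdir <- file.path(path, "blocks", b$config_id)
    dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
    write_json(list(config_id = b$config_id, fs_khz = b$fs_khz,
                    electrode_id = b$electrode_id, dim = dim(b$traces)),
               file.path(bdir, "meta.json"))
    write_f64(b$traces, file.path(bdir, "traces.f64"))
  }
  for (id in names(session$footprints %||% list())) {
    fp <- session$footprints[[id]]
    ndir <- file.path(path, "neurons", id)
    dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
    write_json(list(neuron = fp$neuron, t_ms = fp$t_ms,
                    electrode_id = fp$electrode_id, n_spikes = fp$n_spikes,
                    ais_electrode = fp$ais_electrode,
                    dim = dim(fp$waveforms)),
               file.path(ndir, "footprint.json"))
    write_f64(fp$waveforms, file.path(ndir, "waveforms.f64"))
  }
  for (id in names(session$segmentations %||% list())) {
    ndir <- file.path(path, "neurons", id)
    dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
    for (seg in session$segmentations[[id]]) {
      write_json(list(neuron = seg$neuron, method = seg$method,
                      params = seg$params, electrodes = seg$electrodes),
                 file.path(ndir, paste0("segmentation_", seg$method,
                                        ".json")))
    }
  }
  for (id in names(session$ground_truth %||% list())) {
    gdir <- file.path(path, "ground_truth")
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(session$ground_truth[[id]]),
                     file.path(gdir, paste0(id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname session_io
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session directory at ", path)
  meta <- read_json(file.path(path, "meta.json"))
  if (!identical(meta$format, "axonmap-session"))
    stop("not an axonmap session: ", file.path(path, "meta.json"))
  out <- list()
  lp <- file.path(path, "layout.csv")
  if (file.exists(lp)) out$layout <- read_layout(lp)
  cp <- file.path(path, "config.json")
  if (file.exists(cp)) out$config <- read_json(cp)
  ep <- file.path(path, "events.csv")
  if (file.exists(ep)) out$events <- utils::read.csv(ep)
  fe <- file.path(path, "fixed_electrodes.json")
  if (file.exists(fe)) out$fixed_ids <- read_json(fe)$fixed_ids
  cj <- file.path(path, "configurations.json")
  if (file.exists(cj)) out$configurations <- jsonlite::read_json(
    cj, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  aj <- file.path(path, "arbors.json")
  if (file.exists(aj)) {
    raw <- jsonlite::read_json(aj, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    out$arbors <- lapply(raw, function(a)
      structure(list(soma = a$soma, branches = lapply(a$branches, function(b)
        list(points = if (is.matrix(b$points)) b$points else
               do.call(rbind, b$points),
             pathlen = b$pathlen, amp_uV = b$amp_uV,
             parent = if (is.null(b$parent) || is.na(b$parent))
               NA_integer_ else as.integer(b$parent)))),
        class = "sim_arbor"))
  }
  broot <- file.path(path, "blocks")
  if (dir.exists(broot)) {
    out$blocks <- lapply(list.dirs(broot, recursive = FALSE), function(bdir) {
      bm <- read_json(file.path(bdir, "meta.json"))
      tr <- matrix(read_f64(file.path(bdir, "traces.f64"), prod(bm$dim)),
                   bm$dim[1], bm$dim[2])
      structure(list(traces = tr, fs_khz = bm$fs_khz,
                     electrode_id = bm$electrode_id,
                     config_id = bm$config_id, spike_times_ms = NULL),
                class = "recording_block")
    })
  }
  nroot <- file.path(path, "neurons")
  if (dir.exists(nroot)) {
    out$footprints <- list()
    out$segmentations <- list()
    for (ndir in list.dirs(nroot, recursive = FALSE)) {
      id <- basename(ndir)
      fj <- file.path(ndir, "footprint.json")
      if (file.exists(fj)) {
        fm <- read_json(fj)
        wav <- matrix(read_f64(file.path(ndir, "waveforms.f64"),
                               prod(fm$dim)), fm$dim[1], fm$dim[2])
        out$footprints[[id]] <- footprint(
          wav, fm$t_ms, fm$electrode_id, fm$n_spikes,
          fixed_ids = fm$ais_electrode, neuron = fm$neuron %||% NA)
      }
      segs <- list.files(ndir, pattern = "^segmentation_.*\\.json$",
                         full.names = TRUE)
      if (length(segs))
        out$segmentations[[id]] <- lapply(segs, read_json)
    }
    if (!length(out$footprints)) out$footprints <- NULL
    if (!length(out$segmentations)) out$segmentations <- NULL
  }
  groot <- file.path(path, "ground_truth")
  if (dir.exists(groot)) {
    files <- list.files(groot, pattern = "\\.csv$", full.names = TRUE)
    out$ground_truth <- lapply(files, function(f) as.matrix(utils::read.csv(f)))
    names(out$ground_truth) <- sub("\\.csv$", "", basename(files))
  }
  out
}
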