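#' Read a photon stream from a columnar TSV file
#'
#' The interchange layout is a plain TSV with a commented header carrying the
#' instrument metadata and one row per photon:
#' ```
#' # mfdburst-photons v1
#' # sync_rate_hz=26670000
#' # n_tcspc_bins=4096
#' # duration_s=10
#' macrotime  nanotime  detector
#' 13332      512       Bpar
#' ```
#' `macrotime` is in integer sync counts, `nanotime` in integer TCSPC bins,
#' `detector` one of `Bpar`, `Bperp`, `Rpar`, `Rperp`. Gates are recomputed on
#' read from the (optional) stored windows, so a gate label is never stored.
#'
#' @param path file path.
#' @param nrows,skip read at most `nrows` photon records, skipping the first
#'   `skip` records -- a chunked read; defaults read everything.
#' @return a [photon_stream()].
#' @export
read_photons <- function(path, nrows = Inf, skip = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con); on.exit(NULL)
  meta <- parse_photon_header(header)
  n_head <- length(header)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = n_head,
                          nrows = if (is.finite(nrows)) nrows + skip else Inf)
  for (f in c("macrotime", "nanotime", "detector"))
    if (!f %in% names(dt)) stop("photon file misses mandatory field '", f, "'")
  dt$detector <- as.character(dt$detector)
  if (skip > 0) {
    dt <- if (skip >= nrow(dt)) dt[0, , drop = FALSE]
          else dt[(skip + 1L):nrow(dt), , drop = FALSE]
  }
  if (is.finite(nrows) && nrow(dt) > nrows) dt <- dt[seq_len(nrows), , drop = FALSE]
  ps <- photon_stream(dt$macrotime, dt$nanotime, dt$detector,
                      sync_rate_hz = meta$sync_rate_hz,
                      n_tcspc_bins = meta$n_tcspc_bins,
                      duration_s = meta$duration_s)
  if (!is.null(meta$windows)) ps <- assign_pie_gates(ps, meta$windows)
  ps
}

parse_photon_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) default else as.numeric(vals[i])
  }
  sync <- get("sync_rate_hz")
  if (is.null(sync)) stop("photon file misses mandatory field 'sync_rate_hz'")
  windows <- NULL
  if (!is.na(match("gate_donor_s", keys))) {
    dw <- as.numeric(strsplit(vals[match("gate_donor_s", keys)], ",")[[1]])
    aw <- as.numeric(strsplit(vals[match("gate_acceptor_s", keys)], ",")[[1]])
    windows <- gate_windows(dw, aw)
  }
  list(sync_rate_hz = sync,
       n_tcspc_bins = as.integer(get("n_tcspc_bins", 4096)),
       duration_s = get("duration_s"),
       windows = windows)
}

#' Write a photon stream to a columnar TSV file
#'
#' Writes the layout documented in [read_photons()]. Integer fields round-trip
#' exactly.
#'
#' @param ps a [photon_stream()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_photons <- function(ps, path) {
  stopifnot(inherits(ps, "photon_stream"))
  header <- c("# mfdburst-photons v1",
              sprintf("# sync_rate_hz=%.10g", ps$sync_rate_hz),
              sprintf("# n_tcspc_bins=%d", ps$n_tcspc_bins),
              sprintf("# duration_s=%.10g", ps$duration_s))
  if (!is.null(ps$windows)) {
    header <- c(header,
      sprintf("# gate_donor_s=%.12g,%.12g", ps$windows$donor[1], ps$windows$donor[2]),
      sprintf("# gate_acceptor_s=%.12g,%.12g", ps$windows$acceptor[1], ps$windows$acceptor[2]))
  }
  ok <- tryCatch({
    writeLines(header, path)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  dt <- data.table::data.table(
    macrotime = sprintf("%.0f", ps$macrotime),
    nanotime = ps$nanotime,
    detector = DETECTORS[ps$detector])
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
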