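# Plain-text interchange formats for trials and spectrograms.

#' Write / read a single trial as delimited text
#'
#' One integer ADC code per line, preceded by a header comment carrying the
#' label and seed (`# label=<int> seed=<int>`).
#'
#' @param trial a [raw_trial()].
#' @param path output file.
#' @return `path` invisibly, or a [raw_trial()] for the reader.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "raw_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%d seed=%d", trial$label, trial$seed), con)
  writeLines(as.character(trial$samples), con)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  m <- regmatches(header, regexec("label=(-?\\d+) seed=(-?\\d+)", header))[[1]]
  if (length(m) != 3) stop_config("missing '# label=.. seed=..' header")
  raw_trial(as.integer(lines[-1]), as.integer(m[2]), as.integer(m[3]))
}

#' Write / read a multi-trial container
#'
#' Tab-separated text with one row per trial: columns `label`, `seed`, then
#' the 2112 sample codes (`s1` ... `s2112`).
#'
#' @param trials a `semg_trials` list.
#' @param path output file.
#' @return `path` invisibly, or a `semg_trials` list for the reader.
#' @export
write_trials <- function(trials, path) {
  n <- length(trials[[1]]$samples)
  dt <- data.table::as.data.table(
    t(vapply(trials, function(tr) c(tr$label, tr$seed, tr$samples),
             integer(n + 2))))
  data.table::setnames(dt, c("label", "seed", paste0("s", seq_len(n))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  trials <- lapply(seq_len(nrow(dt)), function(i) {
    raw_trial(as.integer(dt[i, -(1:2)]), dt$label[i], dt$seed[i])
  })
  structure(trials, class = "semg_trials")
}

#' Write / read a spectrogram as delimited text
#'
#' 32 rows (frequency, ascending retained-bin order) by 32 tab-separated
#' columns (time); a header comment records the label when known.
#'
#' @param spect a `spectrogram32`.
#' @param path output file.
#' @return `path` invisibly, or a `spectrogram32` for the reader.
#' @export
write_spectrogram <- function(spect, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spectrogram32 label=%d",
                     attr(spect, "label") %||% NA_integer_), con)
  utils::write.table(unclass(spect), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrogram
#' @export
read_spectrogram <- function(path) {
  lines <- readLines(path)
  label <- suppressWarnings(
    as.integer(sub(".*label=(-?\\d+|NA).*", "\\1", lines[1])))
  m <- as.matrix(utils::read.table(text = lines[-1], sep = "\t"))
  dimnames(m) <- NULL
  structure(m, label = label, class = c("spectrogram32", "matrix", "array"))
}
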