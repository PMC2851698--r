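#' Assemble a multichannel physiological recording
#'
#' An `edr_recording` is a tibble with one row per sample and columns
#' `time` (seconds from the first sample at 0), `eda` (skin conductance,
#' microsiemens), `resp` (respiration belt, arbitrary units) and `bvp`
#' (blood volume pulse, sensor units), plus attributes carrying the sampling
#' rate and an annotation table.  Sample `i` covers the half-open interval
#' `[i/fs, (i+1)/fs)`.
#'
#' @param eda,resp,bvp Numeric channel vectors of equal length.
#' @param fs Sampling rate in Hz (default 256).
#' @param annotations Tibble of events; see [annotations()].  May be `NULL`.
#' @param extras Optional named list of auxiliary per-sample vectors kept as
#'   an attribute (e.g. a simulator's ground-truth heart-rate profile).
#'
#' @return A tibble of class `edr_recording`.
#' @export
#' @examples
#' rec <- recording(eda = rep(2, 256), resp = sin(2 * pi * 0.25 * (0:255) / 256),
#'                  bvp = rep(0, 256), fs = 256)
#' duration(rec)
recording <- function(eda, resp, bvp, fs = 256, annotations = NULL,
                      extras = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  n <- length(eda)
  if (n == 0L) abort("zero-length channel: a recording needs at least one sample.")
  if (length(resp) != n || length(bvp) != n) {
    abort("channels `eda`, `resp`, `bvp` must all have the same length.")
  }
  ann <- normalize_annotations(annotations, duration_s = n / fs)
  out <- tibble(
    time = (seq_len(n) - 1) / fs,
    eda = as.numeric(eda),
    resp = as.numeric(resp),
    bvp = as.numeric(bvp)
  )
  attr(out, "fs") <- fs
  attr(out, "annotations") <- ann
  attr(out, "extras") <- extras
  class(out) <- c("edr_recording", class(tibble()))
  out
}

normalize_annotations <- function(annotations, duration_s) {
  kinds <- c("rest", "imagery", "startle", "deep_breath", "spontaneous_edr",
             "noise_condition")
  if (is.null(annotations) || (is.data.frame(annotations) && nrow(annotations) == 0L)) {
    return(tibble(kind = character(), onset_s = numeric(),
                  duration_s = numeric(), truth_label = character(),
                  edr_onset_s = numeric(), amp_uS = numeric(),
                  rise_uS = numeric()))
  }
  ann <- as_tibble(annotations)
  stopifnot(all(c("kind", "onset_s") %in% names(ann)))
  if (is.null(ann[["duration_s"]])) ann$duration_s <- 0
  if (is.null(ann[["edr_onset_s"]])) ann$edr_onset_s <- NA_real_
  if (is.null(ann[["amp_uS"]])) ann$amp_uS <- NA_real_
  if (is.null(ann[["rise_uS"]])) ann$rise_uS <- NA_real_
  if (!all(ann$kind %in% kinds)) {
    abort(paste0("unknown annotation kind(s): ",
                 paste(setdiff(unique(ann$kind), kinds), collapse = ", ")))
  }
  if (any(ann$onset_s < 0 | ann$onset_s > duration_s)) {
    abort("annotation onsets must lie within the recording.")
  }
  # truth follows the event kind: imagery / deep breath are voluntary,
  # startle / spontaneous are involuntary
  ann$truth_label <- dplyr::case_when(
    ann$kind %in% c("imagery", "deep_breath") ~ "voluntary",
    ann$kind %in% c("startle", "spontaneous_edr") ~ "involuntary",
    TRUE ~ "none"
  )
  ann[c("kind", "onset_s", "duration_s", "truth_label", "edr_onset_s",
        "amp_uS", "rise_uS")]
}

#' Recording accessors
#'
#' @param rec An [recording()].
#' @return `sampling_rate()` the rate in Hz; `duration()` the length in
#'   seconds; `annotations()` the annotation tibble (columns `kind`,
#'   `onset_s`, `duration_s`, `truth_label`, `edr_onset_s`, `amp_uS`).
#' @export
sampling_rate <- function(rec) {
  fs <- attr(rec, "fs", exact = TRUE)
  if (is.null(fs)) abort("not an `edr_recording`: missing sampling rate.")
  fs
}

#' @rdname sampling_rate
#' @export
duration <- function(rec) nrow(rec) / sampling_rate(rec)

#' @rdname sampling_rate
#' @export
annotations <- function(rec) {
  attr(rec, "annotations", exact = TRUE) %||%
    normalize_annotations(NULL, 0)
}

#' Read a recording from CSV (+ optional annotation sidecar)
#'
#' Expects a CSV with header `time,eda,resp,bvp` on a uniform time grid.  If
#' `<path minus .csv>.json` exists it is read as the annotation sidecar
#' written by [write_recording()].
#'
#' @param path CSV file path.
#' @param fs_expected Expected sampling rate in Hz; the median time step must
#'   agree within 1%.
#' @return An [recording()].
#' @export
read_recording <- function(path, fs_expected = 256) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "eda", "resp", "bvp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("recording file is missing channel column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dt <- diff(df$time)
  if (length(dt) > 0L) {
    if (abs(median(dt) - 1 / fs_expected) > 0.01 / fs_expected ||
        max(abs(dt - median(dt))) > 0.01 / fs_expected) {
      abort(paste0("time stamps are not uniform at ", fs_expected, " Hz."))
    }
  }
  side <- sidecar_path(path)
  ann <- NULL
  if (file.exists(side)) {
    ann_raw <- jsonlite::fromJSON(side)
    if (length(ann_raw) > 0L) ann <- as_tibble(ann_raw)
  }
  recording(df$eda, df$resp, df$bvp, fs = fs_expected, annotations = ann)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a recording to CSV (+ annotation sidecar)
#'
#' Channels go to `path` with header `time,eda,resp,bvp` at full double
#' precision; annotations, if any, to `<path minus .csv>.json`.
#'
#' @param rec An [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "edr_recording"))
  if (nrow(rec) == 0L) abort("refusing to write a zero-length recording.")
  df <- as.data.frame(rec[c("time", "eda", "resp", "bvp")])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  ann <- annotations(rec)
  if (nrow(ann) > 0L) {
    jsonlite::write_json(ann, sidecar_path(path), digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
print.edr_recording <- function(x, ...) {
  cat(sprintf("<edr_recording: %.1f s at %g Hz, %d annotation(s)>\n",
              duration(x), sampling_rate(x), nrow(annotations(x))))
  NextMethod()
}
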