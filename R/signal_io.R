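# External formats: CSV single-lead signals, WFDB (PhysioNet) records in
# storage format 16, the enrollment repository (versioned JSON holding
# embeddings only, never raw samples), and evaluation report JSON.

REPO_FORMAT_VERSION <- "ecgverify-repo/1"
CSV_VOLTAGE_DIGITS <- 6L  # decimal places written; roundtrip exact to 1e-6 mV

#' Write a record as a two-column CSV
#'
#' Columns `sample_index` (0-based) and `voltage_mV`, voltages written with
#' six decimal places, so a write/read roundtrip reproduces samples to
#' 1e-6 mV.
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  lines <- c("sample_index,voltage_mV",
             sprintf("%d,%.*f", seq_along(record$samples) - 1L,
                     CSV_VOLTAGE_DIGITS, record$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-lead signal from CSV
#'
#' Accepts one- or two-column CSV (voltage only, or index + voltage), with or
#' without a header row; a header is recognized by a non-numeric first line.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz (CSV carries none).
#' @param subject_id Subject label to attach.
#' @return An [ecg_record()] with `source = "csv"`.
#' @export
read_csv_record <- function(path, fs, subject_id = basename(path)) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_invalid("parse error in ", path, ": file is empty")
  fields <- strsplit(lines, ",", fixed = TRUE)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(fields[[1]])))
  data_start <- if (first_numeric) 1L else 2L
  if (data_start > length(lines)) {
    abort_invalid("parse error in ", path, ": header but no data rows")
  }
  n_fields <- lengths(fields[data_start:length(fields)])
  bad <- which(!n_fields %in% c(1L, 2L))
  if (length(bad)) {
    abort_invalid("parse error in ", path, " at line ", bad[1] + data_start - 1L,
                  ": expected 1 or 2 comma-separated fields")
  }
  take_last <- function(f) f[[length(f)]]
  raw <- vapply(fields[data_start:length(fields)], take_last, character(1))
  volts <- suppressWarnings(as.numeric(raw))
  if (anyNA(volts)) {
    abort_invalid("parse error in ", path, " at line ",
                  which(is.na(volts))[1] + data_start - 1L, ": non-numeric voltage")
  }
  ecg_record(volts, fs = fs, subject_id = subject_id, source = "csv")
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort_invalid("malformed WFDB header: ", hea_path)
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- head_fields[1]
  n_sig <- as.integer(head_fields[2])
  fs <- if (length(head_fields) >= 3) as.numeric(head_fields[3]) else 250
  n_samp <- if (length(head_fields) >= 4) as.integer(head_fields[4]) else NA_integer_
  sig <- lapply(lines[2:(1 + n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[3]
    # gain may carry "(baseline)/units", e.g. "200(0)/mV"
    gain <- as.numeric(sub("[(/].*$", "", gain_spec))
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    list(file = f[1], format = sub("x.*$", "", f[2]), gain = gain,
         baseline = baseline, lead = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                                     else paste0("sig", f[1]))
  })
  list(record = record_name, n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

#' Read one lead of a WFDB record
#'
#' Minimal reader for PhysioNet WFDB records in storage format 16
#' (interleaved little-endian 16-bit integers), the format used by the
#' ECG-ID and PTB databases. Samples are converted to physical units as
#' `(adc - baseline) / gain` mV.
#'
#' @param path Path to the `.hea` header file (or record name without
#'   extension).
#' @param lead Lead name as given in the header's signal description
#'   (e.g. `"i"`).
#' @return An [ecg_record()] with `source = "wfdb"`; the subject id is the
#'   record's directory name.
#' @export
read_wfdb <- function(path, lead) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort_invalid("WFDB header not found: ", hea)
  h <- parse_wfdb_header(hea)
  leads <- vapply(h$signals, `[[`, character(1), "lead")
  k <- match(lead, leads)
  if (is.na(k)) {
    abort_invalid("lead not found: '", lead, "'; available leads: ",
                  paste(leads, collapse = ", "))
  }
  fmts <- unique(vapply(h$signals, `[[`, character(1), "format"))
  if (!identical(fmts, "16")) {
    abort_invalid("unsupported WFDB storage format(s): ", paste(fmts, collapse = ", "),
                  " (only format 16 is supported)")
  }
  dat_files <- unique(vapply(h$signals, `[[`, character(1), "file"))
  if (length(dat_files) != 1L) abort_invalid("multi-file WFDB records are not supported")
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat)) abort_invalid("WFDB signal file not found: ", dat)
  n_total <- file.info(dat)$size / 2
  raw <- readBin(dat, "integer", n = n_total, size = 2L, signed = TRUE,
                 endian = "little")
  mat <- matrix(raw, ncol = h$n_sig, byrow = TRUE)
  sig <- h$signals[[k]]
  volts <- (mat[, k] - sig$baseline) / sig$gain
  subj <- basename(dirname(normalizePath(hea)))
  ecg_record(volts, fs = h$fs, subject_id = subj, source = "wfdb")
}

#' Write a multi-lead WFDB record (format 16)
#'
#' Testing and interchange utility: writes a header/signal pair readable by
#' [read_wfdb()]. Voltages are quantized as `round(v * gain) + baseline`.
#'
#' @param signals Named list of numeric vectors (one per lead, equal length),
#'   in mV.
#' @param fs Sampling rate in Hz.
#' @param path Record path without extension.
#' @param gain ADC units per mV (default 200).
#' @param baseline ADC value corresponding to 0 mV (default 0).
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(signals, fs, path, gain = 200, baseline = 0) {
  stopifnot(is.list(signals), length(signals) >= 1L, !is.null(names(signals)))
  n <- unique(lengths(signals))
  if (length(n) != 1L) abort_invalid("all leads must have equal length")
  rec <- basename(path)
  dat_name <- paste0(rec, ".dat")
  hea <- paste0(path, ".hea")
  header <- c(
    sprintf("%s %d %g %d", rec, length(signals), fs, n),
    vapply(names(signals), function(ld) {
      sprintf("%s 16 %g(%d)/mV 16 0 0 0 0 %s", dat_name, gain, as.integer(baseline), ld)
    }, character(1))
  )
  writeLines(header, hea)
  adc <- vapply(signals, function(v) as.integer(round(v * gain) + baseline),
                integer(n))
  con <- file(file.path(dirname(path), dat_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(hea)
}

#' Create an empty enrollment repository
#'
#' The repository stores, per enrolled user, exactly `n_ref` encoder
#' embeddings — never raw signal samples — so new users can be registered
#' without retraining the model.
#'
#' @param n_ref Number of reference templates per user.
#' @param preset Preprocessing preset name the templates were built with.
#' @return An object of class `template_repository`.
#' @export
new_repository <- function(n_ref = 3L, preset = "ecgid-like") {
  if (!is_count(n_ref) || n_ref < 1) abort_invalid("n_ref must be a positive integer")
  structure(
    list(format_version = REPO_FORMAT_VERSION, n_ref = as.integer(n_ref),
         embed_dim = NA_integer_, preset = preset, users = list()),
    class = "template_repository"
  )
}

validate_repository <- function(repo) {
  if (!identical(repo$format_version, REPO_FORMAT_VERSION)) {
    abort_invalid("unsupported repository format version: ",
                  repo$format_version, " (expected ", REPO_FORMAT_VERSION, ")")
  }
  dims <- integer(0)
  for (uid in names(repo$users)) {
    emb <- repo$users[[uid]]$embeddings
    if (length(emb) != repo$n_ref) {
      abort_invalid("repository invariant violated: user ", uid, " has ",
                    length(emb), " embeddings, expected ", repo$n_ref)
    }
    dims <- c(dims, vapply(emb, length, integer(1)))
    if (!all(vapply(emb, function(e) all(is.finite(e)), logical(1)))) {
      abort_invalid("repository invariant violated: non-finite embedding for user ", uid)
    }
  }
  if (length(dims) && length(unique(dims)) != 1L) {
    abort_invalid("repository invariant violated: embeddings of differing dimension")
  }
  invisible(repo)
}

#' Save / load an enrollment repository
#'
#' Versioned JSON with embeddings written at 17 significant digits, so
#' 64-bit floats roundtrip bit-exactly. Loading validates the format version
#' and all repository invariants.
#'
#' @param repo A `template_repository`.
#' @param path JSON file path.
#' @return `save_repository` returns `path` invisibly; `load_repository`
#'   returns the repository.
#' @export
save_repository <- function(repo, path) {
  stopifnot(inherits(repo, "template_repository"))
  validate_repository(repo)
  obj <- unclass(repo)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_repository
#' @export
load_repository <- function(path) {
  if (!file.exists(path)) abort_invalid("repository file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  users <- lapply(obj$users, function(u) {
    u$embeddings <- lapply(u$embeddings, function(e) as.numeric(unlist(e)))
    u
  })
  repo <- structure(
    list(format_version = obj$format_version,
         n_ref = as.integer(obj$n_ref),
         embed_dim = if (is.null(obj$embed_dim) || is.na(obj$embed_dim)) NA_integer_
                     else as.integer(obj$embed_dim),
         preset = obj$preset, users = users),
    class = "template_repository"
  )
  validate_repository(repo)
  repo
}

#' @export
print.template_repository <- function(x, ...) {
  cat(sprintf("<template_repository> %d user(s), n_ref=%d, embed_dim=%s, preset=%s\n",
              length(x$users), x$n_ref,
              ifelse(is.na(x$embed_dim), "?", x$embed_dim), x$preset))
  invisible(x)
}
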