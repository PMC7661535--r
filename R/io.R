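#' Raw PPG recording container
#'
#' One subject's 7-column recording: timestamps, red/green/blue light PPG
#' channels and a 3-axis accelerometer, plus the subject's covariate
#' metadata. Only the time and red columns are analyzed downstream; the
#' remaining columns are retained for completeness.
#'
#' @param subject_id character scalar.
#' @param time seconds, monotone non-decreasing.
#' @param red,green,blue PPG intensity vectors, same length as `time`.
#' @param acc_x,acc_y,acc_z accelerometer vectors, same length as `time`.
#' @param meta named list with elements `sex` ("male"/"female"/NA),
#'   `age` (years), `weight` (kg), `height` (cm), `smoking` ("yes"/"no"/NA);
#'   missing elements become `NA`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(subject_id, time, red, green = NULL, blue = NULL,
                          acc_x = NULL, acc_y = NULL, acc_z = NULL,
                          meta = list()) {
  n <- length(time)
  if (n < 2L) stop("recording must have at least 2 samples")
  zero <- rep(0, n)
  if (is.null(green)) green <- zero
  if (is.null(blue)) blue <- zero
  if (is.null(acc_x)) acc_x <- zero
  if (is.null(acc_y)) acc_y <- zero
  if (is.null(acc_z)) acc_z <- zero
  lens <- lengths(list(red, green, blue, acc_x, acc_y, acc_z))
  if (any(lens != n)) stop("all channel vectors must match the length of `time`")
  if (any(diff(time) < 0)) stop("`time` must be monotone non-decreasing")
  meta <- .complete_meta(meta)
  structure(list(subject_id = as.character(subject_id), time = time,
                 red = red, green = green, blue = blue,
                 acc_x = acc_x, acc_y = acc_y, acc_z = acc_z, meta = meta),
            class = "raw_recording")
}

.meta_fields <- c("sex", "age", "weight", "height", "smoking")

.complete_meta <- function(meta) {
  out <- list(sex = NA_character_, age = NA_real_, weight = NA_real_,
              height = NA_real_, smoking = NA_character_)
  for (f in .meta_fields) if (!is.null(meta[[f]]) && !is.na(meta[[f]])) out[[f]] <- meta[[f]]
  if (!is.na(out$sex) && !out$sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female'")
  if (!is.na(out$smoking) && !out$smoking %in% c("yes", "no"))
    stop("smoking must be 'yes' or 'no'")
  if (!is.na(out$age)) {
    out$age <- as.numeric(out$age)
    if (out$age < 18 || out$age > 120) stop("age out of range [18, 120]")
  }
  if (!is.na(out$weight) && (out$weight <- as.numeric(out$weight)) <= 0)
    stop("weight must be positive")
  if (!is.na(out$height) && (out$height <- as.numeric(out$height)) <= 0)
    stop("height must be positive")
  out
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s  n=%d  span=%.1f s  age=%s sex=%s\n",
              x$subject_id, length(x$time),
              x$time[length(x$time)] - x$time[1L],
              format(x$meta$age), format(x$meta$sex)))
  invisible(x)
}

.rec_header <- c("time", "red", "green", "blue", "accX", "accY", "accZ")

#' Read a per-subject recording CSV
#'
#' The dialect is one file per subject: optional leading comment lines
#' `# key: value` carrying the covariates (sex, age, weight, height,
#' smoking), then a CSV with header `time,red,green,blue,accX,accY,accZ`.
#' A sidecar `<id>.meta.csv` (two columns `key,value`) is also honoured if
#' present; in-file comments win on conflict.
#'
#' @param path path to the recording CSV.
#' @return a [raw_recording]; the subject id is the file name without
#'   extension.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty recording file: ", path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  sidecar <- file.path(dirname(path),
                       paste0(sub("\\.csv$", "", basename(path)), ".meta.csv"))
  if (file.exists(sidecar)) {
    sc <- read.csv(sidecar, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("key", "value") %in% names(sc)))
      stop("sidecar metadata must have columns key,value")
    for (i in seq_len(nrow(sc))) meta[[sc$key[i]]] <- sc$value[i]
  }
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L && m[2] %in% .meta_fields) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path)
  df <- read.csv(text = paste(body, collapse = "\n"), header = TRUE,
                 stringsAsFactors = FALSE)
  missing_cols <- setdiff(.rec_header, names(df))
  if (length(missing_cols) > 0L)
    stop("malformed recording ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  raw_recording(subject_id = sub("\\.csv$", "", basename(path)),
                time = df$time, red = df$red, green = df$green, blue = df$blue,
                acc_x = df$accX, acc_y = df$accY, acc_z = df$accZ, meta = meta)
}

#' Write a recording in the per-subject CSV dialect
#'
#' Inverse of [read_recording]: covariates as `# key: value` comment lines,
#' then the 7-column CSV body.
#'
#' @param rec a [raw_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in .meta_fields) {
    v <- rec$meta[[f]]
    if (!is.na(v)) writeLines(sprintf("# %s: %s", f, format(v, digits = 15)), con)
  }
  df <- data.frame(time = rec$time, red = rec$red, green = rec$green,
                   blue = rec$blue, accX = rec$acc_x, accY = rec$acc_y,
                   accZ = rec$acc_z)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on one recording
#'
#' Preprocess, detect peaks, score quality and (when the quality gate
#' passes) extract the 38-feature vector.
#'
#' @param rec a [raw_recording].
#' @param q_threshold quality threshold; records with Q >= threshold fail.
#' @return list with elements `signal`, `peaks`, `quality`, and `features`
#'   (named numeric of length 38, or `NULL` with `failure` naming the
#'   reason: "quality" or the missing feature family).
#' @export
process_recording <- function(rec, q_threshold = 0.01) {
  sig <- preprocess_recording(rec)
  pk <- detect_peaks(sig)
  qu <- quality_score(sig, pk, threshold = q_threshold)
  out <- list(signal = sig, peaks = pk, quality = qu, features = NULL,
              failure = NULL)
  if (!qu$passed) {
    out$failure <- "quality"
    return(out)
  }
  feats <- tryCatch(extract_features(sig, pk), error = function(e) e)
  if (inherits(feats, "error")) {
    out$failure <- conditionMessage(feats)
  } else {
    out$features <- feats
  }
  out
}

#' Assemble a cohort feature table from recording files
#'
#' Runs preprocess -> peak detection -> quality -> feature extraction for
#' every file, keeps subjects with complete covariate metadata and quality
#' score Q below the threshold, and logs one exclusion reason per dropped
#' subject ("incomplete metadata", "quality", or the failing feature
#' family).
#'
#' @param paths character vector of recording CSV paths.
#' @param q_threshold quality threshold (> 0), default 0.01.
#' @return list with `cohort` (data.frame: subject_id, 38 features, sex,
#'   weight, height, smoking, age, label) and `exclusions` (data.frame:
#'   subject_id, reason).
#' @export
assemble_cohort <- function(paths, q_threshold = 0.01) {
  if (q_threshold <= 0) stop("q_threshold must be > 0")
  rows <- list()
  excl <- list()
  for (p in paths) {
    rec <- read_recording(p)
    meta <- rec$meta
    if (anyNA(unlist(meta, use.names = FALSE))) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = rec$subject_id,
                                              reason = "incomplete metadata")
      next
    }
    res <- process_recording(rec, q_threshold)
    if (is.null(res$features)) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = rec$subject_id,
                                              reason = res$failure)
      next
    }
    rows[[length(rows) + 1L]] <- cohort_row(rec$subject_id, res$features, meta)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), reason = character(0))
  if (length(rows) == 0L) stop("empty cohort: no subject survived assembly")
  list(cohort = do.call(rbind, rows), exclusions = exclusions)
}

# one feature-table row: id + 38 features + 4 covariates + age + label
cohort_row <- function(subject_id, features, meta) {
  stopifnot(length(features) == 38L)
  df <- data.frame(subject_id = subject_id, as.list(features),
                   check.names = FALSE)
  df$sex <- meta$sex
  df$weight <- meta$weight
  df$height <- meta$height
  df$smoking <- meta$smoking
  df$age <- meta$age
  df$label <- dichotomize_age(meta$age)
  df
}

#' Write a cohort feature table to CSV
#'
#' One row per subject: subject_id, the 38 PPG features, the four
#' covariates, age and the HVA label (45 columns). Round-trips losslessly
#' through [read_feature_table].
#'
#' @param cohort the `cohort` data.frame from [assemble_cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(cohort, path) {
  if (is.null(cohort) || nrow(cohort) == 0L) stop("empty cohort")
  expected <- c("subject_id", ppg_feature_names(),
                "sex", "weight", "height", "smoking", "age", "label")
  if (!identical(names(cohort), expected))
    stop("cohort columns do not match the feature-table schema")
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort feature table
#' @param path CSV written by [write_feature_table].
#' @return the cohort data.frame.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("subject_id", ppg_feature_names(),
                "sex", "weight", "height", "smoking", "age", "label")
  if (!identical(names(df), expected))
    stop("file is not a ppgage feature table")
  df$subject_id <- as.character(df$subject_id)
  df
}
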