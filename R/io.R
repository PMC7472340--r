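DATASET_COLUMNS <- c("experiment_id", "signal_type", "concentration_kPa",
                     "replicate", "value", "subset")

#' Write a simulated or measured replicate table to CSV
#'
#' One fixed CSV dialect (comma separated, dot decimal, header required)
#' with columns `experiment_id, signal_type, concentration_kPa, replicate,
#' value, subset`. Units are fixed by the column/signal-type names and are
#' never configurable. Values are written with 12 significant digits so
#' that a write/read round trip preserves them to that precision.
#'
#' @param x a `sim_experiment`, or a data frame already in the schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(x, path) {
  df <- if (inherits(x, "sim_experiment")) x$replicates else x
  if (!is.data.frame(df) || !all(DATASET_COLUMNS %in% names(df)))
    stop("dataset must have columns: ", paste(DATASET_COLUMNS, collapse = ", "))
  df <- df[, DATASET_COLUMNS]
  df$value <- formatC(df$value, digits = 12, format = "g")
  df$concentration_kPa <- formatC(df$concentration_kPa, digits = 12, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicate dataset CSV
#'
#' Validates the fixed schema (see [save_dataset()]), then groups the
#' replicates by experiment and signal type, averaging the
#' calibration-subset replicates per concentration into
#' [calibration_dataset()] objects.
#'
#' @param path CSV path.
#' @return List with `replicates` (the validated data frame) and `cal`
#'   (nested list: experiment id, then signal type, of calibration
#'   datasets).
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DATASET_COLUMNS, names(df))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!df$signal_type %in% SIGNAL_TYPES)
  if (length(bad))
    stop("unknown signal_type '", df$signal_type[bad[1]], "' at line ",
         line[bad[1]])
  bad <- which(!is.finite(df$concentration_kPa) | df$concentration_kPa < 0)
  if (length(bad))
    stop("negative or non-numeric concentration at line ", line[bad[1]])
  bad <- which(!df$subset %in% c("cal", "eval"))
  if (length(bad))
    stop("subset must be 'cal' or 'eval' at line ", line[bad[1]])
  key <- paste(df$experiment_id, df$signal_type, df$concentration_kPa,
               df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (experiment, signal, concentration, replicate) key ",
         "at line ", line[which(duplicated(key))[1]])
  cal <- lapply(split(df, df$experiment_id), function(de) {
    out <- lapply(split(de, de$signal_type), function(ds_df) {
      d <- ds_df[ds_df$subset == "cal", ]
      if (!nrow(d)) return(NULL)
      mu <- tapply(d$value, d$concentration_kPa, mean)
      sdv <- tapply(d$value, d$concentration_kPa, stats::sd)
      nn <- tapply(d$value, d$concentration_kPa, length)
      concs <- as.numeric(names(mu))
      o <- order(concs)
      calibration_dataset(concs[o], as.numeric(mu)[o], as.numeric(sdv)[o],
                          as.numeric(nn)[o],
                          signal_type = ds_df$signal_type[1])
    })
    out[!vapply(out, is.null, logical(1))]
  })
  list(replicates = df, cal = cal)
}

#' Serialise a calibration model to a flat text record
#'
#' Writes the model type, parameter names and values (17 significant
#' digits, lossless for doubles), and for PE models the declared signal
#' range, as `key: value` lines, so a fit is exactly reproducible across
#' runs. [read_cal_model()] restores the model.
#'
#' @param model a `cal_model`.
#' @param path output text path.
#' @return `path`, invisibly.
#' @export
write_cal_model <- function(model, path) {
  stopifnot(inherits(model, "cal_model"))
  num <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = " ")
  lines <- c(paste0("type: ", class(model)[1]))
  if (inherits(model, "pe_model")) {
    lines <- c(lines,
               paste0("coeffs: ", num(model$coeffs)),
               paste0("alpha: ", num(model$alpha)),
               paste0("alpha_free: ", model$alpha_free),
               paste0("signal_range: ", num(model$signal_range)))
  } else {
    for (nm in setdiff(names(model), "degree"))
      lines <- c(lines, paste0(nm, ": ", num(model[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Restore a calibration model written by [write_cal_model()]
#' @param path text path.
#' @return A `cal_model`.
#' @export
read_cal_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  rec <- stats::setNames(lapply(kv, function(p) p[2]),
                         vapply(kv, `[[`, character(1), 1))
  num <- function(key) as.numeric(strsplit(rec[[key]], "\\s+")[[1]])
  switch(rec$type,
    sv_model = sv_model(num("phi0"), num("k")),
    lehrer_model = lehrer_model(num("phi0"), num("k"), num("x")),
    demas_model = demas_model(num("phi0"), num("x"), num("k1"), num("k2")),
    pe_model = pe_model(num("coeffs"), num("alpha"),
                        signal_range = num("signal_range"),
                        alpha_free = identical(rec$alpha_free, "TRUE")),
    stop("unknown model type: ", rec$type))
}
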