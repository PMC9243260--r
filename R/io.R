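#' Read a bivariate time series from a delimited text file
#'
#' Accepts comma- or tab-delimited files (the delimiter is sniffed from the
#' first data line), with or without a single header row (detected by
#' whether the first row parses as numbers). Two channels are selected by
#' name or by column index; by default the first two numeric columns are
#' used. Rows containing missing or non-numeric values are an error that
#' reports the offending row numbers.
#'
#' @param path file path.
#' @param columns length-2 vector of column names or indices, or NULL.
#' @param dt sampling interval attached to the result.
#' @return a bivariate \code{\link{multivariate_signal}}.
#' @export
read_timeseries <- function(path, columns = NULL, dt = 1) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("nacd_usage_error", "nacd_error", "error", "condition")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(errorCondition("input file has fewer than 2 non-empty lines",
                        class = c("nacd_parse_error", "nacd_data_error", "nacd_error", "error", "condition")))
  }
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) >=
             lengths(regmatches(lines[1], gregexpr(",", lines[1])))) "\t" else ","
  first_fields <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_fields))))
  df <- utils::read.table(text = lines, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (is.null(columns)) {
    num <- which(vapply(df, is.numeric, logical(1)))
    if (length(num) < 2L) {
      # columns that failed numeric parsing are still candidates to report
      stop(errorCondition("fewer than 2 numeric columns in input",
                          class = c("nacd_parse_error", "nacd_data_error", "nacd_error", "error", "condition")))
    }
    columns <- num[1:2]
  }
  pick <- function(sel) {
    if (is.character(sel) && grepl("^[0-9]+$", sel)) sel <- as.integer(sel)
    if (is.character(sel)) {
      if (!sel %in% names(df)) {
        stop(errorCondition(sprintf("column '%s' not found (have: %s)", sel,
                                    paste(names(df), collapse = ", ")),
                            class = c("nacd_usage_error", "nacd_error", "error", "condition")))
      }
      df[[sel]]
    } else df[[as.integer(sel)]]
  }
  ch1 <- pick(columns[[1]])
  ch2 <- pick(columns[[2]])
  ch1n <- suppressWarnings(as.numeric(ch1))
  ch2n <- suppressWarnings(as.numeric(ch2))
  bad <- which(!is.finite(ch1n) | !is.finite(ch2n))
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("missing or non-numeric values in data row(s): %s",
              paste(bad, collapse = ", ")),
      class = c("nacd_parse_error", "nacd_data_error", "nacd_error", "error", "condition")))
  }
  if (length(ch1n) < 8L) {
    stop(errorCondition(sprintf("only %d usable rows (need >= 8)", length(ch1n)),
                        class = c("nacd_too_short", "nacd_data_error", "nacd_error", "error", "condition")))
  }
  nm <- if (is.character(columns)) as.character(columns) else c("x", "y")
  multivariate_signal(cbind(ch1n, ch2n), dt = dt, channel_names = nm)
}

#' Write a CSV copy of a multichannel signal
#' @param signal a \code{\link{multivariate_signal}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(signal, path) {
  df <- as.data.frame(signal$values)
  if (is.null(colnames(signal$values))) names(df) <- c("x", "y")[seq_len(ncol(df))]
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
         character(1))
}

#' Write the result files of a causal-decomposition run
#'
#' Writes four plain-text files into \code{outdir}:
#' \code{causal_matrix.tsv} (tab-separated, columns \code{rcs_xy rcs_yx
#' acs_xy acs_yx}: relative strengths first, absolute strengths last),
#' \code{peakmatrix.tsv} (per-IMF frequency/phase summary, sorted report in
#' the same file order as the summary), \code{selection.json} (ICC set,
#' main ICC, selection mode) and \code{run_log.txt} (full configuration,
#' seed and per-repetition IMF counts, so the ensemble trimming is
#' auditable). Reruns with the same configuration produce byte-identical
#' files.
#'
#' @param strengths a \code{\link{causal_strengths}}.
#' @param summary a \code{\link{pl_series}} result.
#' @param selection an \code{\link{icc_selection}}.
#' @param outdir output directory (created if needed).
#' @param config optional \code{\link{noise_config}} echoed into the log.
#' @return character vector (the manifest): the four file paths written.
#' @export
write_outputs <- function(strengths, summary, selection, outdir,
                          config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    stop(errorCondition(sprintf("cannot create output directory: %s", outdir),
                        class = c("nacd_io_error", "nacd_error", "error", "condition")))
  }
  f_causal <- file.path(outdir, "causal_matrix.tsv")
  f_peak <- file.path(outdir, "peakmatrix.tsv")
  f_sel <- file.path(outdir, "selection.json")
  f_log <- file.path(outdir, "run_log.txt")

  writeLines(c(paste(c("rcs_xy", "rcs_yx", "acs_xy", "acs_yx"), collapse = "\t"),
               paste(format_num(c(strengths$rcs_xy, strengths$rcs_yx,
                                  strengths$acs_xy, strengths$acs_yx)),
                     collapse = "\t")),
             f_causal)

  pm <- data.frame(imf_index = summary$imf_index,
                   av_fre1 = format_num(summary$av_fre1),
                   av_fre2 = format_num(summary$av_fre2),
                   difference = format_num(summary$difference))
  utils::write.table(pm, f_peak, sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(list(icc_indices = selection$icc_indices,
                            main_index = selection$main_index,
                            selection_mode = selection$selection_mode),
                       f_sel, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c("nacd run log",
                 sprintf("rcs_xy=%s rcs_yx=%s acs_xy=%s acs_yx=%s",
                         format_num(strengths$rcs_xy), format_num(strengths$rcs_yx),
                         format_num(strengths$acs_xy), format_num(strengths$acs_yx)),
                 sprintf("negligibility=%s", format_num(strengths$negligibility)))
  if (!is.null(config)) {
    log_lines <- c(log_lines,
                   sprintf("level_noise=%s", format_num(config$level_noise)),
                   sprintf("noise_channel_num=%d", config$noise_channel_num),
                   sprintf("en_num=%d", config$en_num),
                   sprintf("seed=%d", config$seed))
  }
  if (!is.null(strengths$diagnostics$ensemble)) {
    log_lines <- c(log_lines,
                   sprintf("rep_imf_counts=%s",
                           paste(strengths$diagnostics$ensemble$rep_imf_counts,
                                 collapse = ",")))
  }
  writeLines(log_lines, f_log)
  c(f_causal, f_peak, f_sel, f_log)
}

#' Run configuration for the end-to-end pipeline
#'
#' Flat bundle of everything a scripted run needs; serializable to JSON or
#' \code{key=value} text and parsed back without loss, so a run can be
#' reproduced from its config file alone.
#'
#' @param input path of the input series (may be NA for in-memory runs).
#' @param columns length-2 column selector or NULL.
#' @param dt sampling interval.
#' @param level_noise,noise_channel_num,en_num,seed see
#'   \code{\link{noise_config}}.
#' @param freq_ratio_max,phase_diff_max,negligibility see
#'   \code{\link{run_causal_decomposition}}.
#' @param icc_override optional integer vector of ICC indices.
#' @param icc_main optional main ICC index.
#' @param outdir output directory.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(input = NA_character_, columns = NULL, dt = 1,
                       level_noise = 0.001, noise_channel_num = 3L,
                       en_num = 5L, seed = NA_integer_,
                       freq_ratio_max = 2, phase_diff_max = pi / 2,
                       negligibility = 0.05, icc_override = NULL,
                       icc_main = NULL, outdir = "nacd_out") {
  if (!is.null(columns)) columns <- as.character(columns)
  structure(list(input = input, columns = columns, dt = dt,
                 level_noise = level_noise,
                 noise_channel_num = as.integer(noise_channel_num),
                 en_num = as.integer(en_num),
                 seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
                 freq_ratio_max = freq_ratio_max,
                 phase_diff_max = phase_diff_max,
                 negligibility = negligibility,
                 icc_override = if (is.null(icc_override)) NULL else
                   as.integer(icc_override),
                 icc_main = if (is.null(icc_main)) NULL else
                   as.integer(icc_main),
                 outdir = outdir),
            class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' @param config a \code{\link{run_config}}.
#' @param path file to write / read.
#' @param format \code{"json"} or \code{"keyvalue"} (sniffed on parse).
#' @return \code{serialize_config}: \code{path} invisibly;
#'   \code{parse_config}: a \code{run_config}.
#' @export
serialize_config <- function(config, path, format = c("json", "keyvalue")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    enc <- function(v) {
      if (is.null(v)) return("")
      if (is.character(v)) paste(v, collapse = ",")
      else paste(vapply(v, function(x) sprintf("%.17g", as.numeric(x)),
                        character(1)), collapse = ",")
    }
    writeLines(sprintf("%s=%s", names(config),
                       vapply(config, enc, character(1))), path)
  }
  invisible(path)
}

#' @rdname serialize_config
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("nacd_usage_error", "nacd_error", "error", "condition")))
  }
  txt <- readLines(path, warn = FALSE)
  lst <- if (any(grepl("^\\s*\\{", txt))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    kv <- strsplit(txt[nzchar(txt)], "=", fixed = TRUE)
    out <- stats::setNames(
      lapply(kv, function(p) if (length(p) < 2L || !nzchar(p[2])) NULL else
        strsplit(p[2], ",", fixed = TRUE)[[1]]),
      vapply(kv, `[`, character(1), 1))
    out
  }
  num <- function(v) if (is.null(v) || (length(v) == 1 && is.na(v))) NA_real_ else
    suppressWarnings(as.numeric(v))
  chr <- function(v) {
    if (is.null(v) || length(v) == 0) return(NA_character_)
    v <- as.character(v)[1]
    if (identical(v, "NA")) NA_character_ else v
  }
  seed <- lst$seed
  run_config(input = chr(lst$input), columns = lst$columns,
             dt = num(lst$dt),
             level_noise = num(lst$level_noise),
             noise_channel_num = num(lst$noise_channel_num),
             en_num = num(lst$en_num),
             seed = if (is.null(seed) || is.na(suppressWarnings(as.integer(seed[1]))))
               NA_integer_ else as.integer(seed[1]),
             freq_ratio_max = num(lst$freq_ratio_max),
             phase_diff_max = num(lst$phase_diff_max),
             negligibility = num(lst$negligibility),
             icc_override = if (is.null(lst$icc_override)) NULL else
               as.integer(lst$icc_override),
             icc_main = if (is.null(lst$icc_main)) NULL else
               as.integer(lst$icc_main),
             outdir = chr(lst$outdir))
}
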