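#' Read a transition curve from CSV
#'
#' Expects a header with at least `conc_M` and `signal` columns; optional
#' `signal_kind` and `sample` columns are honoured. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A `denaturation_curve`.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("conc_M", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # +1 header line -> file line numbers
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$conc_M))) |
                 !is.finite(suppressWarnings(as.numeric(df$signal))))
  if (length(bad)) {
    stop("non-numeric values in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(df$conc_M))
  if (length(dup)) {
    stop("duplicate concentration ", df$conc_M[dup[1]], " in ", path,
         " at line ", dup[1] + 1L, call. = FALSE)
  }
  kind <- if ("signal_kind" %in% names(df)) df$signal_kind[1] else "generic"
  sid <- if ("sample" %in% names(df)) df$sample[1] else
    sub("\\.csv$", "", basename(path))
  denaturation_curve(as.numeric(df$conc_M), as.numeric(df$signal),
                     signal_kind = kind, sample_id = sid)
}

#' Write a transition curve to CSV
#'
#' Columns `conc_M,signal,signal_kind,sample`; round-trips through
#' [read_curve_csv()] losslessly (values written at full precision).
#'
#' @param curve A `denaturation_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "denaturation_curve"))
  df <- as.data.frame(curve)
  df$conc_M <- format(df$conc_M, digits = 17, trim = TRUE, scientific = FALSE)
  df$signal <- format(df$signal, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an emission spectrum from CSV
#'
#' Expects columns `wavelength_nm,intensity` and header comment lines
#' `# conc_M=<x>` and `# sample=<id>` carrying the sample metadata.
#'
#' @param path CSV file path.
#' @param window Allowed wavelength window passed to [emission_spectrum()].
#' @return An `emission_spectrum`.
#' @export
read_spectrum_csv <- function(path, window = c(300, 450)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1]))
  }
  conc <- as.numeric(get_meta("conc_M"))
  sid <- get_meta("sample")
  if (!is.finite(conc)) {
    stop("missing '# conc_M=' header comment in ", path, call. = FALSE)
  }
  if (is.na(sid)) sid <- sub("\\.csv$", "", basename(path))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  emission_spectrum(df$wavelength_nm, df$intensity, denaturant_conc = conc,
                    sample_id = sid, window = window)
}

#' Write an emission spectrum to CSV
#'
#' @param s An `emission_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "emission_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# conc_M=%s",
                       format(s$denaturant_conc, digits = 17)),
               sprintf("# sample=%s", s$sample_id),
               "wavelength_nm,intensity"), con)
  writeLines(paste(format(s$wavelengths, digits = 17, trim = TRUE),
                   format(s$intensities, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a predictor ddG table
#'
#' Accepts a two-column TSV with header `variant<TAB>ddG_kcal_mol`, or a
#' JSON object mapping variant labels to ddG values.
#'
#' @param path TSV or JSON file path.
#' @return Named numeric vector: variant -> ddG (kcal/mol).
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(m) == 0L) stop("empty prediction table: ", path, call. = FALSE)
    vals <- unlist(m)
    if (!is.numeric(vals) || is.null(names(vals))) {
      stop("JSON prediction table must map variant -> number", call. = FALSE)
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("variant", "ddG_kcal_mol")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(df) == 0L) stop("empty prediction table: ", path, call. = FALSE)
    if (any(!is.finite(suppressWarnings(as.numeric(df$ddG_kcal_mol))))) {
      stop("non-numeric ddG values in ", path, call. = FALSE)
    }
    vals <- stats::setNames(as.numeric(df$ddG_kcal_mol), df$variant)
  }
  if (anyDuplicated(names(vals))) {
    stop("duplicate variants in prediction table: ",
         paste(unique(names(vals)[duplicated(names(vals))]), collapse = ", "),
         call. = FALSE)
  }
  vals
}

#' Write a stability table as TSV
#'
#' Human-readable mirror of the per-variant thermodynamics: variant, dG_NI
#' (+se), dG_IU (+se), dG_NU, ddG_NU, m_NI (+se), m_IU (+se), source.
#'
#' @param table A `stability_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(table, path) {
  stopifnot(inherits(table, "stability_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stability table as JSON
#'
#' @param table A `stability_table`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(table, path) {
  stopifnot(inherits(table, "stability_table"))
  jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
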