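# Readers/writers for the pipeline's delimited-text interfaces:
# per-channel plate matrices (CSV, 16 rows A-P x 24 columns), rack
# manifests (CSV) and screen reports (TSV).

#' Read one measurement channel of a plate
#'
#' Accepts either the canonical matrix form (16 data rows labelled A-P,
#' header `row,1,...,24`) or a long-form table with columns `well,value`.
#' Both forms yield identical results.
#'
#' @param path file to read.
#' @return data.frame with columns `well`, `value`, one row per well in
#'   row-major plate order.  In long form, wells absent from the file are
#'   returned with `NA` and a warning.
#' @export
read_plate_matrix <- function(path) {
  header <- gsub("\"", "", strsplit(readLines(path, n = 1L), ",")[[1]])
  if (length(header) == 2L && tolower(trimws(header[1])) == "well") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    wl <- parse_well(tab$well)
    if (anyDuplicated(wl$well)) {
      stop("duplicate well entries in ", path)
    }
    if (!is.numeric(tab$value)) {
      stop("non-numeric values in ", path)
    }
    all_wells <- plate_wells()
    value <- rep(NA_real_, length(all_wells))
    value[match(wl$well, all_wells)] <- tab$value
    if (anyNA(value)) {
      warning(sum(is.na(value)), " well(s) missing from ", path)
    }
    return(data.frame(well = all_wells, value = value,
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) != PLATE_ROWS || ncol(tab) != PLATE_COLS + 1L) {
    stop("plate matrix in ", path, " must be ", PLATE_ROWS, " rows x ",
         PLATE_COLS, " columns plus row labels, got ",
         nrow(tab), " x ", ncol(tab) - 1L)
  }
  row_labels <- toupper(trimws(as.character(tab[[1]])))
  if (!identical(row_labels, LETTERS[seq_len(PLATE_ROWS)])) {
    stop("plate matrix row labels must be A-P in order")
  }
  vals <- as.matrix(tab[, -1L])
  if (!is.numeric(vals)) {
    stop("non-numeric cells in plate matrix ", path)
  }
  data.frame(well = plate_wells(),
             value = as.vector(t(vals)),
             stringsAsFactors = FALSE)
}

#' Write one measurement channel as a canonical plate matrix
#'
#' @param values named numeric vector (names = well labels) or a
#'   data.frame with columns `well`, `value`; all 384 wells required.
#' @param path file to write (CSV).
#' @export
write_plate_matrix <- function(values, path) {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$well
    values <- v
  }
  all_wells <- plate_wells()
  idx <- match(all_wells, toupper(names(values)))
  if (anyNA(idx)) {
    stop("values must cover all ", length(all_wells), " wells")
  }
  m <- matrix(as.numeric(values[idx]), nrow = PLATE_ROWS,
              ncol = PLATE_COLS, byrow = TRUE)
  tab <- data.frame(row = LETTERS[seq_len(PLATE_ROWS)],
                    format_full(m), check.names = FALSE)
  names(tab) <- c("row", as.character(seq_len(PLATE_COLS)))
  utils::write.table(tab, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# full-precision decimal rendering so that write -> read is the identity
format_full <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    formatC(v, digits = 17, format = "g")
  }, character(1))
  if (is.matrix(x)) {
    out <- matrix(out, nrow = nrow(x))
    colnames(out) <- colnames(x)
  }
  out
}

#' Read a rack manifest
#'
#' Expects a CSV with header
#' `compound_id,rack_position,role,stock_concentration_mM`; the
#' standard rack carries 93 test compounds plus one positive (tZ), one
#' negative (antagonist) and one neutral (DMSO) control, barcoded, at a
#' 5 mM stock in DMSO.
#'
#' @param path CSV file.
#' @return validated rack data.frame (see [validate_rack()]).
#' @export
read_rack_manifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"stock_concentration_mm" %in% names(tab)) {
    tab$stock_concentration_mm <- NA_real_
  }
  rack <- data.frame(
    compound_id = as.character(tab$compound_id),
    rack_position = tab$rack_position,
    role = tab$role,
    stock_concentration_mM = as.numeric(tab$stock_concentration_mm),
    stringsAsFactors = FALSE
  )
  validate_rack(rack)
}

#' Write a rack manifest
#'
#' @param rack rack data.frame.
#' @param path CSV file to write.
#' @export
write_rack_manifest <- function(rack, path) {
  rack <- validate_rack(rack)
  utils::write.csv(rack, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

REPORT_COLUMNS <- c("compound_id", "mean_ratio", "sd_ratio", "n",
                    "t_statistic", "p_value", "significant", "category",
                    "flags")

#' Write a per-compound screen report
#'
#' Tab-delimited, one row per compound, columns `compound_id`,
#' `mean_ratio`, `sd_ratio`, `n`, `t_statistic`, `p_value`, `significant`,
#' `category`, `flags` (semicolon-joined flag names, empty if none).
#' Numeric columns are written at full double precision so a read-back
#' reproduces the values exactly.
#'
#' @param results data.frame carrying at least the report columns
#'   (e.g. the `results` element of [run_screen()]).
#' @param path TSV file to write.
#' @export
write_screen_report <- function(results, path) {
  if (nrow(results) == 0L) {
    out <- results[REPORT_COLUMNS[REPORT_COLUMNS %in% names(results)]]
    if (!all(REPORT_COLUMNS %in% names(out))) {
      out <- data.frame(matrix(ncol = length(REPORT_COLUMNS), nrow = 0,
                               dimnames = list(NULL, REPORT_COLUMNS)))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  missing <- setdiff(REPORT_COLUMNS, names(results))
  if (length(missing)) {
    stop("results lack report column(s): ", paste(missing, collapse = ", "))
  }
  out <- results[REPORT_COLUMNS]
  for (col in c("mean_ratio", "sd_ratio", "t_statistic", "p_value")) {
    out[[col]] <- format_full(as.numeric(out[[col]]))
  }
  out$n <- as.integer(out$n)
  out$significant <- ifelse(out$significant, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a screen report written by [write_screen_report()]
#'
#' @param path TSV file.
#' @return data.frame with the report columns at full precision.
#' @export
read_screen_report <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(compound_id = "character",
                                          category = "character",
                                          flags = "character"))
  if (nrow(tab)) {
    tab$significant <- as.logical(tab$significant)
    tab$n <- as.integer(tab$n)
    tab$flags[is.na(tab$flags)] <- ""
  }
  tab[REPORT_COLUMNS]
}

#' Read the two screening-plate channels from a directory
#'
#' Expects files `od600.csv` and `rfu_end.csv` (matrix or long form).
#'
#' @param dir directory containing the channel files.
#' @return data.frame with columns `well`, `od600`, `rfu_end`.
#' @export
read_screening_plate <- function(dir) {
  od <- read_plate_matrix(file.path(dir, "od600.csv"))
  rfu <- read_plate_matrix(file.path(dir, "rfu_end.csv"))
  data.frame(well = od$well, od600 = od$value, rfu_end = rfu$value,
             stringsAsFactors = FALSE)
}

#' Read the two reference-plate channels from a directory
#'
#' Expects files `rfu_pre_spike.csv` and `rfu_post_spike.csv`, the
#' fluorescence before and after the 4-MU spike.
#'
#' @param dir directory containing the channel files.
#' @return data.frame with columns `well`, `rfu_pre_spike`,
#'   `rfu_post_spike`.
#' @export
read_reference_plate <- function(dir) {
  pre <- read_plate_matrix(file.path(dir, "rfu_pre_spike.csv"))
  post <- read_plate_matrix(file.path(dir, "rfu_post_spike.csv"))
  data.frame(well = pre$well, rfu_pre_spike = pre$value,
             rfu_post_spike = post$value, stringsAsFactors = FALSE)
}

#' Concentration after a dilution step
#'
#' Nominal dilution arithmetic: `stock * volume_added / final_volume`,
#' with both volumes in the same unit.  The returned concentration is in
#' the unit of `stock`.  For the assay's internal standard, 2 ul of 1 mM
#' tZ into 40 ml gives 1 mM * 2/40000 = 50 nM.
#'
#' @param stock_concentration stock concentration (any molar unit).
#' @param volume_added volume of stock added (>= 0).
#' @param final_volume nominal final volume (> 0), same unit as
#'   `volume_added`.
#' @return concentration in the unit of `stock_concentration`.
#' @export
dilution_concentration <- function(stock_concentration, volume_added,
                                   final_volume) {
  if (any(final_volume <= 0)) stop("final_volume must be positive")
  if (any(stock_concentration <= 0)) stop("stock_concentration must be positive")
  if (any(volume_added < 0)) stop("volume_added must be non-negative")
  if (any(volume_added > final_volume)) {
    stop("volume_added cannot exceed final_volume")
  }
  stock_concentration * volume_added / final_volume
}
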