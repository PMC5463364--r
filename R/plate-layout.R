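# Plate and rack geometry: 96-well source racks (rows A-H x columns 1-12)
# stamped in quadruplicate onto 384-well assay plates (rows A-P x columns
# 1-24).  Wells are stored as zero-based (row, col) indices internally and
# exposed as plate-reader labels ("A1".."P24").

PLATE_ROWS <- 16L
PLATE_COLS <- 24L
RACK_ROWS <- 8L
RACK_COLS <- 12L

CONTROL_ROLES <- c("positive_control", "negative_control", "neutral_control")
COMPOUND_ROLES <- c("test", CONTROL_ROLES)

#' Well labels of a plate, in row-major order
#'
#' @param n_rows,n_cols plate dimensions (default 384-well: 16 x 24).
#' @return character vector of labels `"A1"`, `"A2"`, ... `"P24"`.
#' @export
plate_wells <- function(n_rows = PLATE_ROWS, n_cols = PLATE_COLS) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

#' Rack positions of a 96-well source rack, in row-major order
#'
#' @return character vector `"A1"` .. `"H12"`.
#' @export
rack_positions <- function() {
  plate_wells(RACK_ROWS, RACK_COLS)
}

#' Parse well labels into row/column indices
#'
#' @param x character vector of labels such as `"A1"` or `"P24"`.
#' @param n_rows,n_cols plate dimensions used for bounds checking.
#' @return data.frame with columns `well`, `row`, `col` (1-based indices).
#' @export
parse_well <- function(x, n_rows = PLATE_ROWS, n_cols = PLATE_COLS) {
  x <- toupper(trimws(as.character(x)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", x)
  if (!all(ok)) {
    stop("malformed well label(s): ", paste(unique(x[!ok]), collapse = ", "))
  }
  row <- match(substr(x, 1L, 1L), LETTERS)
  col <- as.integer(substring(x, 2L))
  bad <- row > n_rows | col < 1L | col > n_cols
  if (any(bad)) {
    stop("well label(s) outside the ", n_rows, "x", n_cols, " plate: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  data.frame(well = x, row = row, col = col, stringsAsFactors = FALSE)
}

well_label <- function(row, col) paste0(LETTERS[row], col)

#' Validate a rack manifest
#'
#' A valid rack holds exactly 96 records (one per source position A1-H12),
#' unique compound ids, unique positions, and exactly one compound for each
#' of the three control roles (positive tZ, negative antagonist, neutral
#' DMSO); all other records carry role `"test"`.
#'
#' @param rack data.frame with columns `compound_id`, `rack_position`,
#'   `role`, `stock_concentration_mM`.
#' @return the rack, invisibly, with normalized role tokens.
#' @export
validate_rack <- function(rack) {
  needed <- c("compound_id", "rack_position", "role")
  missing <- setdiff(needed, names(rack))
  if (length(missing)) {
    stop("rack manifest lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(rack) != RACK_ROWS * RACK_COLS) {
    stop("rack must contain exactly ", RACK_ROWS * RACK_COLS,
         " records, got ", nrow(rack))
  }
  rack$role <- normalize_role(rack$role)
  rack$compound_id <- as.character(rack$compound_id)
  if (anyDuplicated(rack$compound_id)) {
    stop("duplicate compound_id in rack: ",
         paste(unique(rack$compound_id[duplicated(rack$compound_id)]),
               collapse = ", "))
  }
  pos <- parse_well(rack$rack_position, RACK_ROWS, RACK_COLS)
  if (anyDuplicated(pos$well)) {
    stop("duplicate rack_position in rack")
  }
  rack$rack_position <- pos$well
  for (ctrl in CONTROL_ROLES) {
    k <- sum(rack$role == ctrl)
    if (k != 1L) {
      stop("rack must contain exactly one ", ctrl, ", found ", k)
    }
  }
  invisible(rack)
}

normalize_role <- function(role) {
  role <- gsub("[ -]", "_", tolower(trimws(as.character(role))))
  alias <- c(test = "test", compound = "test",
             positive_control = "positive_control", positive = "positive_control",
             negative_control = "negative_control", negative = "negative_control",
             neutral_control = "neutral_control", neutral = "neutral_control",
             dmso = "neutral_control")
  out <- unname(alias[role])
  if (anyNA(out)) {
    stop("unknown role token(s): ",
         paste(unique(role[is.na(out)]), collapse = ", "))
  }
  out
}

#' Stamp a 96-well rack onto a 384-well plate in quadruplicate
#'
#' Every source position receives four technical-replicate wells on the
#' assay plate.  The default `"block2x2"` scheme stamps source well
#' (r, c) onto the 2x2 block of plate rows 2r-1, 2r and columns 2c-1, 2c
#' (so A1 -> A1, A2, B1, B2 and H12 -> O23, O24, P23, P24).  The
#' `"quadrant"` scheme places one replicate in each plate quadrant:
#' (r, c), (r, c+12), (r+8, c), (r+8, c+12).
#'
#' @param rack validated rack manifest (see [validate_rack()]).
#' @param scheme stamping geometry, `"block2x2"` (default) or `"quadrant"`.
#' @return a `plate_layout`: data.frame with one row per assay well
#'   (`compound_id`, `rack_position`, `role`, `well`, `replicate`), 384 rows,
#'   with the scheme stored as an attribute.
#' @export
assign_quadruplicate_layout <- function(rack, scheme = c("block2x2", "quadrant")) {
  scheme <- match.arg(scheme)
  rack <- validate_rack(rack)
  pos <- parse_well(rack$rack_position, RACK_ROWS, RACK_COLS)
  r <- pos$row
  c <- pos$col
  if (scheme == "block2x2") {
    rows <- cbind(2L * r - 1L, 2L * r - 1L, 2L * r, 2L * r)
    cols <- cbind(2L * c - 1L, 2L * c, 2L * c - 1L, 2L * c)
  } else {
    rows <- cbind(r, r, r + RACK_ROWS, r + RACK_ROWS)
    cols <- cbind(c, c + RACK_COLS, c, c + RACK_COLS)
  }
  layout <- data.frame(
    compound_id = rep(rack$compound_id, each = 4L),
    rack_position = rep(rack$rack_position, each = 4L),
    role = rep(rack$role, each = 4L),
    well = well_label(as.vector(t(rows)), as.vector(t(cols))),
    replicate = rep.int(1:4, nrow(rack)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(layout$well) || nrow(layout) != PLATE_ROWS * PLATE_COLS) {
    stop("internal error: stamping scheme did not cover the plate bijectively")
  }
  structure(layout, scheme = scheme, class = c("plate_layout", "data.frame"))
}

#' Recover the source rack position of assay wells
#'
#' Inverts a quadruplicate layout: every assay well maps back to the rack
#' position (and compound) it was stamped from.
#'
#' @param layout a `plate_layout` from [assign_quadruplicate_layout()].
#' @param wells character vector of assay well labels.
#' @return data.frame with `well`, `compound_id`, `rack_position`, `role`.
#' @export
invert_layout <- function(layout, wells = layout$well) {
  idx <- match(toupper(trimws(wells)), layout$well)
  if (anyNA(idx)) {
    stop("well(s) not present in layout: ",
         paste(wells[is.na(idx)], collapse = ", "))
  }
  data.frame(well = layout$well[idx],
             compound_id = layout$compound_id[idx],
             rack_position = layout$rack_position[idx],
             role = layout$role[idx],
             stringsAsFactors = FALSE)
}
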