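#' @keywords internal
"_PACKAGE"

# Canonical column names of the long (one well per row) screen format.
#' Default column-name mapping for long-format screen tables
#'
#' Maps the fields of the data model to column headers in a delimited file.
#' Override individual entries to read files with different headers. `well`
#' holds spreadsheet-style coordinates (`"A01"`, `"AC12"`, ...); alternatively
#' a file may carry explicit integer `row`/`col` columns.
#'
#' @return Named list of column names.
#' @export
default_format_spec <- function() {
  list(plate = "plate", well = "well", row = "row", col = "col",
       reagent_row = "reagent_row", reagent_col = "reagent_col",
       value = "value", biorep = "biorep", techrep = "techrep",
       control = "control")
}

CONTROL_ROLES <- c("none", "positive", "negative")

## spreadsheet-style row labels: A..Z, AA..AZ, ...
row_label <- function(i) {
  stopifnot(all(i >= 1))
  vapply(as.integer(i), function(k) {
    s <- ""
    while (k > 0) {
      r <- (k - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      k <- (k - 1L) %/% 26L
    }
    s
  }, character(1))
}

row_index <- function(lab) {
  vapply(toupper(lab), function(s) {
    ch <- strsplit(s, "")[[1]]
    sum((match(ch, LETTERS)) * 26^(rev(seq_along(ch)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

well_name <- function(row, col) paste0(row_label(row), sprintf("%02d", col))

parse_well <- function(w) {
  m <- regmatches(w, regexec("^([A-Za-z]+)([0-9]+)$", w))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("format error: unparseable well coordinate(s): ",
         paste(utils::head(w[bad], 3), collapse = ", "))
  data.frame(row = row_index(vapply(m, `[`, "", 2L)),
             col = as.integer(vapply(m, `[`, "", 3L)))
}

#' Construct a screen table
#'
#' A `screen_table` ties well-level records (plate, 1-based row/column
#' coordinates, the unordered reagent pair dispensed from the row and column
#' stock plates, the raw readout, and replicate labels) to a reagent registry
#' carrying control annotation.
#'
#' @param wells data.frame with columns `plate`, `row`, `col`, `reagent_row`,
#'   `reagent_col`, `readout`, `bio_rep`, `tech_rep`. `readout` may be `NA`
#'   in a design skeleton but must be positive where present.
#' @param reagents data.frame with columns `id`, `target`, `control_role`
#'   (one of `"none"`, `"positive"`, `"negative"`).
#' @param plate_rows,plate_cols plate geometry (default 384-well, 16 x 24).
#' @return An object of class `screen_table`.
#' @export
screen_table <- function(wells, reagents, plate_rows = 16L, plate_cols = 24L) {
  wells <- as.data.frame(wells)
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  x <- structure(list(wells = wells, reagents = as.data.frame(reagents),
                      plate_rows = as.integer(plate_rows),
                      plate_cols = as.integer(plate_cols)),
                 class = "screen_table")
  validate_screen_table(x)
}

#' Validate a screen table against the data-model invariants
#'
#' Checks column presence, uniqueness of reagent ids and of (plate, row, col)
#' coordinates, positivity of readouts, and that every referenced reagent is
#' registered.
#'
#' @param x a `screen_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_screen_table <- function(x) {
  w <- x$wells
  need <- c("plate", "row", "col", "reagent_row", "reagent_col",
            "readout", "bio_rep", "tech_rep")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("format error: missing well column(s): ", paste(miss, collapse = ", "))
  r <- x$reagents
  if (anyDuplicated(r$id))
    stop("integrity error: duplicated reagent id(s): ",
         paste(unique(r$id[duplicated(r$id)]), collapse = ", "))
  if (any(grepl(":", r$id, fixed = TRUE)))
    stop("value error: reagent ids must not contain ':'")
  if (!all(r$control_role %in% CONTROL_ROLES))
    stop("value error: control_role must be one of ",
         paste(CONTROL_ROLES, collapse = "/"))
  key <- paste(w$plate, w$row, w$col)
  if (anyDuplicated(key))
    stop("integrity error: duplicated well coordinate(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  bad <- !is.na(w$readout) & w$readout <= 0
  if (any(bad))
    stop("value error: non-positive readout at table row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  unk <- setdiff(c(w$reagent_row, w$reagent_col), r$id)
  if (length(unk))
    stop("integrity error: unregistered reagent id(s): ",
         paste(unk, collapse = ", "))
  invisible(x)
}

#' @export
print.screen_table <- function(x, ...) {
  ctrl <- well_is_control(x)
  cat(sprintf(
    "screen_table: %d wells (%d control) on %d plate(s), %d reagents (%d scored)\n",
    nrow(x$wells), sum(ctrl), length(unique(x$wells$plate)),
    nrow(x$reagents), sum(x$reagents$control_role == "none")))
  invisible(x)
}

#' Which wells are controls?
#'
#' A well is a control iff either of its reagents has a control role.
#'
#' @param screen a `screen_table`.
#' @return Logical vector over the rows of `screen$wells`.
#' @export
well_is_control <- function(screen) {
  role <- stats::setNames(screen$reagents$control_role, screen$reagents$id)
  unname(role[screen$wells$reagent_row] != "none" |
           role[screen$wells$reagent_col] != "none")
}

#' Which wells are self-pairs?
#'
#' Self-pairs carry the same reagent from the row and the column stock plate.
#' They are retained through IO but excluded from model fitting by default.
#'
#' @param screen a `screen_table`.
#' @return Logical vector over the rows of `screen$wells`.
#' @export
well_is_self_pair <- function(screen) {
  screen$wells$reagent_row == screen$wells$reagent_col & !well_is_control(screen)
}

#' Canonical unordered pair key
#'
#' @param a,b reagent id vectors.
#' @return Character vector `"i:j"` with `i <= j` lexicographically.
#' @export
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")

#' Ids of the scored (non-control) reagents
#'
#' @param screen a `screen_table`.
#' @return Character vector in registry order.
#' @export
scored_reagents <- function(screen) {
  screen$reagents$id[screen$reagents$control_role == "none"]
}

#' Index the wells of every unordered reagent pair
#'
#' @param screen a validated `screen_table`.
#' @return Named list mapping each unordered pair key (`"i:j"`, `i <= j`) to
#'   the integer row indices of its wells in `screen$wells`. Control wells are
#'   excluded; self-pairs appear under key `"i:i"`.
#' @export
pair_index <- function(screen) {
  keep <- which(!well_is_control(screen))
  w <- screen$wells[keep, , drop = FALSE]
  key <- pair_key(w$reagent_row, w$reagent_col)
  idx <- split(keep, key)
  idx[order(names(idx))]
}

#' Generate a criss-cross plate design
#'
#' Lays out a matrix co-RNAi screen: scored reagents occupy plate rows
#' 1..N (row stock plate) and N reagent columns (column stock plate), so that
#' every unordered pair (i, j), i != j, is measured twice per plate, at
#' (row i, col j) and (row j, col i). Control wells fill designated columns
#' over all used rows. Technical replicate labels combine the plate index
#' within a biological replicate with the symmetric occurrence ("a" when the
#' row reagent precedes the column reagent in registry order), giving
#' `2 * plates_per_biorep` technical replicates per biological replicate.
#'
#' @param reagents character vector of scored reagent ids (or a data.frame
#'   with columns `id`, `target`).
#' @param plates_per_biorep plates per biological replicate (default 5).
#' @param bioreps number of biological replicates (default 2).
#' @param control_columns named list of column indices for control classes,
#'   e.g. `list(positive = 7, negative = 14)`; may be empty.
#' @param include_self_pairs include diagonal wells (same reagent twice)?
#' @param plate_rows,plate_cols plate geometry (default 16 x 24).
#' @return A `screen_table` skeleton with `readout = NA`.
#' @export
generate_crisscross_design <- function(reagents,
                                       plates_per_biorep = 5L,
                                       bioreps = 2L,
                                       control_columns = list(positive = 7L,
                                                              negative = 14L),
                                       include_self_pairs = FALSE,
                                       plate_rows = 16L,
                                       plate_cols = 24L) {
  if (is.data.frame(reagents)) {
    ids <- as.character(reagents$id)
    targets <- if ("target" %in% names(reagents)) reagents$target else ids
  } else {
    ids <- as.character(reagents)
    targets <- ids
  }
  N <- length(ids)
  if (N < 2) stop("layout error: need at least 2 scored reagents")
  if (anyDuplicated(ids)) stop("integrity error: duplicated reagent ids")
  ctrl_cols <- unlist(control_columns, use.names = FALSE)
  if (anyDuplicated(ctrl_cols))
    stop("layout error: control columns must be distinct")
  if (N > plate_rows)
    stop("layout error: ", N, " reagents exceed ", plate_rows, " plate rows")
  free_cols <- setdiff(seq_len(plate_cols), ctrl_cols)
  if (N > length(free_cols))
    stop("layout error: ", N, " reagents exceed ", length(free_cols),
         " non-control plate columns")
  reagent_cols <- free_cols[seq_len(N)]
  col_of <- stats::setNames(reagent_cols, ids)

  ctrl_ids <- character(0)
  ctrl_roles <- character(0)
  ctrl_map <- character(0)     # column -> control reagent id
  for (role in names(control_columns)) {
    if (!role %in% c("positive", "negative"))
      stop("layout error: unknown control class '", role, "'")
    id <- paste0("ctrl_", substr(role, 1, 3))
    ctrl_ids <- c(ctrl_ids, id)
    ctrl_roles <- c(ctrl_roles, role)
    for (cc in control_columns[[role]]) ctrl_map[as.character(cc)] <- id
  }

  one_plate <- function() {
    ri <- rep(seq_len(N), each = N + length(ctrl_cols))
    cols <- c(reagent_cols, ctrl_cols)
    cj <- rep(cols, times = N)
    rr <- ids[ri]
    rc <- ifelse(cj %in% ctrl_cols, ctrl_map[as.character(cj)],
                 ids[match(cj, reagent_cols)])
    occ <- ifelse(cj %in% ctrl_cols, "a",
                  ifelse(match(rr, ids) <= match(rc, ids), "a", "b"))
    d <- data.frame(row = ri, col = cj, reagent_row = rr, reagent_col = rc,
                    occ = occ, stringsAsFactors = FALSE)
    if (!include_self_pairs)
      d <- d[!(d$reagent_row == d$reagent_col & !(d$col %in% ctrl_cols)), ]
    d
  }
  plate <- one_plate()

  wells <- do.call(rbind, lapply(seq_len(bioreps), function(b) {
    do.call(rbind, lapply(seq_len(plates_per_biorep), function(p) {
      data.frame(plate = sprintf("b%d_p%d", b, p),
                 row = plate$row, col = plate$col,
                 reagent_row = plate$reagent_row,
                 reagent_col = plate$reagent_col,
                 readout = NA_real_,
                 bio_rep = sprintf("b%d", b),
                 tech_rep = paste0(p, plate$occ),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(wells) <- NULL
  reg <- data.frame(id = c(ids, ctrl_ids),
                    target = c(targets, rep("", length(ctrl_ids))),
                    control_role = c(rep("none", N), ctrl_roles),
                    stringsAsFactors = FALSE)
  screen_table(wells, reg, plate_rows, plate_cols)
}

#' Read a long-format screen table
#'
#' Reads a tab- or comma-separated table with one well per row. The separator
#' is inferred from the file extension (`.csv` means comma). Rows with missing
#' readouts are dropped and counted in the load report (attribute
#' `"load_report"`). Reagent control roles are inferred from the `control`
#' column: a reagent that appears exclusively in wells of a single control
#' class gets that role.
#'
#' @param path file path.
#' @param format_spec column-name mapping, see [default_format_spec()].
#' @param plate_rows,plate_cols plate geometry; inferred from the data when
#'   `NULL`.
#' @return A validated `screen_table`.
#' @export
read_screen_table <- function(path, format_spec = default_format_spec(),
                              plate_rows = NULL, plate_cols = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  fs <- utils::modifyList(default_format_spec(), format_spec)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  need <- c("plate", "reagent_row", "reagent_col", "value")
  miss <- need[!unlist(fs[need]) %in% names(raw)]
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(unlist(fs[miss]), collapse = ", "))
  has_well <- fs$well %in% names(raw)
  has_rc <- all(c(fs$row, fs$col) %in% names(raw))
  if (!has_well && !has_rc)
    stop("format error: need either a '", fs$well, "' column or '",
         fs$row, "'/'", fs$col, "' columns")
  coords <- if (has_rc) {
    data.frame(row = as.integer(raw[[fs$row]]), col = as.integer(raw[[fs$col]]))
  } else parse_well(as.character(raw[[fs$well]]))

  grab <- function(field, default) {
    if (fs[[field]] %in% names(raw)) as.character(raw[[fs[[field]]]])
    else rep(default, nrow(raw))
  }
  wells <- data.frame(plate = as.character(raw[[fs$plate]]),
                      row = coords$row, col = coords$col,
                      reagent_row = as.character(raw[[fs$reagent_row]]),
                      reagent_col = as.character(raw[[fs$reagent_col]]),
                      readout = as.numeric(raw[[fs$value]]),
                      bio_rep = grab("biorep", "b1"),
                      tech_rep = grab("techrep", "t1"),
                      stringsAsFactors = FALSE)
  control <- grab("control", "none")
  control[control == "" | is.na(control)] <- "none"

  dropped <- is.na(wells$readout)
  wells <- wells[!dropped, , drop = FALSE]
  control <- control[!dropped]
  rownames(wells) <- NULL

  ids <- sort(unique(c(wells$reagent_row, wells$reagent_col)))
  role <- vapply(ids, function(id) {
    lab <- unique(control[wells$reagent_row == id | wells$reagent_col == id])
    if (length(lab) == 1L && lab %in% c("positive", "negative")) lab else "none"
  }, character(1))
  reg <- data.frame(id = ids, target = ids, control_role = unname(role),
                    stringsAsFactors = FALSE)
  if (is.null(plate_rows)) plate_rows <- max(16L, max(wells$row))
  if (is.null(plate_cols)) plate_cols <- max(24L, max(wells$col))
  out <- screen_table(wells, reg, plate_rows, plate_cols)
  attr(out, "load_report") <- list(rows_read = nrow(raw),
                                   rows_dropped_missing = sum(dropped))
  out
}

#' Write a screen table in the long format
#'
#' Inverse of [read_screen_table()]: the written file round-trips
#' field-for-field through the reader.
#'
#' @param screen a `screen_table` (normalized screens also carry a `value`
#'   column, which is written alongside the raw readout).
#' @param path output path; `.csv` selects comma separation.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  w <- screen$wells
  role <- stats::setNames(screen$reagents$control_role, screen$reagents$id)
  ctrl <- ifelse(role[w$reagent_row] != "none", role[w$reagent_row],
                 ifelse(role[w$reagent_col] != "none", role[w$reagent_col],
                        "none"))
  out <- data.frame(plate = w$plate, well = well_name(w$row, w$col),
                    reagent_row = w$reagent_row, reagent_col = w$reagent_col,
                    value = w$readout, biorep = w$bio_rep,
                    techrep = w$tech_rep, control = unname(ctrl),
                    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a screen to a set of plates
#'
#' @param screen a `screen_table` (possibly normalized).
#' @param plates character vector of plate ids to keep.
#' @return The filtered screen, same class.
#' @export
subset_plates <- function(screen, plates) {
  keep <- screen$wells$plate %in% plates
  if (!any(keep)) stop("value error: no wells on plate(s) ",
                       paste(plates, collapse = ", "))
  screen$wells <- screen$wells[keep, , drop = FALSE]
  rownames(screen$wells) <- NULL
  if (!is.null(screen$centers))
    screen$centers <- screen$centers[names(screen$centers) %in% plates]
  screen
}

#' Export the plate layout as per-plate matrices
#'
#' Writes, for each plate, a `plate_rows x plate_cols` text matrix of the
#' pair labels (or values) for visual inspection.
#'
#' @param screen a `screen_table`.
#' @param dir output directory (created if needed).
#' @param what `"pair"` writes reagent-pair labels, `"value"` the readout.
#' @return The directory, invisibly.
#' @export
export_layout <- function(screen, dir, what = c("pair", "value")) {
  what <- match.arg(what)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- screen$wells
  for (p in unique(w$plate)) {
    sub <- w[w$plate == p, ]
    m <- matrix("", screen$plate_rows, screen$plate_cols,
                dimnames = list(row_label(seq_len(screen$plate_rows)),
                                seq_len(screen$plate_cols)))
    fill <- if (what == "pair") pair_key(sub$reagent_row, sub$reagent_col)
            else as.character(sub$readout)
    m[cbind(sub$row, sub$col)] <- fill
    utils::write.table(m, file.path(dir, paste0("layout_", p, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}
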