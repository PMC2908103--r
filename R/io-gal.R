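## Numbers in vendor description tables are printed with spaces inside the
## exponent ("1.47E + 05"); strip whitespace before parsing. Returns NA for
## non-numeric strings without warnings.
.parseDensity <- function(s) {
  suppressWarnings(as.numeric(gsub("[[:space:]]", "", s)))
}

## map a GAL/description Name string to (role, density)
.nameToRole <- function(nm) {
  val <- .parseDensity(nm)
  if (!is.na(val)) {
    if (val == 0) list(role = "blank", density = 0)
    else list(role = "dilution", density = val)
  } else if (grepl("^marker", trimws(nm), ignore.case = TRUE)) {
    list(role = "marker", density = NA_real_)
  } else if (grepl("^buffer", trimws(nm), ignore.case = TRUE)) {
    list(role = "buffer", density = NA_real_)
  } else {
    .scError("scancal_format_error",
             paste0("unrecognised spot Name field: '", nm, "'"))
  }
}

.roleToName <- function(role, density) {
  switch(role,
         dilution = sprintf("%.10E", density),
         blank = "0",
         buffer = "Buffer",
         marker = "Marker")
}

#' Write a slide layout as a GAL (GenePix Array List) file
#'
#' Emits an ATF-container GAL file with one record per spot: Block, Column,
#' Row, Name, ID. Dilution spots carry their nominal density in the Name
#' field (full precision, so the file round-trips through [readGal()]);
#' blanks carry "0", buffer spots "Buffer", markers "Marker"; the ID field
#' carries the dye label. Coordinates are 1-based per GAL convention.
#'
#' @param layout a [SlideLayout-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeGal <- function(layout, path) {
  stopifnot(is(layout, "SlideLayout"))
  cols <- layout@columns
  nrep <- layout@replicatesPerColumn
  if (is.na(nrep)) nrep <- 1L
  recs <- do.call(rbind, lapply(seq_len(nrow(cols)), function(i) {
    data.frame(Block = 1L, Column = cols$series[i], Row = seq_len(nrep),
               Name = .roleToName(cols$role[i], cols$density[i]),
               ID = cols$dye[i], stringsAsFactors = FALSE)
  }))
  header <- c("ATF\t1.0",
              "4\t5",
              "\"Type=GenePix ArrayList V1.0\"",
              "\"BlockCount=1\"",
              "\"BlockType=0\"",
              "\"Supplier=scancal simulated calibration slide\"",
              "Block\tColumn\tRow\tName\tID")
  body <- sprintf("%d\t%d\t%d\t\"%s\"\t\"%s\"",
                  recs$Block, recs$Column, recs$Row, recs$Name, recs$ID)
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a GAL (GenePix Array List) file
#'
#' Parses the ATF header and spot records (via \pkg{limma}'s GAL reader,
#' which tolerates both plain tab-delimited and quoted dialects), validates
#' coordinates, and derives a per-column [SlideLayout-class]: numeric Name
#' fields become nominal densities, "0" blanks, "Buffer"/"Marker" their
#' roles.
#'
#' @param path GAL file path.
#' @return A list with elements `layout` (a [SlideLayout-class]) and
#'   `records` (data.frame of raw spot records: Block, Column, Row, Name,
#'   ID).
#' @export
readGal <- function(path) {
  if (!file.exists(path))
    .scError("scancal_io_error", paste("readGal: no such file:", path))
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 1L || !grepl("^ATF\\b", head2[1]))
    .scError("scancal_format_error", paste0(
      "readGal: ", path, " line 1: not an ATF file (expected 'ATF' token)"))
  if (length(head2) < 2L ||
      !grepl("^[0-9]+\\s+[0-9]+\\s*$", head2[2]))
    .scError("scancal_format_error", paste0(
      "readGal: ", path,
      " line 2: expected '<n header records> <n columns>' counts"))
  recs <- limma::readGAL(path)
  need <- c("Block", "Column", "Row", "Name", "ID")
  miss <- setdiff(need, names(recs))
  if (length(miss))
    .scError("scancal_format_error",
             paste("readGal: missing GAL column(s):",
                   paste(miss, collapse = ", ")))
  key <- paste(recs$Block, recs$Column, recs$Row)
  if (anyDuplicated(key))
    .scError("scancal_validation_error", paste(
      "readGal: duplicated spot coordinates, e.g. block/column/row",
      key[anyDuplicated(key)]))
  recs$Name <- as.character(recs$Name)
  recs$ID <- as.character(recs$ID)

  cols <- sort(unique(recs$Column))
  role <- character(length(cols)); density <- numeric(length(cols))
  dye <- character(length(cols))
  for (i in seq_along(cols)) {
    sub <- recs[recs$Column == cols[i], , drop = FALSE]
    nm <- unique(sub$Name)
    if (length(nm) != 1L)
      .scError("scancal_validation_error", paste0(
        "readGal: column ", cols[i], " mixes Name values: ",
        paste(nm, collapse = ", ")))
    rd <- .nameToRole(nm)
    role[i] <- rd$role; density[i] <- rd$density
    dye[i] <- sub$ID[1]
  }
  layout <- new("SlideLayout",
                columns = data.frame(series = as.integer(cols), role = role,
                                     dye = dye, density = density,
                                     stringsAsFactors = FALSE),
                replicatesPerColumn = as.integer(
                  max(table(recs$Column))))
  list(layout = layout, records = recs[, need])
}

#' Write spot-level observations as an intensity CSV
#'
#' Fixed dialect: header
#' `spot_id,block,column,row,series,channel,pmt_gain,x_nominal,signal,saturated`,
#' UTF-8, "." decimal separator, `x_nominal` left empty for buffer/marker
#' spots. Numeric fields are written at full precision so the file
#' round-trips through [readIntensityTable()] bit-exactly.
#'
#' @param observations spot-level data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeIntensityTable <- function(observations, path) {
  .validateObservations(observations)
  obs <- observations[, .obsColumns]
  num <- function(v) ifelse(is.na(v), "",
                            formatC(v, digits = 17, format = "g"))
  lines <- c(paste(.obsColumns, collapse = ","),
             sprintf("%s,%d,%d,%d,%d,%s,%s,%s,%s,%s",
                     obs$spot_id, obs$block, obs$column, obs$row, obs$series,
                     obs$channel, num(obs$pmt_gain), num(obs$x_nominal),
                     num(obs$signal), tolower(obs$saturated)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a spot-intensity CSV
#'
#' Reads the dialect written by [writeIntensityTable()]. The saturation
#' flag is recomputed against `ceiling` (a signal at or above the ceiling
#' is saturated). `channel`/`pmtGain` overrides replace the file's values,
#' for exports that lack scan metadata.
#'
#' @param path CSV file path.
#' @param ceiling saturation ceiling in counts (default 65535).
#' @param channel,pmtGain optional overrides applied to every row.
#' @return Spot-level data.frame (zero rows for a header-only file).
#' @export
readIntensityTable <- function(path, ceiling = 65535, channel = NULL,
                               pmtGain = NULL) {
  if (!file.exists(path))
    .scError("scancal_io_error",
             paste("readIntensityTable: no such file:", path))
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.obsColumns, names(obs))
  if (length(miss))
    .scError("scancal_format_error", paste0(
      "readIntensityTable: ", path, " is missing required column(s): ",
      paste(miss, collapse = ", ")))
  obs <- obs[, .obsColumns]
  for (cc in c("block", "column", "row", "series"))
    obs[[cc]] <- as.integer(obs[[cc]])
  for (cc in c("pmt_gain", "x_nominal", "signal"))
    obs[[cc]] <- .parseDensity(obs[[cc]])
  if (nrow(obs) == 0L) {
    obs$saturated <- logical(0)
    return(obs)
  }
  bad <- which(is.na(obs$signal) | obs$signal < 0)
  if (length(bad))
    .scError("scancal_validation_error", paste0(
      "readIntensityTable: ", path, " row ", bad[1],
      ": missing or negative signal intensity"))
  if (!is.null(channel)) obs$channel <- channel
  if (!is.null(pmtGain)) obs$pmt_gain <- as.numeric(pmtGain)
  obs$saturated <- obs$signal >= ceiling
  .validateObservations(obs[, .obsColumns])
}

#' Write a manual-style slide description table
#'
#' Two-column CSV `series,density_or_role`, the machine analogue of the
#' vendor manual's description table: dilution columns print their density,
#' blanks "0", and the buffer and marker columns their role names.
#'
#' @param layout a [SlideLayout-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSlideDescription <- function(layout, path) {
  stopifnot(is(layout, "SlideLayout"))
  cols <- layout@columns
  val <- vapply(seq_len(nrow(cols)), function(i)
    .roleToName(cols$role[i], cols$density[i]), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("series,density_or_role",
               sprintf("%d,%s", cols$series, val)), con, sep = "\n")
  invisible(path)
}

#' Read a manual-style slide description table
#'
#' Parses the two-column CSV of [writeSlideDescription()] (or a transcribed
#' vendor manual table). Density strings may contain embedded spaces around
#' the exponent sign ("1.47E + 05") and either "E" or "e"; "Buffer",
#' "Marker" and "0" map to the buffer, marker and blank roles.
#'
#' @param path CSV file path with header `series,density_or_role`.
#' @param dye dye label to record (description tables carry none;
#'   default "Cy3").
#' @return A [SlideLayout-class] (replicates per column unknown, NA).
#' @export
readSlideDescription <- function(path, dye = "Cy3") {
  if (!file.exists(path))
    .scError("scancal_io_error",
             paste("readSlideDescription: no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("series", "density_or_role") %in% names(tab)))
    .scError("scancal_format_error", paste0(
      "readSlideDescription: ", path,
      " must have columns 'series' and 'density_or_role'"))
  rd <- lapply(tab$density_or_role, .nameToRole)
  new("SlideLayout",
      columns = data.frame(series = as.integer(tab$series),
                           role = vapply(rd, `[[`, character(1), "role"),
                           dye = dye,
                           density = vapply(rd, `[[`, numeric(1), "density"),
                           stringsAsFactors = FALSE),
      replicatesPerColumn = NA_integer_)
}

#' Audit a manual slide description against a GAL layout
#'
#' Compares two layouts column by column: density-vs-density within a
#' relative tolerance (symmetric: relative difference is measured against
#' the larger magnitude), role-vs-role by identity. A role-vs-density
#' conflict — the manual calling a column "Buffer" while the layout file
#' assigns it a dye concentration, the classic vendor-documentation
#' discrepancy — is reported as a mismatch quoting both claims and which
#' source made each. Columns present in only one source are reported as
#' missing; differing column counts are noted and the audit continues on
#' the overlap.
#'
#' @param manual [SlideLayout-class] from the manual description table.
#' @param gal [SlideLayout-class] from the GAL file.
#' @param tolerance relative density tolerance (default 0.01, i.e. 1%).
#' @return A [ConsistencyReport-class].
#' @examples
#' a <- makeSlideLayout(replicatesPerColumn = 1)
#' checkLayoutConsistency(a, a)   # all match
#' @export
checkLayoutConsistency <- function(manual, gal, tolerance = 0.01) {
  stopifnot(is(manual, "SlideLayout"), is(gal, "SlideLayout"))
  mc <- manual@columns; gc <- gal@columns
  note <- character()
  if (nrow(mc) != nrow(gc))
    note <- paste0("column counts differ: manual has ", nrow(mc),
                   ", layout file has ", nrow(gc),
                   "; audited the overlap only")
  allidx <- sort(union(mc$series, gc$series))
  describe <- function(row) {
    if (row$role == "dilution") sprintf("density %.3E", row$density)
    else row$role
  }
  rows <- lapply(allidx, function(k) {
    mrow <- mc[mc$series == k, , drop = FALSE]
    grow <- gc[gc$series == k, , drop = FALSE]
    if (nrow(mrow) == 0L || nrow(grow) == 0L) {
      src <- if (nrow(mrow) == 0L) "manual" else "layout file"
      return(data.frame(column = k, manual = if (nrow(mrow)) describe(mrow)
                        else NA_character_,
                        gal = if (nrow(grow)) describe(grow)
                        else NA_character_,
                        verdict = "missing",
                        detail = paste0("column absent from ", src),
                        stringsAsFactors = FALSE))
    }
    mdesc <- describe(mrow); gdesc <- describe(grow)
    both_num <- mrow$role %in% c("dilution", "blank") &&
      grow$role %in% c("dilution", "blank")
    if (both_num) {
      md <- mrow$density; gd <- grow$density
      reldiff <- if (md == gd) 0 else abs(md - gd) / max(abs(md), abs(gd))
      verdict <- if (reldiff <= tolerance) "match" else "mismatch"
      detail <- if (verdict == "match") "densities agree" else
        sprintf("manual says %s but layout file says %s (relative difference %.3g)",
                mdesc, gdesc, reldiff)
    } else if (mrow$role == grow$role) {
      verdict <- "match"; detail <- paste("both sources say", mrow$role)
    } else {
      verdict <- "mismatch"
      detail <- sprintf("manual says %s but layout file says %s",
                        mdesc, gdesc)
    }
    data.frame(column = k, manual = mdesc, gal = gdesc, verdict = verdict,
               detail = detail, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts <- c(match = sum(tab$verdict == "match"),
              mismatch = sum(tab$verdict == "mismatch"),
              missing = sum(tab$verdict == "missing"))
  new("ConsistencyReport", table = tab, counts = counts, note = note)
}
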