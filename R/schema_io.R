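#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter group_by ungroup summarise bind_rows
#'   left_join row_number desc n
NULL

# Sentinel the primary-screen deposit uses for "no odor applied"
NO_ODOR_SENTINEL <- 9999

# Column sets of the five tab-separated deposit dialects, in deposit order.
# Internal names are snake_case; deposit headers are the canonical ones.
.SCHEMAS <- list(
  primary = c(
    Plate = "plate_id", Well = "well_index", Concentration = "concentration_uM",
    Luc = "luc_counts", RL = "rl_counts", OR = "receptor_id",
    Odor = "odor_id", Date = "date"
  ),
  secondary = c(
    Date = "date", OR = "receptor_id", Odor = "odor_id",
    Concentration = "concentration_uM", NormalizedLuc = "normalized_luc"
  ),
  dose = c(
    Concentration = "concentration_log10M", NormLuc = "normalized_luc",
    OR = "receptor_id", Odor = "odor_id", Date = "date"
  ),
  receptor = c(OR = "receptor_id", Gene = "gene_label",
               NucleotideSeq = "nucleotide_seq"),
  odor = c(Odor = "odor_id", CASRegistryNum = "cas_number",
           OdorName = "odor_name", CID = "cid", SMILES = "smiles")
)

.NUMERIC_COLS <- list(
  primary = c("well_index", "concentration_uM", "luc_counts", "rl_counts"),
  secondary = c("concentration_uM", "normalized_luc"),
  dose = c("concentration_log10M", "normalized_luc"),
  receptor = character(0),
  odor = "cid"
)

.check_kind <- function(kind) {
  if (length(kind) != 1L || !kind %in% names(.SCHEMAS)) {
    stop("`kind` must be one of: ", paste(names(.SCHEMAS), collapse = ", "),
         call. = FALSE)
  }
  kind
}

# Accept both ASCII hyphen-minus and the typographic minus the deposit
# documentation prints ("−12"), then parse.
.parse_num <- function(x) {
  x <- gsub("−", "-", trimws(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# Dates are MM/DD/YY; two-digit years map to 2000-2099.
.parse_date <- function(x) {
  d <- as.Date(trimws(x), format = "%m/%d/%y")
  bad <- !is.na(x) & nzchar(trimws(x)) & is.na(d)
  if (any(bad)) {
    stop("unparseable date(s) in MM/DD/YY format, e.g. row ",
         which(bad)[1], ": '", x[which(bad)[1]], "'", call. = FALSE)
  }
  # R's %y puts 69-99 in the 1900s; the deposit's years are all 2000-2099
  fix <- !is.na(d) & as.integer(format(d, "%Y")) < 2000L
  if (any(fix)) {
    lt <- as.POSIXlt(d[fix])
    lt$year <- lt$year + 100L
    d[fix] <- as.Date(lt)
  }
  d
}

.format_date <- function(d) format(d, "%m/%d/%y")

#' Read one of the five screening data tables
#'
#' Reads a tab-separated file in one of the deposit's five dialects
#' (primary screen wells, secondary screen wells, dose-response wells,
#' receptor clone metadata, odorant metadata) into a validated tibble
#' with snake_case columns. Sentinel concentrations are decoded: in
#' primary tables `9999` means no odor (stored as `NA` in
#' `concentration_uM` with `no_odor = TRUE`); in dose tables the no-odor
#' condition is coded as log10 molarity `-12` (kept literally, flagged
#' via `no_odor`). Both the ASCII hyphen-minus and the Unicode minus sign
#' are accepted in numeric fields.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param kind One of `"primary"`, `"secondary"`, `"dose"`, `"receptor"`,
#'   `"odor"`.
#' @param col_map Optional named character vector mapping file headers to
#'   the canonical deposit headers (e.g. `c(Conc = "Concentration")`) for
#'   deposits whose headers deviate from the documented field names.
#'
#' @return A tibble, one row per input row, with an attribute
#'   `kind` recording the dialect. Primary and dose tables gain a logical
#'   `no_odor` column.
#' @export
read_record_table <- function(path, kind, col_map = NULL) {
  kind <- .check_kind(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    hit <- match(names(raw), names(col_map))
    names(raw)[!is.na(hit)] <- col_map[hit[!is.na(hit)]]
  }
  schema <- .SCHEMAS[[kind]]
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop("schema error: '", kind, "' table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- as_tibble(raw[, names(schema), drop = FALSE])
  names(out) <- unname(schema)

  for (col in .NUMERIC_COLS[[kind]]) {
    val <- .parse_num(out[[col]])
    bad <- !is.na(out[[col]]) & nzchar(trimws(out[[col]])) & is.na(val)
    if (any(bad)) {
      stop("parse error: non-numeric value in column '", col, "', row ",
           which(bad)[1], ": '", out[[col]][which(bad)[1]], "'",
           call. = FALSE)
    }
    out[[col]] <- val
  }
  if ("date" %in% names(out)) out$date <- .parse_date(out$date)

  out <- .validate_records(out, kind)
  attr(out, "kind") <- kind
  out
}

.validate_records <- function(out, kind) {
  if (kind == "primary") {
    if (any(is.na(out$well_index)) ||
        any(out$well_index < 1 | out$well_index > 96)) {
      stop("validation error: well_index must be in 1..96", call. = FALSE)
    }
    if (any(is.na(out$rl_counts) | out$rl_counts <= 0)) {
      stop("validation error: rl_counts must be > 0 (dead/failed well), row ",
           which(is.na(out$rl_counts) | out$rl_counts <= 0)[1], call. = FALSE)
    }
    if (any(out$luc_counts < 0, na.rm = TRUE)) {
      stop("validation error: negative luc_counts", call. = FALSE)
    }
    out$no_odor <- !is.na(out$concentration_uM) &
      out$concentration_uM == NO_ODOR_SENTINEL
    out$concentration_uM[out$no_odor] <- NA_real_
  } else if (kind == "secondary") {
    if (any(out$concentration_uM < 0, na.rm = TRUE)) {
      stop("validation error: negative concentration", call. = FALSE)
    }
  } else if (kind == "dose") {
    out$no_odor <- !is.na(out$concentration_log10M) &
      out$concentration_log10M == -12
  } else if (kind == "receptor") {
    if (any(!nzchar(out$nucleotide_seq))) {
      stop("validation error: empty nucleotide_seq", call. = FALSE)
    }
    seqs <- toupper(out$nucleotide_seq)
    if (any(grepl("[^ACGT]", seqs))) {
      stop("validation error: nucleotide_seq contains non-ACGT characters",
           call. = FALSE)
    }
    # Length not divisible by 3 is flagged, not rejected
    out$frame_ok <- nchar(seqs) %% 3L == 0L
  }
  out
}

#' Write screening records back to the deposit's tab-separated dialect
#'
#' Inverse of [read_record_table()]: re-encodes sentinels (`NA`
#' concentration with `no_odor = TRUE` becomes the literal `9999`; dose
#' no-odor rows carry `-12`), formats dates as MM/DD/YY, and writes a
#' tab-separated file with the deposit's header names. Reading the file
#' back reproduces the records field for field.
#'
#' @param records A tibble as produced by [read_record_table()] or the
#'   simulators, with the snake_case columns of `kind`.
#' @inheritParams read_record_table
#' @return `path`, invisibly.
#' @export
write_record_table <- function(records, path, kind = attr(records, "kind")) {
  kind <- .check_kind(kind)
  schema <- .SCHEMAS[[kind]]
  missing <- setdiff(unname(schema), names(records))
  if (length(missing)) {
    stop("type error: records lack column(s) of kind '", kind, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(records[, unname(schema)], stringsAsFactors = FALSE)
  if (kind == "primary" && "no_odor" %in% names(records)) {
    out$concentration_uM[records$no_odor] <- NO_ODOR_SENTINEL
  }
  if ("date" %in% names(out)) out$date <- .format_date(out$date)
  names(out) <- names(schema)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a well index to its 96-well plate coordinate
#'
#' Wells are numbered row-major: left to right, then top to bottom, so
#' well 1 is A1 (upper-left), well 85 is H1 (lower-left) and well 96 is
#' H12. This is the numbering of the primary-screen deposit.
#'
#' @param well_index Integer vector with values in 1..96.
#' @return A tibble with columns `well_index`, `row` (letter A-H) and
#'   `column` (integer 1-12).
#' @seealso [well_index()] for the inverse.
#' @export
#' @examples
#' well_position(c(1, 85, 96))
well_position <- function(well_index) {
  if (any(is.na(well_index)) || any(well_index < 1 | well_index > 96) ||
      any(well_index != as.integer(well_index))) {
    stop("well_index must be integers in 1..96", call. = FALSE)
  }
  i <- as.integer(well_index) - 1L
  tibble(
    well_index = as.integer(well_index),
    row = LETTERS[i %/% 12L + 1L],
    column = i %% 12L + 1L
  )
}

#' Convert a 96-well plate coordinate to its well index
#'
#' @param row Letter A-H (character vector).
#' @param column Integer 1-12.
#' @return Integer well index in 1..96.
#' @seealso [well_position()]
#' @export
well_index <- function(row, column) {
  r <- match(toupper(row), LETTERS[1:8])
  if (any(is.na(r)) || any(column < 1 | column > 12)) {
    stop("row must be A-H and column 1-12", call. = FALSE)
  }
  as.integer((r - 1L) * 12L + column)
}

#' Default 96-well primary-screen plate layout
#'
#' Every primary-screen plate holds 85 test wells, five broadly tuned
#' control receptors, and six Olfr544 standard wells of which three
#' receive the known agonist (10 uM nonanedioic acid) and three the
#' diluent (CD293). With row-major numbering and wells 1 and 85 fixed as
#' the upper-left and lower-left corners, the eleven non-test wells are
#' 86-96 (H2-H12); the default places the broadly tuned receptors at
#' 86-90, the standard+agonist wells at 91-93 and the standard+diluent
#' wells at 94-96. All positions are configurable.
#'
#' @param test_wells Integer well indices holding test receptors.
#' @param broad_wells Wells holding the broadly tuned control receptors.
#' @param standard_agonist_wells Olfr544 wells challenged with agonist.
#' @param standard_diluent_wells Olfr544 wells challenged with diluent.
#' @param vector_wells Optional wells for empty-vector controls.
#' @return An object of class `plate_layout`: a list with the well-role
#'   vectors above.
#' @export
plate_layout <- function(test_wells = 1:85,
                         broad_wells = 86:90,
                         standard_agonist_wells = 91:93,
                         standard_diluent_wells = 94:96,
                         vector_wells = integer(0)) {
  layout <- list(
    test_wells = as.integer(test_wells),
    broad_wells = as.integer(broad_wells),
    standard_agonist_wells = as.integer(standard_agonist_wells),
    standard_diluent_wells = as.integer(standard_diluent_wells),
    vector_wells = as.integer(vector_wells)
  )
  all_wells <- unlist(layout, use.names = FALSE)
  if (any(all_wells < 1 | all_wells > 96)) {
    stop("layout wells must be in 1..96", call. = FALSE)
  }
  if (anyDuplicated(all_wells)) {
    stop("layout well roles must be disjoint", call. = FALSE)
  }
  structure(layout, class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("96-well plate layout:\n")
  cat("  test wells:            ", length(x$test_wells), "\n")
  cat("  broadly tuned wells:   ", paste(x$broad_wells, collapse = ", "), "\n")
  cat("  standard+agonist:      ",
      paste(x$standard_agonist_wells, collapse = ", "), "\n")
  cat("  standard+diluent:      ",
      paste(x$standard_diluent_wells, collapse = ", "), "\n")
  if (length(x$vector_wells))
    cat("  empty-vector wells:    ", paste(x$vector_wells, collapse = ", "), "\n")
  invisible(x)
}
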