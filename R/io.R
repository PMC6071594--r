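#' Read a plot-level yield-trial table
#'
#' Reads a CSV of plot records for one or more location-years of a yield
#' trial. The header must contain the columns `line_id`, `year`, `location`,
#' `row`, `col`, `block`, `rep`, `is_check`, `yield`. Layout fields must be
#' complete positive integers; yield may be missing (damaged plots) and is
#' parsed as `NA`, never as zero.
#'
#' @param path path to the CSV file.
#' @param sep field separator (default comma).
#' @return A validated data.frame of plot records ("trial table").
#' @details Plot coordinates `(row, col)` must be unique within each
#'   `(location, year, rep)`; violations raise an error naming the offending
#'   plot.
#' @examples
#' tt <- data.frame(line_id = c("A", "B"), year = 2012, location = "MEAD",
#'                  row = 1:2, col = 1, block = 1, rep = 1,
#'                  is_check = FALSE, yield = c(5.1, NA))
#' f <- tempfile(fileext = ".csv")
#' writeTrialTable(tt, f)
#' readTrialTable(f)
#' @export
readTrialTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validateTrialTable(df)
}

#' Validate a trial table
#'
#' Checks the plot-record invariants: required columns present, layout
#' fields complete integers, plot coordinates unique within a
#' location-year-replicate, every block non-empty.
#'
#' @param df data.frame of plot records.
#' @return The validated data.frame (layout columns coerced to integer,
#'   `is_check` to logical), invisibly usable downstream.
#' @export
validateTrialTable <- function(df) {
  required <- c("line_id", "year", "location", "row", "col", "block",
                "rep", "is_check", "yield")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("trial table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("no records")
  for (cc in c("year", "row", "col", "block", "rep")) {
    v <- df[[cc]]
    if (anyNA(v)) stop("layout field '", cc, "' may not be missing")
    vi <- suppressWarnings(as.integer(v))
    if (anyNA(vi) || any(vi != as.numeric(v)))
      stop("non-integer values in layout field '", cc, "'")
    df[[cc]] <- vi
  }
  if (any(df$row < 1) || any(df$col < 1) || any(df$block < 1) ||
      any(df$rep < 1))
    stop("layout fields row, col, block, rep must be >= 1")
  df$is_check <- as.logical(df$is_check)
  if (anyNA(df$is_check)) stop("is_check must be TRUE/FALSE")
  df$yield <- as.numeric(df$yield)
  df$line_id <- as.character(df$line_id)
  key <- paste(df$location, df$year, df$rep, df$row, df$col, sep = "|")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicated plot coordinates: ",
         paste(unique(key[dup]), collapse = "; "))
  df
}

#' Write a trial table to CSV
#'
#' @param df trial table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrialTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a line x marker genotype matrix
#'
#' Reads the deposited-panel dialect: a delimited table with line ids in the
#' first column and marker ids in the header, entries coded either in
#' half-dosage (1 = homozygous major, 0 = homozygous minor, 0.5 =
#' heterozygous) or full dosage (2/0/1). The separator (tab or comma) is
#' auto-detected from the header line. `"NA"` and empty cells are both read
#' as missing.
#'
#' @param path path to the genotype file.
#' @param coding `"half_dosage"` (default) or `"dosage"`; `"dosage"` input is
#'   converted to the canonical half-dosage alphabet on read.
#' @param orientation `"lines_by_markers"` (rows are lines; the deposited
#'   orientation), `"markers_by_lines"`, or `"auto"` which transposes when
#'   there are more rows than columns (marker panels are much wider than
#'   they are tall).
#' @param map optional marker-map data.frame to attach.
#' @param allelicR2 optional named vector of imputation quality scores.
#' @return A [GenotypePanel-class].
#' @export
readGenotypeMatrix <- function(path, coding = c("half_dosage", "dosage"),
                               orientation = c("lines_by_markers", "auto",
                                               "markers_by_lines"),
                               map = NULL, allelicR2 = NULL) {
  coding <- match.arg(coding)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop("no records")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !(m %in% if (coding == "half_dosage")
                               HALF_DOSAGE_ALPHABET else c(0, 1, 2)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("symbol outside the ", coding, " alphabet at row '",
         rownames(m)[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]], "'")
  if (coding == "dosage") m <- m / 2
  if (orientation == "markers_by_lines" ||
      (orientation == "auto" && nrow(m) > ncol(m)))
    m <- t(m)
  GenotypePanel(m, map = map, allelicR2 = allelicR2)
}

#' Write a GenotypePanel in the deposited-matrix dialect
#'
#' Writes a tab-separated line x marker table (line ids in the first column,
#' marker ids in the header) that [readGenotypeMatrix()] reads back
#' identically.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @param sep separator, tab by default.
#' @return `path`, invisibly.
#' @export
writeGenotypeMatrix <- function(panel, path, sep = "\t") {
  m <- calls(panel)
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' @param path CSV with columns `marker_id`, `chrom`, `pos`.
#' @return data.frame with those columns, `pos` coerced to integer.
#' @export
readMarkerMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "chrom", "pos") %in% names(df)))
    stop("marker map must have columns marker_id, chrom, pos")
  df$pos <- as.integer(df$pos)
  if (anyDuplicated(df$marker_id)) stop("duplicated marker ids in map")
  df
}

#' Import genotype calls from a VCF
#'
#' Converts the GT field of biallelic records to the half-dosage alphabet:
#' `0/0 -> 1` (homozygous reference/major), `1/1 -> 0`, `0/1` or `1/0 ->
#' 0.5`, `./. -> NA`. Multiallelic records are skipped and their count
#' logged. Coordinates are taken 1-based from CHROM/POS as in the standard.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return A [GenotypePanel-class] with the map filled from CHROM/POS.
#' @export
vcfToCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no records in VCF")
  alt <- v@fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    bgsLog("vcfToCalls: skipped ", n_multi, " multiallelic record(s)")
  if (!any(biallelic)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  conv <- c("0/0" = 1, "1/1" = 0, "0/1" = 0.5, "1/0" = 0.5, "./." = NA_real_)
  m <- matrix(conv[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  unknown <- !is.na(gt) & !(gt %in% names(conv))
  if (any(unknown)) m[unknown] <- NA_real_
  fix <- v@fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  auto <- is.na(ids) | ids == "."
  ids[auto] <- paste0("S", fix[auto, "CHROM"], "_", fix[auto, "POS"])
  rownames(m) <- ids
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  GenotypePanel(t(m), map = map)
}
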