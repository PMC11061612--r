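# Readers and writers for the screen's file formats: long-format well CSV
# and MOBEM-style binary feature TSV.

.wellColumns <- c("plate", "well", "well_class", "cell_line", "drug_A",
                  "drug_B", "dose_index_A", "dose_index_B", "conc_A",
                  "conc_B", "raw_signal")
.wellClasses <- c("COMBO", "SA_A", "SA_B", "NC0", "NC1", "PC1", "PC2", "B")

#' Read and validate a long-format well table
#'
#' The screen serialization is one CSV row per well: `plate`, `well`,
#' `well_class` (one of COMBO, SA_A, SA_B, NC0, NC1, PC1, PC2, B),
#' `cell_line`, `drug_A`, `drug_B`, `dose_index_A`, `dose_index_B` (1-based,
#' 1 = lowest dose), `conc_A`, `conc_B`, `raw_signal`. Dose indices must lie
#' within `1..nDoses` where present (both for COMBO wells, the matching one
#' for single-agent wells, none for controls), and `(plate, well)` must be
#' unique. Violations raise a parse error naming the offending line.
#'
#' @param path CSV file path.
#' @param nDoses Number of doses per drug (default 7).
#' @return Validated well data frame.
#' @export
readScreen <- function(path, nDoses = 7) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) inputError("empty well table: ", path)
  missing <- setdiff(.wellColumns, names(tab))
  if (length(missing))
    inputError("well table missing column(s): ",
               paste(missing, collapse = ", "))
  for (col in c("plate", "well", "well_class", "cell_line", "drug_A",
                "drug_B"))
    tab[[col]] <- as.character(tab[[col]])
  lineNo <- function(i) i + 1L  # header occupies line 1

  bad <- which(!tab$well_class %in% .wellClasses)
  if (length(bad))
    inputError("unknown well_class '", tab$well_class[bad[1]],
               "' at line ", lineNo(bad[1]))

  inRange <- function(x) !is.na(x) & x >= 1 & x <= nDoses
  combo <- tab$well_class == "COMBO"
  bad <- which(combo & !(inRange(tab$dose_index_A) &
                           inRange(tab$dose_index_B)))
  badA <- which(tab$well_class == "SA_A" & !inRange(tab$dose_index_A))
  badB <- which(tab$well_class == "SA_B" & !inRange(tab$dose_index_B))
  bad <- sort(c(bad, badA, badB))
  if (length(bad))
    inputError("dose index out of 1..", nDoses, " at line ", lineNo(bad[1]))

  key <- paste(tab$plate, tab$well)
  dup <- which(duplicated(key))
  if (length(dup))
    inputError("duplicate (plate, well) key '", key[dup[1]],
               "' at line ", lineNo(dup[1]))
  tab
}

#' Write a well table (or SyntheticScreen) to CSV
#'
#' Rows are sorted by plate then well so output is deterministic.
#'
#' @param x A [SyntheticScreen-class] or a well data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeScreen <- function(x, path) {
  wells <- if (is(x, "SyntheticScreen")) x@wells else x
  wells <- wells[order(wells$plate, wells$well), .wellColumns]
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MOBEM-style binary feature matrix
#'
#' Tab-separated binary event matrix. Orientation is auto-detected from the
#' first header field: `feature` means features are rows and cell lines are
#' columns (the conventional public MOBEM layout); `cell_line` means the
#' transpose. Any value outside {0, 1} is a parse error naming the offending
#' row and column.
#'
#' @param path TSV file path.
#' @return Integer 0/1 matrix, cell lines in rows, features in columns.
#' @export
readMobem <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || nrow(tab) == 0)
    inputError("MOBEM file is empty or lacks data columns: ", path)
  sentinel <- names(tab)[1]
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!(m %in% c(0, 1)) | is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    inputError("non-binary MOBEM value '", m[bad[1, 1], bad[1, 2]],
               "' at row '", ids[bad[1, 1]], "', column '",
               colnames(m)[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (sentinel == "feature") t(m)
  else if (sentinel == "cell_line") m
  else inputError("cannot detect MOBEM orientation: first column must be ",
                  "named 'feature' or 'cell_line', got '", sentinel, "'")
}

#' Write a binary feature matrix as MOBEM TSV
#'
#' @param features Integer 0/1 matrix, cell lines in rows.
#' @param path Output TSV path.
#' @param orientation `"feature"` (features as rows, the public MOBEM
#'   convention; default) or `"cell_line"`.
#' @return `path`, invisibly.
#' @export
writeMobem <- function(features, path,
                       orientation = c("feature", "cell_line")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "feature") t(features) else features
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- orientation
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
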