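# Lightweight workbook I/O.
#
# Worksheets are written as SpreadsheetML with every cell an inline string, so
# that read(write(x)) round-trips all cell values bit-exact as strings —
# including censoring tokens like "BDL" that a typed writer would mangle.
# Reading goes through readxl with col_types = "text" for the same reason.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

worksheet_xml <- function(df) {
  df[] <- lapply(df, as_chr)
  cell <- function(j, i, v)
    sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            col_letter(j), i, xml_escape(v))
  rows <- character(nrow(df) + 1)
  rows[1] <- sprintf('<row r="1">%s</row>', paste(
    vapply(seq_along(df), function(j) cell(j, 1, names(df)[j]), ""), collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (!nzchar(v)) "" else cell(j, i + 1, v)
    }, "")
    rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1, paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write data frames to a plain Excel workbook
#'
#' Writes one worksheet per element of `sheets`, every cell as text. Intended
#' for the package's troubleshooting exports and the WQX submission workbook;
#' values survive a write/read cycle exactly as strings.
#'
#' @param sheets named list of data frames; names become sheet names.
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @seealso [read_workbook()]
#' @export
write_workbook <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) > 0, !is.null(names(sheets)),
            all(nzchar(names(sheets))))
  n <- length(sheets)
  tmp <- tempfile("wb")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  put <- function(rel, txt) writeLines(txt, file.path(tmp, rel), useBytes = TRUE)
  put("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '</Types>'))
  put("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'))
  put("xl/workbook.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"',
    ' xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    '</sheets></workbook>'))
  put("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>'))
  for (i in seq_len(n))
    put(sprintf("xl/worksheets/sheet%d.xml", i), worksheet_xml(sheets[[i]]))
  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  if (file.exists(path)) unlink(path)
  # zip() works from `root`, so the archive path must be absolute
  abs_path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                        basename(path))
  zip::zip(zipfile = abs_path, files = files, root = tmp, mode = "mirror")
  invisible(path)
}

#' Read a workbook written by [write_workbook()] (or any xlsx) as text
#'
#' @param path `.xlsx` path.
#' @param sheet sheet name or index; `NULL` reads all sheets into a named list.
#' @return A tibble with all columns character, or a named list of them.
#' @export
read_workbook <- function(path, sheet = NULL) {
  if (is.null(sheet)) {
    sheets <- readxl::excel_sheets(path)
    return(setNames(lapply(sheets, function(s) read_workbook(path, s)), sheets))
  }
  out <- readxl::read_excel(path, sheet = sheet, col_types = "text")
  out[] <- lapply(out, as_chr)
  out
}

# read any tabular input: data frame passthrough, .csv via readr, .xlsx via
# readxl — always all-character cells so downstream parsing is uniform
read_table_any <- function(x, sheet = 1) {
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
    out[] <- lapply(out, as_chr)
    return(out)
  }
  stopifnot(is.character(x), length(x) == 1)
  if (!file.exists(x)) stop("File not found: ", x, call. = FALSE)
  if (grepl("\\.csv$", x, ignore.case = TRUE)) {
    out <- readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  } else {
    out <- readxl::read_excel(x, sheet = sheet, col_types = "text")
  }
  out[] <- lapply(out, as_chr)
  out
}

# write a table as csv or xlsx keyed on the file extension
write_table_any <- function(df, path, sheet_name = "Sheet1") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, na = "")
  } else {
    write_workbook(setNames(list(df), sheet_name), path)
  }
  invisible(path)
}
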