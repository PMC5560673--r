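# Minimal XLSX (OOXML spreadsheet) writer: one worksheet per data frame,
# header row + body, numbers as numeric cells, everything else as inline
# strings, no shared-string table, no styles. The archive is a plain zip
# built with the zip package. Enough for downstream tools (verified against
# readxl in the test suite); not a general-purpose spreadsheet library.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- character(length(j))
  for (k in seq_along(j)) {
    n <- j[k]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

sheet_xml <- function(df) {
  cols <- names(df)
  rows <- character(nrow(df) + 1L)
  hdr <- paste0(sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
                        col_letter(seq_along(cols)), xml_escape(cols)),
                collapse = "")
  rows[1] <- sprintf('<row r="1">%s</row>', hdr)
  if (nrow(df) > 0) {
    is_num <- vapply(df, is.numeric, logical(1))
    for (i in seq_len(nrow(df))) {
      cells <- character(0)
      for (j in seq_along(cols)) {
        v <- df[i, j]
        if (is.na(v)) next
        ref <- paste0(col_letter(j), i + 1L)
        cells <- c(cells, if (is_num[j]) {
          sprintf('<c r="%s"><v>%s</v></c>', ref,
                  format(v, digits = 15, scientific = FALSE, trim = TRUE))
        } else {
          sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                  xml_escape(as.character(v)))
        })
      }
      rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                              paste0(cells, collapse = ""))
    }
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')
}

write_minimal_xlsx <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) > 0, !is.null(names(sheets)))
  root <- tempfile("xlsx")
  dir.create(file.path(root, "_rels"), recursive = TRUE)
  dir.create(file.path(root, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(root, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)

  overrides <- paste0(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, '</Types>'),
    file.path(root, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'),
    file.path(root, "_rels", ".rels"))

  sheet_entries <- paste0(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheet_entries, '</sheets></workbook>'),
    file.path(root, "xl", "workbook.xml"))

  rels <- paste0(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, '</Relationships>'),
    file.path(root, "xl", "_rels", "workbook.xml.rels"))

  for (k in seq_len(n)) {
    writeLines(sheet_xml(as.data.frame(sheets[[k]])),
               file.path(root, "xl", "worksheets", sprintf("sheet%d.xml", k)))
  }
  if (file.exists(path)) unlink(path)
  path_abs <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                        basename(path))
  zip::zip(path_abs,
           files = c("[Content_Types].xml", "_rels", "xl"),
           root = root, mode = "mirror", include_directories = FALSE)
  invisible(path)
}
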