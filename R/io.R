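#' Read and validate a gene table
#'
#' All tables in this package share one dialect: UTF-8 TSV with a header row,
#' genes as rows, a `gene` column of unique symbols, and `NA` for missing
#' values. Schema violations are rejected with the file, column and offending
#' gene named.
#'
#' @param path Path to a TSV file.
#' @param numeric_cols Columns that must be present and numeric; `NULL`
#'   accepts any.
#' @param range Optional length-2 numeric vector; non-`NA` values of the
#'   numeric columns must fall inside it.
#' @return A data frame.
#' @export
read_gene_table <- function(path, numeric_cols = NULL, range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE, fileEncoding = "UTF-8"
  )
  if (!"gene" %in% names(df)) {
    stop(path, ": missing required column 'gene'", call. = FALSE)
  }
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0) {
    stop(path, ": duplicate gene symbol(s): ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in numeric_cols) {
    if (!col %in% names(df)) {
      stop(path, ": missing required column '", col, "'", call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      bad <- df$gene[is.na(suppressWarnings(as.numeric(df[[col]]))) &
        !is.na(df[[col]])][1]
      stop(path, ": column '", col, "' is not numeric (row for gene ",
        bad, ")",
        call. = FALSE
      )
    }
    if (!is.null(range)) {
      out <- !is.na(df[[col]]) & (df[[col]] < range[1] | df[[col]] > range[2])
      if (any(out)) {
        stop(path, ": column '", col, "' outside [", range[1], ", ", range[2],
          "] (gene ", df$gene[which(out)[1]], ")",
          call. = FALSE
        )
      }
    }
  }
  df
}

#' Write a gene table in the package TSV dialect
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(table, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", fileEncoding = "UTF-8"
  )
  invisible(path)
}

read_intensity_table <- function(path) {
  regions <- ALL_REGIONS
  df <- read_gene_table(path, numeric_cols = NULL)
  present <- intersect(regions, names(df))
  if (length(present) < 2) {
    stop(path, ": expected region columns among ",
      paste(regions, collapse = ", "),
      call. = FALSE
    )
  }
  read_gene_table(path, numeric_cols = present, range = c(0, 255))
}
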