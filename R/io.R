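# Tabular I/O shared by all modules and by the command-line interface.

#' Read a compound table
#'
#' Accepts comma- or tab-separated tables with a header and required columns
#' `id` and `smiles`, or SMILES files (`.smi`: whitespace-delimited
#' `smiles id` without header). Rows with unparseable structures are skipped
#' with a counted warning; duplicate ids are an error.
#'
#' @param path input file.
#' @return data.frame with at least `id` and `smiles` (additional columns
#'   are carried through).
#' @export
read_compound_table <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    df <- data.frame(
      id = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                  character(1)),
      smiles = vapply(parts, `[[`, character(1), 1),
      stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE,
                            quote = "\"")
    for (col in c("id", "smiles")) {
      if (!col %in% names(df)) {
        stop("compound table is missing required column '", col, "'",
             call. = FALSE)
      }
    }
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate compound id: ", df$id[duplicated(df$id)][1], call. = FALSE)
  }
  ok <- is_valid_smiles(df$smiles)
  if (any(!ok)) {
    warning(sum(!ok), " rows with unparseable structures skipped",
            call. = FALSE)
  }
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a table with a provenance header
#'
#' Writes a CSV preceded by comment lines recording the tool version, the
#' seed, and md5 digests of the input files, so every output is traceable.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param seed seed used by the producing computation (optional).
#' @param inputs character vector of input file paths to digest (optional).
#' @return `path`, invisibly.
#' @export
write_molce_table <- function(df, path, seed = NULL, inputs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("molce"))
  writeLines(paste0("# molce ", ver), con)
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  for (f in inputs) {
    writeLines(paste0("# input ", basename(f), " md5=",
                      unname(tools::md5sum(f))), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_molce_table()]
#'
#' @param path input file.
#' @return data.frame (provenance comment lines are skipped).
#' @export
read_molce_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
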