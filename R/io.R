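# Tabular I/O and variant-string parsing.
#
# TSV dialect: tab-separated, UTF-8, '#'-prefixed comment lines, '.' for
# missing values. Writing then reading reproduces identical values.

#' Read / write tab-separated tables
#'
#' The package's TSV dialect: tab separator, `#` comment lines, `.` for
#' missing values, header row of exact column names.
#'
#' @param path File path.
#' @return `read_codp_tsv()`: a data frame.
#' @export
read_codp_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_codp_tsv
#' @param x Data frame to write.
#' @param comment Optional character vector written as leading `#` lines.
#' @export
write_codp_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    v <- as.character(x[[j]])
    v[is.na(v)] <- "."
    x[[j]] <- v
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse protein variant strings
#'
#' Accepts the wild-type letter + 1-based position + mutant letter
#' convention (e.g. `"E1193K"`); anything else is rejected.
#'
#' @param x Character vector of variant strings.
#' @return Data frame with `variant`, `wt`, `position`, `mut`.
#' @examples
#' parse_variant(c("G566R", "E1193K"))
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("codp_invalid_variant: not of the form <wt><position><mut>: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  wt <- toupper(vapply(m, `[`, character(1), 2L))
  mut <- toupper(vapply(m, `[`, character(1), 4L))
  .check_aa(wt, "wt")
  .check_aa(mut, "mut")
  data.frame(variant = x, wt = wt,
             position = as.integer(vapply(m, `[`, character(1), 3L)),
             mut = mut, stringsAsFactors = FALSE)
}

.codp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "codp")
  if (path == "") {
    # during development (package loaded from source tree)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    stop("codp_internal: packaged file not found: ", file, call. = FALSE)
  }
  path
}
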