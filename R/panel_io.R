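#' Read a prediction panel from a delimited text file
#'
#' The on-disk layout is one variant per row with header, UTF-8, and a
#' schema config naming the per-tool call/score columns, each tool's native
#' vocabulary and its score polarity. Missing tool outputs are encoded with
#' an explicit sentinel token (default \code{"."}), never an empty
#' convention-dependent cell, so round-trips are unambiguous; empty cells
#' are nevertheless accepted on input as missing.
#'
#' @param path File to read.
#' @param schema Schema config: a list, or the path of a YAML file, with
#'   entries \code{format} (\code{"tsv"} default or \code{"csv"}),
#'   \code{missing_token}, and \code{tools}, a named list per tool with
#'   \code{call_column}, optional \code{score_column}, \code{polarity},
#'   optional \code{metaserver} flag and \code{vocabulary} (raw label ->
#'   damaging/tolerated). See [panel_schema()].
#' @return A [prediction_panel()].
#' @export
read_panel <- function(path, schema) {
  schema <- load_schema(schema)
  sep <- if (identical(schema$format, "csv")) "," else "\t"
  sentinel <- schema$missing_token %||% "."

  raw_lines <- readLines(path, encoding = "UTF-8")
  if (!length(raw_lines)) stop("empty panel file: ", path, call. = FALSE)
  nfield <- utils::count.fields(path, sep = sep, quote = "", comment.char = "")
  if (length(unique(nfield)) > 1) {
    bad <- which(nfield != nfield[1])[1]
    stop(sprintf("ragged row in %s at line %d: %d fields, header has %d",
                 path, bad, nfield[bad], nfield[1]), call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", colClasses = "character",
                           check.names = FALSE, encoding = "UTF-8")

  variant_cols <- c("variant_id", "gene", "truth", "evidence",
                    "allele_frequency", "region")
  tool_names <- names(schema$tools)
  declared <- c(variant_cols,
                unlist(lapply(schema$tools, function(t)
                  c(t$call_column, t$score_column)), use.names = FALSE))
  undeclared <- setdiff(names(tab), declared)
  if (length(undeclared)) {
    stop("undeclared columns in ", path, ": ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(c(variant_cols, vapply(schema$tools, `[[`, "", "call_column")),
                    names(tab))
  if (length(absent)) {
    stop("columns required by the schema are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$variant_id)) {
    dup <- unique(tab$variant_id[duplicated(tab$variant_id)])
    first <- which(tab$variant_id %in% dup)[1] + 1L   # +1 for header line
    stop(sprintf("duplicate variant ID '%s' (first duplicate at line %d)",
                 tab$variant_id[which(duplicated(tab$variant_id))[1]], first),
         call. = FALSE)
  }

  de_sentinel <- function(x) ifelse(is.na(x) | x == sentinel | x == "", NA, x)
  variants <- data.frame(
    variant_id = tab$variant_id,
    gene = tab$gene,
    truth = tab$truth,
    evidence = de_sentinel(tab$evidence),
    allele_frequency = as.numeric(de_sentinel(tab$allele_frequency)),
    region = ifelse(is.na(de_sentinel(tab$region)), "unassigned", tab$region),
    stringsAsFactors = FALSE
  )

  n <- nrow(tab)
  calls <- matrix(NA_character_, n, length(tool_names),
                  dimnames = list(NULL, tool_names))
  scores <- matrix(NA_real_, n, length(tool_names),
                   dimnames = list(NULL, tool_names))
  vocab <- lapply(schema$tools, function(t) {
    m <- unlist(t$vocabulary)
    stats::setNames(as.character(m), tolower(trimws(names(m))))
  })
  for (tl in tool_names) {
    spec_t <- schema$tools[[tl]]
    raw <- de_sentinel(tab[[spec_t$call_column]])
    ok <- !is.na(raw)
    if (any(ok)) {
      calls[ok, tl] <- vapply(raw[ok], function(lbl)
        harmonize_label(tl, lbl, vocab), character(1))
    }
    if (!is.null(spec_t$score_column) && spec_t$score_column %in% names(tab)) {
      scores[, tl] <- as.numeric(de_sentinel(tab[[spec_t$score_column]]))
    }
  }
  polarity <- vapply(schema$tools, function(t)
    t$polarity %||% "high_is_damaging", character(1))
  metaserver <- vapply(schema$tools, function(t)
    isTRUE(t$metaserver), logical(1))
  prediction_panel(variants, calls, scores,
                   polarity = stats::setNames(polarity, tool_names),
                   metaserver = stats::setNames(metaserver, tool_names))
}

#' Write a prediction panel to a delimited text file
#'
#' Harmonized calls are written as their own vocabulary
#' (\code{damaging}/\code{tolerated}), so a written panel reads back with
#' the schema returned by [panel_schema()] and the round trip is exact for
#' call labels and stable to printed precision for scores.
#'
#' @param panel A [prediction_panel()].
#' @param path Output file.
#' @param format \code{"tsv"} (default) or \code{"csv"}.
#' @param missing_token Sentinel written for missing cells.
#' @param schema_path Optional path; when given, the matching YAML schema is
#'   written there as well.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path, format = "tsv", missing_token = ".",
                        schema_path = NULL) {
  stopifnot(inherits(panel, "prediction_panel"))
  sep <- if (identical(format, "csv")) "," else "\t"
  out <- panel$variants
  out$allele_frequency <- ifelse(is.na(out$allele_frequency), missing_token,
                                 format(out$allele_frequency, digits = 15,
                                        scientific = FALSE, trim = TRUE))
  for (tl in panel$tools) {
    cc <- panel$calls[, tl]
    sc <- panel$scores[, tl]
    out[[paste0(tl, "_call")]] <- ifelse(is.na(cc), missing_token, cc)
    out[[paste0(tl, "_score")]] <- ifelse(is.na(sc), missing_token,
                                          format(sc, digits = 15,
                                                 scientific = FALSE, trim = TRUE))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema_path)) {
    yaml::write_yaml(panel_schema(panel, format = format,
                                  missing_token = missing_token), schema_path)
  }
  invisible(path)
}

#' Schema config matching [write_panel()]'s column layout
#'
#' @inheritParams write_panel
#' @return Schema list suitable for [read_panel()] (and for
#'   \code{yaml::write_yaml()}).
#' @export
panel_schema <- function(panel, format = "tsv", missing_token = ".") {
  tools <- lapply(panel$tools, function(tl) {
    list(call_column = paste0(tl, "_call"),
         score_column = paste0(tl, "_score"),
         polarity = unname(panel$polarity[tl]),
         metaserver = unname(panel$metaserver[tl]),
         vocabulary = list(damaging = "damaging", tolerated = "tolerated"))
  })
  names(tools) <- panel$tools
  list(format = format, missing_token = missing_token, tools = tools)
}

load_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  if (!is.list(schema) || is.null(schema$tools) || !length(schema$tools)) {
    stop("schema must declare at least one tool", call. = FALSE)
  }
  schema$format <- schema$format %||% "tsv"
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a
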