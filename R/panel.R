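#' Prediction panel constructor
#'
#' A \code{prediction_panel} is the rectangular variants-by-tools container
#' every downstream stage consumes: a variant table (id, gene, truth label,
#' evidence class, optional allele frequency, protein-region annotation),
#' a matrix of harmonized binary calls and a parallel matrix of continuous
#' scores, plus per-tool score polarity and a metaserver flag. Missing tool
#' outputs are kept as \code{NA} cells, never dropped at construction;
#' downstream policies decide how to treat them.
#'
#' @param variants data.frame with columns \code{variant_id}, \code{gene},
#'   \code{truth} (\code{"pathogenic"}/\code{"benign"}), \code{evidence}
#'   (\code{"functional"}, \code{"cosegregation"}, \code{"allele_frequency"}),
#'   \code{allele_frequency} (fraction or NA) and \code{region}
#'   (\code{"n_term"}, \code{"transmembrane"}, \code{"c_term"},
#'   \code{"loop"}, \code{"unassigned"}).
#' @param calls character matrix (variants x tools) with entries
#'   \code{"damaging"}, \code{"tolerated"} or \code{NA}; column names are
#'   the tool names.
#' @param scores numeric matrix of the same shape (or NULL for no scores).
#' @param polarity named character vector per tool,
#'   \code{"high_is_damaging"} or \code{"low_is_damaging"}.
#' @param metaserver named logical vector per tool; metaservers are scored
#'   as single tools and never enter tool committees.
#' @return An object of class \code{prediction_panel}.
#' @seealso [read_panel()], [write_panel()], [generate_panel()]
#' @export
prediction_panel <- function(variants, calls, scores = NULL,
                             polarity = NULL, metaserver = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("variant_id", "gene", "truth", "evidence", "allele_frequency", "region")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols)) {
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  calls <- as.matrix(calls)
  tools <- colnames(calls)
  if (is.null(tools) || anyDuplicated(tools)) {
    stop("call matrix must have unique tool column names", call. = FALSE)
  }
  if (nrow(calls) != nrow(variants)) {
    stop("call matrix rows must match the variant table", call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    dup <- unique(variants$variant_id[duplicated(variants$variant_id)])
    stop("duplicate variant IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(variants$gene) & !nzchar(variants$gene)) || anyNA(variants$gene)) {
    stop("gene symbols must be non-empty", call. = FALSE)
  }
  bad_truth <- setdiff(unique(variants$truth), c("pathogenic", "benign"))
  if (length(bad_truth)) {
    stop("unknown truth labels: ", paste(bad_truth, collapse = ", "), call. = FALSE)
  }
  bad_call <- setdiff(unique(as.vector(calls)), c("damaging", "tolerated", NA))
  if (length(bad_call)) {
    stop("calls must be damaging/tolerated/NA; got: ",
         paste(bad_call, collapse = ", "), call. = FALSE)
  }
  if (is.null(scores)) {
    scores <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!identical(dim(scores), dim(calls))) {
    stop("score matrix must have the same shape as the call matrix", call. = FALSE)
  }
  colnames(scores) <- tools
  if (is.null(polarity)) {
    polarity <- stats::setNames(rep("high_is_damaging", length(tools)), tools)
  }
  if (is.null(metaserver)) {
    metaserver <- stats::setNames(rep(FALSE, length(tools)), tools)
  }
  polarity <- polarity[tools]
  metaserver <- metaserver[tools]
  if (anyNA(polarity) || !all(polarity %in% c("high_is_damaging", "low_is_damaging"))) {
    stop("polarity must be declared for every tool", call. = FALSE)
  }
  rownames(calls) <- rownames(scores) <- variants$variant_id
  structure(
    list(variants = variants, tools = tools, calls = calls, scores = scores,
         polarity = polarity, metaserver = stats::setNames(as.logical(metaserver), tools)),
    class = "prediction_panel"
  )
}

#' @export
print.prediction_panel <- function(x, ...) {
  n_path <- sum(x$variants$truth == "pathogenic")
  cat(sprintf("prediction_panel: %d variants (%d pathogenic / %d benign), %d tools\n",
              nrow(x$variants), n_path, nrow(x$variants) - n_path, length(x$tools)))
  cat("  genes:", paste(sprintf("%s (%d)", names(table(x$variants$gene)),
                                table(x$variants$gene)), collapse = ", "), "\n")
  meta <- x$tools[x$metaserver]
  cat("  tools:", paste(setdiff(x$tools, meta), collapse = ", "), "\n")
  if (length(meta)) cat("  metaservers:", paste(meta, collapse = ", "), "\n")
  n_missing <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d / %d cells\n", n_missing, length(x$calls)))
  invisible(x)
}

#' Inclusion filter on truth-label evidence
#'
#' Variants qualify for the benchmark only when their truth label rests on
#' acceptable evidence: pathogenic variants must be functionally
#' characterised in vitro or supported by family co-segregation; benign
#' variants must be functionally characterised or common in the population
#' (allele frequency strictly greater than 1%).
#'
#' This is a filter, not a validator: every record lands in exactly one of
#' \code{kept} or \code{rejected}, and each rejected record carries a
#' machine-readable reason.
#'
#' @param records data.frame with at least \code{truth}, \code{evidence} and
#'   \code{allele_frequency} columns (e.g. a panel's \code{variants} table).
#' @return list with elements \code{kept} (data.frame) and \code{rejected}
#'   (data.frame with an added \code{reason} column).
#' @examples
#' rec <- data.frame(
#'   variant_id = c("p.A1B", "p.C2D"), truth = c("benign", "benign"),
#'   evidence = "allele_frequency", allele_frequency = c(0.02, 0.005)
#' )
#' apply_inclusion_filter(rec)$rejected$reason
#' @export
apply_inclusion_filter <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"allele_frequency" %in% names(records)) records$allele_frequency <- NA_real_
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    tr <- records$truth[i]; ev <- records$evidence[i]
    af <- records$allele_frequency[i]
    if (tr == "pathogenic") {
      if (!ev %in% c("functional", "cosegregation")) {
        reason[i] <- "pathogenic_requires_functional_or_cosegregation"
      }
    } else if (tr == "benign") {
      if (ev == "functional") {
        # acceptable as-is
      } else if (ev == "allele_frequency") {
        if (is.na(af)) {
          reason[i] <- "benign_allele_frequency_missing"
        } else if (af <= 0.01) {   # strictly greater than 1%
          reason[i] <- "benign_allele_frequency_not_above_0.01"
        }
      } else {
        reason[i] <- "benign_requires_functional_or_allele_frequency"
      }
    } else {
      reason[i] <- "unknown_truth_label"
    }
  }
  keep <- !nzchar(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}
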