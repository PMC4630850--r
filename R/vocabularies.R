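#' Default output vocabularies for the supported prediction tools
#'
#' Each in silico missense predictor reports its verdict in its own
#' vocabulary ("Tolerated"/"Damaging", "Neutral"/"Deleterious",
#' "Neutral"/"Non-neutral", "Disease"/"Neutral", and PolyPhen-2's
#' three-level "Benign"/"Possibly damaging"/"Probably damaging").
#' This function returns the shipped harmonization maps that collapse every
#' native label onto the common binary \code{damaging}/\code{tolerated}
#' vocabulary; in particular both PolyPhen-2 "damaging" grades collapse to
#' \code{damaging}.
#'
#' Users may extend or override the maps: the return value is a plain named
#' list (tool name -> named character vector mapping lower-cased raw label to
#' \code{"damaging"} or \code{"tolerated"}) and any list of the same shape is
#' accepted wherever a \code{vocabulary} argument appears.
#'
#' @return Named list of named character vectors.
#' @examples
#' vocab <- default_vocabularies()
#' names(vocab)
#' vocab[["PolyPhen-2"]]
#' @export
default_vocabularies <- function() {
  list(
    "PolyPhen-2" = c(
      "probably damaging" = "damaging",
      "possibly damaging" = "damaging",
      "benign"            = "tolerated"
    ),
    "SIFT" = c(
      "damaging"  = "damaging",
      "tolerated" = "tolerated"
    ),
    "PROVEAN" = c(
      "deleterious" = "damaging",
      "neutral"     = "tolerated"
    ),
    "SNPs&GO" = c(
      "disease" = "damaging",
      "neutral" = "tolerated"
    ),
    "SNAP" = c(
      "non-neutral" = "damaging",
      "neutral"     = "tolerated"
    ),
    "Meta-SNP" = c(
      "disease" = "damaging",
      "neutral" = "tolerated"
    ),
    "PredictSNP" = c(
      "deleterious" = "damaging",
      "neutral"     = "tolerated"
    )
  )
}

#' Default score polarity for the supported tools
#'
#' SIFT and PROVEAN emit scores where LOW values indicate damage (a SIFT
#' score near 0, a strongly negative PROVEAN score); the probabilistic
#' tools and metaservers emit scores where HIGH values indicate damage.
#'
#' @return Named character vector with values \code{"high_is_damaging"} or
#'   \code{"low_is_damaging"}.
#' @export
default_polarities <- function() {
  c(
    "PolyPhen-2" = "high_is_damaging",
    "SIFT"       = "low_is_damaging",
    "PROVEAN"    = "low_is_damaging",
    "SNPs&GO"    = "high_is_damaging",
    "SNAP"       = "high_is_damaging",
    "Meta-SNP"   = "high_is_damaging",
    "PredictSNP" = "high_is_damaging"
  )
}

#' Harmonize one raw tool label onto the binary call vocabulary
#'
#' Matching is case- and surrounding-whitespace-insensitive. An unknown
#' label for the tool is an error, never a silent coercion: mapping a label
#' the tool cannot emit (say, a PolyPhen-2 grade offered as a SIFT call)
#' almost always means the panel columns are mislabelled.
#'
#' @param tool Tool name (must be a name in \code{vocabulary}).
#' @param raw_label The label as printed by the tool.
#' @param vocabulary Harmonization maps, as from [default_vocabularies()].
#' @return \code{"damaging"} or \code{"tolerated"}.
#' @examples
#' harmonize_label("PolyPhen-2", "Possibly damaging")
#' harmonize_label("SNAP", " non-Neutral ")
#' @export
harmonize_label <- function(tool, raw_label, vocabulary = default_vocabularies()) {
  if (!tool %in% names(vocabulary)) {
    stop(sprintf("no vocabulary declared for tool '%s'", tool), call. = FALSE)
  }
  map <- vocabulary[[tool]]
  key <- tolower(trimws(raw_label))
  if (!key %in% names(map)) {
    stop(sprintf("unknown raw label '%s' for tool '%s' (known: %s)",
                 raw_label, tool, paste(names(map), collapse = ", ")),
         call. = FALSE)
  }
  unname(map[[key]])
}
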