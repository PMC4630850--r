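#' Majority-vote consensus over harmonized binary calls
#'
#' The committee decision over any number of tools: the consensus is
#' \code{damaging} when at least half of the committee calls damaging —
#' equivalently, when \code{2 * n_damaging >= n_tools}. Ties (possible for
#' even committee sizes) are deliberately called damaging: in a diagnostic
#' setting a benign verdict should be the stringent one, so a split
#' committee escalates rather than dismisses. For odd sizes the rule is a
#' plain strict majority.
#'
#' @param calls Character vector of \code{"damaging"}/\code{"tolerated"}
#'   calls. Must be non-empty and contain no missing values; the caller
#'   decides the missing-data policy first (see [apply_combination()]).
#' @return \code{"damaging"} or \code{"tolerated"}.
#' @examples
#' consensus_call(c("damaging", "tolerated"))                 # tie -> damaging
#' consensus_call(c("tolerated", "tolerated", "damaging"))    # majority wins
#' @export
consensus_call <- function(calls) {
  if (length(calls) == 0) stop("consensus over an empty call set", call. = FALSE)
  if (anyNA(calls)) stop("consensus input contains missing calls", call. = FALSE)
  bad <- setdiff(unique(calls), c("damaging", "tolerated"))
  if (length(bad)) stop("unknown calls: ", paste(bad, collapse = ", "), call. = FALSE)
  n_dam <- sum(calls == "damaging")
  if (2L * n_dam >= length(calls)) "damaging" else "tolerated"
}

#' Enumerate tool combinations
#'
#' All subsets of the given tools at the requested sizes, in deterministic
#' order: ascending by size, then lexicographic by the sorted tool names.
#'
#' @param tools Character vector of tool names (no duplicates).
#' @param sizes Integer vector of committee sizes, each in
#'   \code{1..length(tools)}.
#' @return List of character vectors (each sorted); names are the
#'   \code{"+"}-joined tool names used throughout reports.
#' @examples
#' length(enumerate_combinations(letters[1:5], 2:5))   # 10 + 10 + 5 + 1 = 26
#' @export
enumerate_combinations <- function(tools, sizes) {
  if (anyDuplicated(tools)) stop("duplicate tool names", call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L | sizes > length(tools))) {
    stop(sprintf("combination sizes must lie in 1..%d", length(tools)),
         call. = FALSE)
  }
  tools <- sort(tools)
  out <- list()
  for (s in sizes) {
    combos <- utils::combn(tools, s, simplify = FALSE)
    # combn on sorted input already yields lexicographic order
    out <- c(out, combos)
  }
  names(out) <- vapply(out, paste, character(1), collapse = "+")
  out
}

#' Apply a tool combination to every variant of a panel
#'
#' Computes the per-variant consensus call for one committee, together with
#' the mask of evaluable variants under the chosen missing-data policy:
#' \describe{
#'   \item{\code{"exclude"} (default)}{a variant with any missing call among
#'     the committee tools is masked out of that combination's confusion
#'     matrix;}
#'   \item{\code{"reduce"}}{the vote runs on the non-missing subset (size
#'     >= 1) under the same tie rule; only variants missing every committee
#'     call are masked.}
#' }
#'
#' @param panel A [prediction_panel()].
#' @param combo Character vector of tool names, a subset of
#'   \code{panel$tools}.
#' @param missing_policy \code{"exclude"} or \code{"reduce"}.
#' @return List with \code{call} (character vector, NA where masked) and
#'   \code{mask} (logical vector of evaluable variants).
#' @export
apply_combination <- function(panel, combo, missing_policy = c("exclude", "reduce")) {
  stopifnot(inherits(panel, "prediction_panel"))
  missing_policy <- match.arg(missing_policy)
  if (!all(combo %in% panel$tools)) {
    stop("combination names tools absent from the panel: ",
         paste(setdiff(combo, panel$tools), collapse = ", "), call. = FALSE)
  }
  sub <- panel$calls[, combo, drop = FALSE]
  n_miss <- unname(rowSums(is.na(sub)))
  mask <- if (missing_policy == "exclude") n_miss == 0L else n_miss < length(combo)
  call <- rep(NA_character_, nrow(sub))
  for (i in which(mask)) {
    v <- sub[i, ]
    call[i] <- consensus_call(v[!is.na(v)])
  }
  list(call = call, mask = mask)
}
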