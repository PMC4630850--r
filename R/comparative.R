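#' Phi coefficient between two binary call vectors
#'
#' The phi coefficient is the Pearson correlation of the 0/1 encodings,
#' computed here from the closed 2x2-table form
#' \eqn{(ad - bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}}. It is used to check that
#' no pair of tools is so strongly associated that a committee of them is
#' redundant. Pairs with a missing call in either vector are excluded.
#'
#' @param calls_a,calls_b Character vectors of
#'   \code{"damaging"}/\code{"tolerated"} (NA allowed, excluded pairwise).
#' @return Phi in \[-1, 1\], or \code{NA} when either vector is constant on
#'   the complete pairs (the coefficient is then undefined).
#' @export
phi_association <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(calls_a) & !is.na(calls_b)
  x <- calls_a[ok] == "damaging"
  y <- calls_b[ok] == "damaging"
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  den <- sqrt(prod(as.numeric(c(a + b, c + d, a + c, b + d))))
  if (den == 0) return(NA_real_)
  (as.numeric(a) * d - as.numeric(b) * c) / den
}

#' Pairwise association matrix over a panel's tools
#'
#' @param panel A [prediction_panel()].
#' @param method \code{"phi"} on harmonized binary calls (default — the
#'   committee-redundancy question is about the calls), or
#'   \code{"spearman"} on raw continuous scores.
#' @param tools Tools to include (default: all panel tools).
#' @return Symmetric numeric matrix with unit diagonal, class
#'   \code{association_matrix}.
#' @export
association_matrix <- function(panel, method = c("phi", "spearman"),
                               tools = panel$tools) {
  stopifnot(inherits(panel, "prediction_panel"))
  method <- match.arg(method)
  k <- length(tools)
  m <- matrix(NA_real_, k, k, dimnames = list(tools, tools))
  diag(m) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    v <- if (method == "phi") {
      phi_association(panel$calls[, tools[i]], panel$calls[, tools[j]])
    } else {
      si <- panel$scores[, tools[i]]; sj <- panel$scores[, tools[j]]
      ok <- !is.na(si) & !is.na(sj)
      if (sum(ok) < 3) NA_real_ else
        suppressWarnings(stats::cor(si[ok], sj[ok], method = "spearman"))
    }
    m[i, j] <- m[j, i] <- v
  }
  structure(m, class = c("association_matrix", class(m)))
}

#' Kruskal-Wallis comparison of accuracy observations across groups
#'
#' Rank-based one-way comparison with mid-rank tie correction and the
#' chi-squared approximation for the p-value, delegated to
#' \code{stats::kruskal.test}. The sampling unit is chosen by the caller:
#' [accuracy_observations()] produces the default per-variant correctness
#' indicators (1 = correct call, 0 = incorrect) grouped by tool
#' combination, which is the only reading giving the test non-trivial
#' group sizes; a per-gene-accuracy mode is available there too.
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups, each non-empty.
#' @return List with \code{statistic} (H), \code{df}, \code{p_value},
#'   \code{groups} (data.frame of labels and sizes).
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))$statistic
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(!lengths(groups))) stop("every group must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  if (length(unique(values)) == 1L) {
    # all observations identical: every rank tied, no evidence of difference
    ht <- list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    ht <- stats::kruskal.test(values, factor(labels))
  }
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  list(statistic = unname(as.numeric(ht$statistic)),
       df = unname(as.integer(ht$parameter)),
       p_value = unname(as.numeric(ht$p.value)),
       groups = data.frame(label = nm, n = lengths(groups), row.names = NULL))
}

#' Per-combination accuracy observations for [kruskal_wallis()]
#'
#' @param panel A [prediction_panel()].
#' @param combos List of tool combinations (see [enumerate_combinations()]).
#' @param unit \code{"variant"}: one 0/1 correctness indicator per
#'   evaluable variant per combination (default); \code{"gene"}: one
#'   accuracy percentage per gene per combination.
#' @param missing_policy Passed to [apply_combination()].
#' @return Named list of numeric vectors, one per combination.
#' @export
accuracy_observations <- function(panel, combos, unit = c("variant", "gene"),
                                  missing_policy = "exclude") {
  stopifnot(inherits(panel, "prediction_panel"))
  unit <- match.arg(unit)
  truths <- panel$variants$truth
  out <- lapply(combos, function(combo) {
    ap <- apply_combination(panel, combo, missing_policy)
    correct <- (ap$call == "damaging") == (truths == "pathogenic")
    if (unit == "variant") {
      as.numeric(correct[ap$mask])
    } else {
      vapply(split(seq_along(truths)[ap$mask], panel$variants$gene[ap$mask]),
             function(idx) 100 * mean(correct[idx]), numeric(1))
    }
  })
  names(out) <- names(combos) %||%
    vapply(combos, paste, character(1), collapse = "+")
  out
}
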