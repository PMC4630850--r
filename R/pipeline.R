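#' Collapse protein-region annotations into coarse strata
#'
#' The region subanalysis groups variants into the amino-/carboxyl-termini
#' plus transmembrane domains (\code{"ntmc"}) versus the inter-domain loop
#' regions (\code{"loop"}); \code{"unassigned"} stays unassigned.
#'
#' @param region Character vector of fine region labels.
#' @param collapse_map Named vector fine -> coarse.
#' @return Character vector of coarse labels.
#' @export
collapse_regions <- function(region,
                             collapse_map = c(n_term = "ntmc",
                                              transmembrane = "ntmc",
                                              c_term = "ntmc",
                                              loop = "loop",
                                              unassigned = "unassigned")) {
  unknown <- setdiff(unique(region), names(collapse_map))
  if (length(unknown)) {
    stop("regions without a collapse entry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(collapse_map[region])
}

# Build the stratum list: named list of row masks over the panel.
build_strata <- function(panel, strata = c("gene", "pooled"),
                         region_gene = "SCN5A") {
  v <- panel$variants
  out <- list()
  if ("gene" %in% strata) {
    for (g in sort(unique(v$gene))) out[[g]] <- v$gene == g
  }
  if ("pooled" %in% strata) out[["all"]] <- rep(TRUE, nrow(v))
  if ("region" %in% strata) {
    coarse <- collapse_regions(v$region)
    for (r in c("ntmc", "loop")) {
      sel <- v$gene == region_gene & coarse == r
      if (any(sel)) out[[paste(region_gene, r, sep = ":")]] <- sel
    }
  }
  out
}

#' Evaluate every tool combination on every stratum
#'
#' Runs the full benchmark grid: each committee (all subsets of the
#' non-metaserver tools at the requested sizes) and each metaserver (as a
#' single-column committee, never mixed into tool committees) is scored on
#' each stratum — per gene, pooled across genes, and optionally per
#' collapsed protein region of one gene.
#'
#' A stratum lacking one truth class gets undefined-sentinel (\code{NA})
#' metrics with a warning; the run continues.
#'
#' @param panel A [prediction_panel()].
#' @param sizes Committee sizes over the non-metaserver tools.
#' @param strata Any of \code{"gene"}, \code{"pooled"}, \code{"region"}.
#' @param region_gene Gene whose region split is evaluated when
#'   \code{"region"} is requested.
#' @param missing_policy Passed to [apply_combination()].
#' @return data.frame of class \code{combo_evaluation}: one row per
#'   (combination, stratum) with the confusion counts, the metric battery
#'   at full precision, committee size and \code{n_evaluated}. Rows are in
#'   deterministic order (stratum, then size, then combination name).
#' @export
evaluate_all <- function(panel, sizes = 1:5,
                         strata = c("gene", "pooled"),
                         region_gene = "SCN5A",
                         missing_policy = "exclude") {
  stopifnot(inherits(panel, "prediction_panel"))
  base_tools <- panel$tools[!panel$metaserver]
  sizes <- sizes[sizes <= length(base_tools)]
  combos <- enumerate_combinations(base_tools, sizes)
  metas <- panel$tools[panel$metaserver]
  combos <- c(combos, stats::setNames(as.list(metas), metas))
  stratum_masks <- build_strata(panel, strata, region_gene)

  truths <- panel$variants$truth
  rows <- vector("list", length(combos) * length(stratum_masks))
  i <- 0L
  for (st in names(stratum_masks)) {
    sel <- stratum_masks[[st]]
    if (!any(truths[sel] == "pathogenic") || !any(truths[sel] == "benign")) {
      warning(sprintf("stratum '%s' lacks a truth class; metrics undefined", st))
    }
    for (cn in names(combos)) {
      combo <- combos[[cn]]
      ap <- apply_combination(panel, combo, missing_policy)
      cm <- confusion(ap$call, truths, ap$mask & sel)
      ms <- metric_set(cm)
      i <- i + 1L
      rows[[i]] <- data.frame(
        combination = cn, size = length(combo),
        metaserver = length(combo) == 1L && combo %in% metas,
        stratum = st,
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        n_evaluated = cm$tp + cm$fp + cm$tn + cm$fn,
        accuracy = ms$accuracy, sensitivity = ms$sensitivity,
        specificity = ms$specificity, mcc = ms$mcc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("combo_evaluation", class(out))
  out
}

#' Rank combinations within one stratum by MCC
#'
#' Combinations are chosen by MCC — the balanced view of how well both
#' pathogenic and benign variants are classified — not by raw accuracy,
#' which class imbalance inflates. Ties break toward fewer tools, then
#' higher specificity, then lexicographic name; undefined MCC sorts last.
#'
#' @param evals Result of [evaluate_all()].
#' @param stratum Stratum label to rank within.
#' @return The matching rows, ranked.
#' @export
rank_by_mcc <- function(evals, stratum) {
  e <- evals[evals$stratum == stratum, , drop = FALSE]
  if (!nrow(e)) stop("no evaluations for stratum '", stratum, "'", call. = FALSE)
  und <- is.na(e$mcc)
  o <- order(und,                       # defined MCC first
             -ifelse(und, -Inf, e$mcc),
             e$size,
             -ifelse(is.na(e$specificity), -Inf, e$specificity),
             e$combination)
  out <- e[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC summary for every single tool and metaserver on every stratum
#'
#' @inheritParams evaluate_all
#' @param level Confidence level for the DeLong interval.
#' @return data.frame with one row per (tool, stratum): AUC, CI bounds,
#'   direction and class sizes. Tools or strata where the ROC is undefined
#'   (single truth class, no scores) are reported with NA and a warning.
#' @export
roc_summary <- function(panel, strata = c("gene", "pooled"),
                        region_gene = "SCN5A", level = 0.95) {
  stopifnot(inherits(panel, "prediction_panel"))
  stratum_masks <- build_strata(panel, strata, region_gene)
  truths <- panel$variants$truth
  rows <- list()
  for (st in names(stratum_masks)) {
    sel <- stratum_masks[[st]]
    for (tl in panel$tools) {
      sc <- panel$scores[sel, tl]
      tr <- truths[sel]
      row <- data.frame(tool = tl, stratum = st, auc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        direction = unname(panel$polarity[tl]),
                        n_pos = sum(tr == "pathogenic" & !is.na(sc)),
                        n_neg = sum(tr == "benign" & !is.na(sc)),
                        stringsAsFactors = FALSE)
      ok <- tryCatch({
        roc <- roc_curve(sc, tr, polarity = panel$polarity[tl], stratum = st)
        ci <- suppressWarnings(delong_ci(roc, level))
        row$auc <- roc$auc; row$ci_low <- ci$ci_low; row$ci_high <- ci$ci_high
        TRUE
      }, error = function(e) {
        warning(sprintf("ROC undefined for %s on '%s': %s",
                        tl, st, conditionMessage(e)))
        FALSE
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Run the full evaluation and write the report files
#'
#' Orchestrates one benchmark run: obtain the panel (from a TSV + schema or
#' by simulation from a config), evaluate every combination on every
#' stratum, compute per-tool ROC summaries and the inter-tool association
#' matrix, and write four files into \code{out_dir}:
#' \describe{
#'   \item{\code{combo_evaluations.tsv}}{all combination-by-stratum metrics
#'     at full precision;}
#'   \item{\code{roc_summary.tsv}}{AUC + DeLong CI per single
#'     tool/metaserver per stratum;}
#'   \item{\code{association_matrix.tsv}}{symmetric phi matrix;}
#'   \item{\code{manifest.json}}{run configuration, seed, package version,
#'     warnings.}
#' }
#' Re-running with identical inputs reproduces the TSVs byte for byte.
#'
#' @param panel_path Panel TSV (requires \code{schema}); exclusive with
#'   \code{sim_config}.
#' @param schema Schema for [read_panel()].
#' @param sim_config A [simulation_config()] (or YAML path) to simulate
#'   from.
#' @param out_dir Output directory (created if needed).
#' @param sizes,strata,region_gene,missing_policy Passed to
#'   [evaluate_all()].
#' @param verbose Print progress lines.
#' @return Invisibly, a list with the evaluation table, ROC summary,
#'   association matrix and manifest.
#' @export
run_report <- function(panel_path = NULL, schema = NULL, sim_config = NULL,
                       out_dir, sizes = 1:5, strata = c("gene", "pooled"),
                       region_gene = "SCN5A", missing_policy = "exclude",
                       verbose = TRUE) {
  if (is.null(panel_path) == is.null(sim_config)) {
    stop("give exactly one of panel_path or sim_config", call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  warnings_seen <- character()
  withCallingHandlers({
    if (!is.null(panel_path)) {
      if (is.null(schema)) stop("panel_path requires a schema", call. = FALSE)
      say("reading panel from %s", panel_path)
      panel <- read_panel(panel_path, schema)
      source_desc <- list(type = "file", path = panel_path)
    } else {
      if (is.character(sim_config)) sim_config <- read_simulation_config(sim_config)
      say("simulating panel (seed %d)", sim_config$seed)
      panel <- generate_panel(sim_config)
      source_desc <- list(type = "simulation", seed = sim_config$seed,
                          rho = sim_config$rho,
                          missing_rate = sim_config$missing_rate)
    }
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

    say("evaluating %d tools on %d variants", length(panel$tools),
        nrow(panel$variants))
    evals <- evaluate_all(panel, sizes, strata, region_gene, missing_policy)
    rocs <- roc_summary(panel, strata, region_gene)
    assoc <- association_matrix(panel)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  write_tsv <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
      ifelse(is.na(x), NA, format(x, digits = 15, scientific = FALSE,
                                  trim = TRUE)))
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA",
                       fileEncoding = "UTF-8")
  }
  write_tsv(as.data.frame(evals), "combo_evaluations.tsv")
  write_tsv(rocs, "roc_summary.tsv")
  assoc_df <- data.frame(tool = rownames(assoc),
                         as.data.frame(unclass(assoc), check.names = FALSE),
                         check.names = FALSE)
  write_tsv(assoc_df, "association_matrix.tsv")

  manifest <- list(
    package = "predvote",
    version = as.character(utils::packageVersion("predvote")),
    source = source_desc,
    options = list(sizes = sizes, strata = strata, region_gene = region_gene,
                   missing_policy = missing_policy),
    n_variants = nrow(panel$variants), tools = panel$tools,
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("report written to %s", out_dir)
  invisible(list(evaluations = evals, roc = rocs, association = assoc,
                 manifest = manifest, panel = panel))
}
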