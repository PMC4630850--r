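#' Simulation configuration for synthetic predictor panels
#'
#' Describes a benchmark panel statistically: per-gene class sizes, per-tool
#' operating characteristics (sensitivity on pathogenic variants,
#' specificity on benign ones), a single inter-tool dependence knob
#' \code{rho}, per-tool score separation and polarity, region proportions
#' and a missing-call rate. The seed is mandatory: panels are fully
#' reproducible.
#'
#' @param genes data.frame with columns \code{gene}, \code{n_pathogenic},
#'   \code{n_benign}.
#' @param tools data.frame with columns \code{tool}, \code{sensitivity},
#'   \code{specificity} (each in \[0,1\]), \code{polarity}
#'   (\code{high_is_damaging}/\code{low_is_damaging}), \code{separation}
#'   (>= 0; governs how well the continuous score separates the classes)
#'   and \code{metaserver} (logical).
#' @param rho Inter-tool dependence in \[0, 1): the share of each tool's
#'   latent error variable contributed by a per-variant shared difficulty
#'   term (Gaussian copula). 0 means conditionally independent tools.
#' @param missing_rate Probability that any (variant, tool) cell is
#'   missing, in \[0, 1).
#' @param region_props Named probabilities over
#'   \code{n_term}/\code{transmembrane}/\code{c_term}/\code{loop}.
#' @param seed Integer seed.
#' @return Object of class \code{simulation_config}.
#' @seealso [generate_panel()], [lqts_replica_config()]
#' @export
simulation_config <- function(genes, tools, rho = 0, missing_rate = 0,
                              region_props = c(n_term = 0.15,
                                               transmembrane = 0.35,
                                               c_term = 0.15, loop = 0.35),
                              seed) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  tools <- as.data.frame(tools, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "n_pathogenic", "n_benign") %in% names(genes)),
            all(c("tool", "sensitivity", "specificity") %in% names(tools)))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(genes$n_pathogenic < 0 | genes$n_benign < 0)) {
    stop("class sizes must be non-negative", call. = FALSE)
  }
  probs <- c(tools$sensitivity, tools$specificity)
  if (any(probs < 0 | probs > 1)) {
    stop("sensitivity/specificity must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(tools$tool)) stop("duplicate tool names", call. = FALSE)
  if (is.null(tools$polarity)) tools$polarity <- "high_is_damaging"
  if (is.null(tools$separation)) tools$separation <- 3
  if (is.null(tools$metaserver)) tools$metaserver <- FALSE
  region_props <- region_props / sum(region_props)
  structure(list(genes = genes, tools = tools, rho = rho,
                 missing_rate = missing_rate, region_props = region_props,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic prediction panel
#'
#' Latent-difficulty model with exact marginal control: every variant draws
#' a shared standard-normal difficulty \eqn{z}; tool \eqn{t} errs on it iff
#' \eqn{\sqrt{\rho}\, z + \sqrt{1-\rho}\, \epsilon_t > \Phi^{-1}(p_t)},
#' where \eqn{p_t} is the tool's sensitivity for pathogenic variants and
#' specificity for benign ones and \eqn{\epsilon_t} is tool-specific noise.
#' The left side is standard normal for every \eqn{\rho}, so each tool's
#' marginal correctness rate equals its configured \eqn{p_t} exactly, while
#' \eqn{\rho > 0} makes tools err together on hard variants (positive
#' pairwise phi). Continuous scores are drawn conditional on the emitted
#' call — damaging calls from Beta(2 + separation, 2), tolerated calls from
#' Beta(2, 2 + separation) on the damagingness scale — which guarantees
#' call/score consistency and makes the score AUC increase with the
#' separation parameter; \code{low_is_damaging} tools then report
#' \code{1 - score}. Missing cells are masked uniformly at random.
#'
#' The caller's RNG state is untouched: all randomness flows from the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return A [prediction_panel()] whose variant table carries truth,
#'   evidence, allele-frequency and region annotations consistent with the
#'   inclusion filter.
#' @examples
#' cfg <- lqts_replica_config(seed = 1)
#' panel <- generate_panel(cfg)
#' panel
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  genes <- config$genes; tools <- config$tools
  truth <- unlist(lapply(seq_len(nrow(genes)), function(i)
    rep(c("pathogenic", "benign"),
        c(genes$n_pathogenic[i], genes$n_benign[i]))), use.names = FALSE)
  gene <- unlist(lapply(seq_len(nrow(genes)), function(i)
    rep(genes$gene[i], genes$n_pathogenic[i] + genes$n_benign[i])),
    use.names = FALSE)
  n <- length(truth)
  if (n == 0) stop("configuration yields an empty panel", call. = FALSE)

  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  pos <- integer(n)
  for (g in unique(gene)) {
    idx <- which(gene == g)
    # sampled without replacement: positions unique within a gene, so HGVS
    # ids are unique within the panel
    pos[idx] <- sort(sample.int(20L * length(idx), length(idx)))
  }
  variant_id <- sprintf("%s:p.%s%d%s", gene, sample(aa, n, TRUE), pos,
                        sample(aa, n, TRUE))
  region <- sample(names(config$region_props), n, TRUE,
                   prob = config$region_props)

  evidence <- ifelse(truth == "pathogenic",
                     sample(c("functional", "cosegregation"), n, TRUE,
                            prob = c(0.7, 0.3)),
                     sample(c("functional", "allele_frequency"), n, TRUE,
                            prob = c(0.5, 0.5)))
  allele_frequency <- rep(NA_real_, n)
  af_idx <- evidence == "allele_frequency" & truth == "benign"
  allele_frequency[af_idx] <- stats::runif(sum(af_idx), 0.011, 0.20)

  k <- nrow(tools)
  z <- stats::rnorm(n)
  calls <- matrix(NA_character_, n, k, dimnames = list(NULL, tools$tool))
  scores <- matrix(NA_real_, n, k, dimnames = list(NULL, tools$tool))
  sq_rho <- sqrt(config$rho); sq_com <- sqrt(1 - config$rho)
  for (t in seq_len(k)) {
    p_correct <- ifelse(truth == "pathogenic",
                        tools$sensitivity[t], tools$specificity[t])
    err <- sq_rho * z + sq_com * stats::rnorm(n) > stats::qnorm(p_correct)
    truth_call <- ifelse(truth == "pathogenic", "damaging", "tolerated")
    flip_call <- ifelse(truth == "pathogenic", "tolerated", "damaging")
    calls[, t] <- ifelse(err, flip_call, truth_call)
    sep <- tools$separation[t]
    dam <- calls[, t] == "damaging"
    s <- numeric(n)
    s[dam] <- stats::rbeta(sum(dam), 2 + sep, 2)
    s[!dam] <- stats::rbeta(sum(!dam), 2, 2 + sep)
    if (identical(tools$polarity[t], "low_is_damaging")) s <- 1 - s
    scores[, t] <- s
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * k) < config$missing_rate, n, k)
    calls[mask] <- NA_character_
    scores[mask] <- NA_real_
  }

  variants <- data.frame(variant_id = variant_id, gene = gene, truth = truth,
                         evidence = evidence,
                         allele_frequency = allele_frequency,
                         region = region, stringsAsFactors = FALSE)
  prediction_panel(variants, calls, scores,
                   polarity = stats::setNames(tools$polarity, tools$tool),
                   metaserver = stats::setNames(tools$metaserver, tools$tool))
}

#' Shipped three-gene LQTS benchmark configuration
#'
#' The default synthetic stand-in for a long QT syndrome variant benchmark:
#' three genes with the canonical class sizes (KCNQ1 101 pathogenic / 8
#' benign, KCNH2 82/8, SCN5A 99/14 — 312 variants in total), the five
#' commonly used missense predictors plus two metaserver columns, moderate
#' positive inter-tool dependence, tool-typical score polarities, and a
#' small missing-call rate. Per-tool sensitivity/specificity are free
#' parameters of the emulation: values are chosen to reflect the familiar
#' pattern of high-sensitivity, modest-specificity predictors with
#' metaservers somewhat better calibrated; see the package vignette for the
#' rationale.
#'
#' @param seed Integer seed (default 101).
#' @return A [simulation_config()].
#' @export
lqts_replica_config <- function(seed = 101) {
  genes <- data.frame(
    gene = c("KCNQ1", "KCNH2", "SCN5A"),
    n_pathogenic = c(101L, 82L, 99L),
    n_benign = c(8L, 8L, 14L)
  )
  tools <- data.frame(
    tool = c("PolyPhen-2", "SIFT", "PROVEAN", "SNPs&GO", "SNAP",
             "Meta-SNP", "PredictSNP"),
    sensitivity = c(0.92, 0.88, 0.90, 0.85, 0.90, 0.90, 0.87),
    specificity = c(0.55, 0.70, 0.72, 0.75, 0.45, 0.78, 0.70),
    polarity = unname(default_polarities()[c("PolyPhen-2", "SIFT", "PROVEAN",
                                             "SNPs&GO", "SNAP", "Meta-SNP",
                                             "PredictSNP")]),
    separation = c(2.5, 2.5, 3.0, 2.5, 1.5, 3.5, 2.0),
    metaserver = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  simulation_config(genes, tools, rho = 0.3, missing_rate = 0.02, seed = seed)
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file.
#' @return [read_simulation_config()] returns a [simulation_config()];
#'   [write_simulation_config()] returns \code{path} invisibly.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation_config(
    genes = do.call(rbind, lapply(y$genes, as.data.frame)),
    tools = do.call(rbind, lapply(y$tools, as.data.frame)),
    rho = y$rho %||% 0,
    missing_rate = y$missing_rate %||% 0,
    region_props = if (!is.null(y$region_props)) unlist(y$region_props)
                   else c(n_term = 0.15, transmembrane = 0.35,
                          c_term = 0.15, loop = 0.35),
    seed = y$seed
  )
}

#' @rdname read_simulation_config
#' @param config A [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  y <- list(
    genes = lapply(seq_len(nrow(config$genes)), function(i)
      as.list(config$genes[i, ])),
    tools = lapply(seq_len(nrow(config$tools)), function(i)
      as.list(config$tools[i, ])),
    rho = config$rho, missing_rate = config$missing_rate,
    region_props = as.list(config$region_props), seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
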