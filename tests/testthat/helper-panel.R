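# Small deterministic fixtures built in code.

# A 6-variant, 3-tool panel with one missing cell and mixed polarities.
make_toy_panel <- function() {
  variants <- data.frame(
    variant_id = c("KCNQ1:p.Ala341Val", "KCNQ1:p.Gly189Arg",
                   "KCNH2:p.Tyr616Cys", "KCNH2:p.Arg1047Leu",
                   "SCN5A:p.Glu1784Lys", "SCN5A:p.His558Arg"),
    gene = c("KCNQ1", "KCNQ1", "KCNH2", "KCNH2", "SCN5A", "SCN5A"),
    truth = c("pathogenic", "benign", "pathogenic", "benign",
              "pathogenic", "benign"),
    evidence = c("functional", "functional", "cosegregation",
                 "allele_frequency", "functional", "allele_frequency"),
    allele_frequency = c(NA, NA, NA, 0.03, NA, 0.2),
    region = c("transmembrane", "n_term", "loop", "c_term",
               "c_term", "loop"),
    stringsAsFactors = FALSE
  )
  calls <- matrix(
    c("damaging",  "damaging",  "damaging",
      "tolerated", "tolerated", "damaging",
      "damaging",  "tolerated", "damaging",
      "tolerated", "damaging",  NA,
      "damaging",  "damaging",  "tolerated",
      "tolerated", "tolerated", "tolerated"),
    nrow = 6, byrow = TRUE,
    dimnames = list(NULL, c("SIFT", "PROVEAN", "SNAP"))
  )
  scores <- matrix(
    c(0.01, -4.2, 0.9,
      0.80,  1.1, 0.6,
      0.02, -2.5, 0.7,
      0.65, -3.0, NA,
      0.04, -5.0, 0.2,
      0.90,  0.5, 0.1),
    nrow = 6, byrow = TRUE,
    dimnames = list(NULL, c("SIFT", "PROVEAN", "SNAP"))
  )
  prediction_panel(
    variants, calls, scores,
    polarity = c(SIFT = "low_is_damaging", PROVEAN = "low_is_damaging",
                 SNAP = "high_is_damaging"),
    metaserver = c(SIFT = FALSE, PROVEAN = FALSE, SNAP = FALSE)
  )
}

# Literal transcription of the per-size voting rule table (unanimity rows
# plus the enumerated split rows), kept independent of consensus_call():
# size 1: damaging iff the single call is damaging
# size 2: damaging iff at least one output is damaging
# size 3: damaging iff at least two outputs are damaging
# size 4: damaging iff at least two outputs are damaging
#         (three tolerated -> tolerated)
# size 5: damaging iff at least three outputs are damaging
#         (three tolerated -> tolerated)
rule_table_oracle <- function(calls) {
  d <- sum(calls == "damaging")
  threshold <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 3L)
  if (d >= threshold[[as.character(length(calls))]]) "damaging" else "tolerated"
}

# Pair-counting Mann-Whitney AUC oracle: every (pathogenic, benign) pair,
# wins count 1, ties count 1/2.
pair_count_auc <- function(scores, truths) {
  x <- scores[truths == "pathogenic"]
  y <- scores[truths == "benign"]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}
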