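test_that("harmonization collapses native vocabularies onto damaging/tolerated", {
  cases <- list(
    list("PolyPhen-2", "Possibly damaging", "damaging"),
    list("PolyPhen-2", "Probably damaging", "damaging"),
    list("PolyPhen-2", "Benign", "tolerated"),
    list("SNAP", "Non-neutral", "damaging"),
    list("SNAP", "Neutral", "tolerated"),
    list("PROVEAN", "Neutral", "tolerated"),
    list("PROVEAN", "Deleterious", "damaging"),
    list("SNPs&GO", "Disease", "damaging"),
    list("Meta-SNP", "Disease", "damaging"),
    list("PredictSNP", "Deleterious", "damaging"),
    list("SIFT", "Tolerated", "tolerated")
  )
  for (cs in cases) {
    expect_identical(harmonize_label(cs[[1]], cs[[2]]), cs[[3]])
  }
})

test_that("harmonization is case/whitespace insensitive but rejects unknown labels", {
  expect_identical(harmonize_label("SIFT", "  DAMAGING "), "damaging")
  expect_error(harmonize_label("SIFT", "Probably damaging"),
               "unknown raw label.*SIFT")
  expect_error(harmonize_label("NotATool", "Damaging"), "no vocabulary")
})

test_that("inclusion filter applies the evidence and allele-frequency criteria", {
  rec <- data.frame(
    variant_id = paste0("v", 1:6),
    truth = c("benign", "benign", "pathogenic", "pathogenic",
              "benign", "benign"),
    evidence = c("allele_frequency", "allele_frequency", "cosegregation",
                 "functional", "functional", "allele_frequency"),
    allele_frequency = c(0.02, 0.005, NA, NA, NA, 0.01),
    stringsAsFactors = FALSE
  )
  res <- apply_inclusion_filter(rec)
  expect_setequal(res$kept$variant_id, c("v1", "v3", "v4", "v5"))
  # 0.01 itself fails: threshold is strictly greater than 1%
  expect_setequal(res$rejected$variant_id, c("v2", "v6"))
  expect_true(all(res$rejected$reason == "benign_allele_frequency_not_above_0.01"))
})

test_that("filter output partitions the input", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    rec <- data.frame(
      variant_id = paste0("v", seq_len(n)),
      truth = sample(c("pathogenic", "benign"), n, TRUE),
      evidence = sample(c("functional", "cosegregation", "allele_frequency"),
                        n, TRUE),
      allele_frequency = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.1)),
      stringsAsFactors = FALSE
    )
    res <- apply_inclusion_filter(rec)
    expect_equal(nrow(res$kept) + nrow(res$rejected), n)
    expect_length(intersect(res$kept$variant_id, res$rejected$variant_id), 0)
    expect_true(all(nzchar(res$rejected$reason)))
  }
})

test_that("panel TSV round-trip is stable for calls and scores", {
  panel <- make_toy_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  schema_path <- withr::local_tempfile(fileext = ".yaml")
  write_panel(panel, path, schema_path = schema_path)
  p2 <- read_panel(path, schema_path)

  expect_identical(unname(p2$calls), unname(panel$calls))
  expect_identical(p2$variants$variant_id, panel$variants$variant_id)
  expect_identical(p2$polarity, panel$polarity)
  expect_lt(max(abs(p2$scores - panel$scores), na.rm = TRUE), 1e-12)
  expect_identical(is.na(p2$scores), is.na(panel$scores))

  # write(read(x)) is byte-identical to write(x)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("missing cells use the sentinel token and read back as missing", {
  panel <- make_toy_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  lines <- readLines(path)
  expect_true(any(grepl("\t\\.\t", lines)))   # sentinel present on disk
  p2 <- read_panel(path, panel_schema(panel))
  expect_true(is.na(p2$calls[4, "SNAP"]))
})

test_that("parser rejects duplicate IDs, ragged rows and undeclared columns", {
  panel <- make_toy_panel()
  schema <- panel_schema(panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)

  lines <- readLines(path)
  dup <- c(lines, lines[2])
  dup_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(dup, dup_path)
  expect_error(read_panel(dup_path, schema), "duplicate variant ID.*line")

  ragged <- lines
  ragged[3] <- paste0(lines[3], "\textra")
  ragged_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(ragged, ragged_path)
  expect_error(read_panel(ragged_path, schema), "ragged row.*line 3")

  extra <- sub("^variant_id", "mystery\tvariant_id", lines[1])
  extra_lines <- c(extra, vapply(lines[-1], function(l) paste0("x\t", l), ""))
  extra_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(extra_lines, extra_path)
  expect_error(read_panel(extra_path, schema), "undeclared column")
})

test_that("panel constructor enforces rectangular shape and unique ids", {
  panel <- make_toy_panel()
  v <- panel$variants
  expect_error(prediction_panel(v, panel$calls[-1, ]), "rows must match")
  v2 <- v; v2$variant_id[2] <- v2$variant_id[1]
  expect_error(prediction_panel(v2, panel$calls), "duplicate variant ID")
  calls2 <- panel$calls; colnames(calls2) <- c("SIFT", "SIFT", "SNAP")
  expect_error(prediction_panel(v, calls2), "unique tool")
})
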