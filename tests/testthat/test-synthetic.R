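test_that("generation is deterministic per seed with the requested counts", {
  a <- generate_sequences(10, 20, seed = 42)
  b <- generate_sequences(10, 20, seed = 42)
  c_ <- generate_sequences(10, 20, seed = 43)
  expect_length(a, 30L)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_equal(sum(stackrp:::record_labels(a) == 1L), 10L)
})

test_that("sequences respect the alphabet and length range", {
  recs <- generate_sequences(15, 15, length_range = c(150, 400), seed = 2)
  alphabet <- rownames(recm_table())
  for (r in recs) {
    expect_true(all(strsplit(r$sequence, "")[[1]] %in% alphabet))
    expect_gte(nchar(r$sequence), 150)
    expect_lte(nchar(r$sequence), 400)
  }
})

test_that("residue composition converges to the specified mixture", {
  # at full signal the boosted residues sit at 0.125 each, background 1/20
  recs <- generate_sequences(200, 200, length_range = c(150, 300),
                             signal = 1, seed = 3)
  y <- stackrp:::record_labels(recs)
  freq_of <- function(rr) {
    pooled <- paste(vapply(rr, `[[`, "", "sequence"), collapse = "")
    tab <- table(strsplit(pooled, "")[[1]])
    as.numeric(tab["L"] / sum(tab))
  }
  expect_lt(abs(freq_of(recs[y == 1]) - 0.125), 0.015)
  expect_lt(abs(freq_of(recs[y == 0]) - 0.05), 0.01)
  # at zero signal the two classes share the background composition
  null <- generate_sequences(200, 200, length_range = c(150, 300),
                             signal = 0, seed = 4)
  yn <- stackrp:::record_labels(null)
  expect_lt(abs(freq_of(null[yn == 1]) - freq_of(null[yn == 0])), 0.01)
})

test_that("dataset writing emits class FASTAs plus a label table", {
  dir <- withr::local_tempdir()
  recs <- generate_sequences(4, 6, length_range = c(50, 80), seed = 5)
  write_dataset(recs, dir)
  expect_true(all(file.exists(file.path(dir,
    c("positive.fasta", "negative.fasta", "labels.tsv")))))
  back <- read_dataset(positive = file.path(dir, "positive.fasta"),
                       negative = file.path(dir, "negative.fasta"))
  expect_equal(sort(stackrp:::record_ids(back)),
               sort(stackrp:::record_ids(recs)))
})

test_that("the CLI round-trips simulate -> extract -> train -> predict", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  cli_main(c("simulate", "--out", data_dir, "--n-pos", "20", "--n-neg", "40",
             "--signal", "1", "--seed", "7"))
  expect_true(file.exists(file.path(data_dir, "config.json")))
  feats <- file.path(dir, "features.tsv")
  cli_main(c("extract",
             "--positive", file.path(data_dir, "positive.fasta"),
             "--negative", file.path(data_dir, "negative.fasta"),
             "--out", feats))
  X <- read_features_tsv(feats)
  expect_equal(dim(X), c(60L, 1160L))
  sel_dir <- file.path(dir, "selection")
  cli_main(c("select", "--features", feats,
             "--labels", paste0(feats, ".labels.tsv"),
             "--out", sel_dir, "--k", "16"))
  ranking <- read.delim(file.path(sel_dir, "ranking.tsv"))
  expect_equal(nrow(ranking), 1160L)
  expect_length(readLines(file.path(sel_dir, "selected_features.txt")), 16L)
  model_path <- file.path(dir, "model.rds")
  cli_main(c("train",
             "--positive", file.path(data_dir, "positive.fasta"),
             "--negative", file.path(data_dir, "negative.fasta"),
             "--model", model_path, "--k", "16", "--seed", "7"))
  preds_path <- file.path(dir, "preds.tsv")
  cli_main(c("predict", "--model", model_path,
             "--fasta", file.path(data_dir, "positive.fasta"),
             "--out", preds_path))
  preds <- read.delim(preds_path)
  expect_equal(nrow(preds), 20L)
  expect_true(all(preds$probability >= 0 & preds$probability <= 1))
  metrics_path <- file.path(dir, "metrics.json")
  cli_main(c("evaluate", "--model", model_path,
             "--positive", file.path(data_dir, "positive.fasta"),
             "--negative", file.path(data_dir, "negative.fasta"),
             "--out", metrics_path))
  m <- jsonlite::read_json(metrics_path)
  expect_true(m$accuracy >= 0 && m$accuracy <= 1)
})

test_that("prediction with mismatched feature configuration is an error", {
  recs <- generate_sequences(8, 8, length_range = c(60, 90), seed = 8)
  cfg <- pipeline_config(lambda = 3L,
                         selection = selection_config(k = 6))
  model <- rp_train(recs, cfg, seed = 9)
  other <- extract_features(recs, lambda = 5L)
  expect_error(rp_predict(model, other), "mismatch")
  # bare width mismatches are caught even without a config attribute
  bare <- other[, 1:100]
  attr(bare, "config") <- NULL
  expect_error(rp_predict(model, bare), "width")
})

test_that("unknown CLI options and subcommands fail loudly", {
  expect_error(cli_main(c("simulate", "--bogus", "1")), "unknown option")
  expect_error(cli_main("transmogrify"), "unknown subcommand")
  expect_error(cli_main(character(0)), "usage")
})
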