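skip_if_no_mzr <- function() skip_if_not_installed("mzR")

tiny_metabolites <- function() {
  tibble::tibble(
    metabolite = "ala",
    quant_precursor = 118.1, quant_product = 59.1,
    qual_precursor = 120.1, qual_product = 63.1,
    istd_precursor = NA_real_, istd_product = NA_real_,
    polarity = "positive", expected_rt = 1, expected_ratio = 2,
    db_id = "HMDB:1")
}

write_tiny_mzml <- function(path, time_unit = "minute", extra = NULL) {
  t <- seq(0, 2, by = 0.02)
  if (time_unit == "second") t <- t * 60
  entries <- list(
    list(id = "SRM SIC Q1=118.1 Q3=59.1", q1 = 118.1, q3 = 59.1,
         polarity = "positive", times = t,
         intensities = 100 * exp(-0.5 * ((t / ifelse(time_unit == "second", 60, 1) - 1) / 0.1)^2)),
    list(id = "SRM SIC Q1=120.1 Q3=63.1", q1 = 120.1, q3 = 63.1,
         polarity = "positive", times = t,
         intensities = 50 * exp(-0.5 * ((t / ifelse(time_unit == "second", 60, 1) - 1) / 0.1)^2)))
  if (!is.null(extra)) entries <- c(entries, extra)
  mrmpick:::write_mzml_file(path, entries, time_unit = time_unit)
  path
}

test_that("mzML transitions are matched to quantifier and qualifier", {
  skip_if_no_mzr()
  path <- write_tiny_mzml(withr::local_tempfile(fileext = ".mzML"))
  rec <- read_mrm_mzml(path, tiny_metabolites())
  expect_equal(sort(rec$role), c("qualifier", "quantifier"))
  q <- rec$chromatogram[[which(rec$role == "quantifier")]]
  expect_equal(max(q$intensity), 100, tolerance = 1e-6)
  expect_equal(max(q$time), 2, tolerance = 1e-9)
})

test_that("absent transitions are flagged missing without aborting", {
  skip_if_no_mzr()
  path <- write_tiny_mzml(withr::local_tempfile(fileext = ".mzML"))
  mets <- tiny_metabolites()
  mets$qual_precursor <- 999.0
  mets$qual_product <- 111.0
  expect_warning(rec <- read_mrm_mzml(path, mets), "No chromatogram")
  expect_equal(rec$role, "quantifier")
})

test_that("times stored in seconds come back in minutes", {
  skip_if_no_mzr()
  path <- write_tiny_mzml(withr::local_tempfile(fileext = ".mzML"),
                          time_unit = "second")
  rec <- read_mrm_mzml(path, tiny_metabolites())
  q <- rec$chromatogram[[which(rec$role == "quantifier")]]
  # source max time is 120 s -> 2 min
  expect_equal(max(q$time), 2, tolerance = 1e-9)
})

test_that("duplicate transition matches raise an ambiguity error", {
  skip_if_no_mzr()
  t <- seq(0, 2, by = 0.02)
  dup <- list(list(id = "SRM SIC Q1=118.12 Q3=59.08", q1 = 118.12, q3 = 59.08,
                   polarity = "positive", times = t, intensities = rep(1, length(t))))
  path <- write_tiny_mzml(withr::local_tempfile(fileext = ".mzML"), extra = dup)
  expect_error(read_mrm_mzml(path, tiny_metabolites()), "Ambiguous")
})

test_that("the reader is total over generated batches written as mzML", {
  skip_if_no_mzr()
  batch <- generate_batch(sim_config(n_samples = 2, n_metabolites = 3, seed = 10))
  dir <- withr::local_tempdir()
  paths <- write_mrm_mzml(batch, dir)
  for (p in paths) {
    rec <- read_mrm_mzml(p, batch$metabolites)
    expect_equal(nrow(rec), 9L)  # 3 metabolites x 3 roles, none missing
    s <- sub("\\.mzML$", "", basename(p))
    orig <- batch$chromatograms[batch$chromatograms$sample_id == s, ]
    key <- paste(orig$metabolite, orig$role)
    for (i in seq_len(nrow(rec))) {
      o <- orig$chromatogram[[match(paste(rec$metabolite[i], rec$role[i]), key)]]
      expect_equal(rec$chromatogram[[i]]$intensity, o$intensity, tolerance = 1e-12)
      expect_equal(rec$chromatogram[[i]]$time, o$time, tolerance = 1e-12)
    }
  }
})

test_that("metabolite DB reading validates schema and preserves order", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    metabolite = c("a", "b", "c"),
    quant_precursor = c(100, 200, 300), quant_product = c(50, 60, 70),
    qual_precursor = c(101, NA, 301), qual_product = c(51, NA, 71),
    expected_rt = c(1, 2, 3), expected_ratio = c(2, NA, 3)), path)
  db <- read_metabolite_db(path)
  expect_equal(db$metabolite, c("a", "b", "c"))
  expect_true(is.na(db$qual_precursor[2]))
  expect_true(is.na(db$db_id[1]))  # absent optional column filled with NA

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metabolite = "a", quant_precursor = 100), bad)
  expect_error(read_metabolite_db(bad), "quant_product")

  neg <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metabolite = "a", quant_precursor = 100,
                                  quant_product = 50, expected_rt = -1), neg)
  expect_error(read_metabolite_db(neg), "row\\(s\\): 1")
})

test_that("sample info requires unique sample ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s2"), group = c("g", "g")), path)
  info <- read_sample_info(path)
  expect_equal(info$sample_id, c("s1", "s2"))
  dup <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s1")), dup)
  expect_error(read_sample_info(dup), "Duplicate")
})

test_that("peak tables round-trip bit-exactly and honour the reporting gate", {
  res <- small_result()
  dir <- withr::local_tempdir()
  paths <- write_peak_tables(res, dir)
  expect_length(paths, 5L)

  primary <- read_peak_table(file.path(dir, "peaks_reported.csv"))
  raw <- read_peak_table(file.path(dir, "area_raw.csv"))
  expect_equal(primary$metabolite, unique(res$metabolites$metabolite))
  expect_equal(names(primary)[-1], res$sample_ids)
  # unreported cells are empty exactly where the gate said no
  n_empty <- sum(is.na(as.matrix(primary[, -1])))
  expect_equal(n_empty, sum(!res$peaks$reported))
  # raw table round-trips the numeric areas bit-exactly
  m <- as.matrix(raw[, -1])
  for (i in seq_len(nrow(res$peaks))) {
    p <- res$peaks[i, ]
    got <- m[match(p$metabolite, raw$metabolite), p$sample_id]
    if (is.finite(p$area)) expect_identical(unname(got), p$area)
  }
  # reformatting what was read reproduces the file byte-for-byte
  raw2 <- raw
  for (col in names(raw2)[-1]) raw2[[col]] <- mrmpick:::fmt_sig17(raw2[[col]])
  readr::write_csv(raw2, file.path(dir, "area_raw2.csv"), na = "")
  expect_identical(readLines(file.path(dir, "area_raw.csv")),
                   readLines(file.path(dir, "area_raw2.csv")))
})

test_that("processing parameters load from key-value and yaml files", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smoothing_width\t7", "n_candidates\t3", "report_threshold\t0.6"), tsv)
  p <- read_processing_params(tsv)
  expect_equal(p$smoothing_width, 7L)
  expect_equal(p$n_candidates, 3L)
  expect_equal(p$report_threshold, 0.6)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("not_a_parameter\t1", bad)
  expect_error(read_processing_params(bad), "Unknown parameter")

  skip_if_not_installed("yaml")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("smoothing_width: 9", "initial_shift_window: 0.4"), yml)
  p2 <- read_processing_params(yml)
  expect_equal(p2$smoothing_width, 9L)
  expect_equal(p2$initial_shift_window, 0.4)
})
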