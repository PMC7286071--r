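test_that("read_bed parses, merges and validates", {
  lay <- genome_layout(c("chr1", "chr2"), c(1000, 500))

  f <- withr::local_tempfile(lines = "chr1\t100\t200")
  trk <- read_bed(f, lay)
  expect_equal(trk, tibble::tibble(chrom = "chr1", start = 100, end = 200))
  expect_equal(sum(trk$end - trk$start), 100)

  f <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr1\t150\t250"))
  expect_equal(read_bed(f, lay),
               tibble::tibble(chrom = "chr1", start = 100, end = 250))

  f <- withr::local_tempfile(lines = "chr1\t200\t100")
  expect_error(read_bed(f, lay), "line 1")
  f <- withr::local_tempfile(lines = c("chr1\t1\t2", "chr1\t5\tx"))
  expect_error(read_bed(f, lay), "line 2")

  # unknown chromosomes: skip with warning by default, error in strict mode
  f <- withr::local_tempfile(lines = c("chr1\t1\t2", "scaffold_7\t1\t2"))
  expect_warning(trk <- read_bed(f, lay), "skipped")
  expect_equal(trk$chrom, "chr1")
  expect_error(suppressWarnings(read_bed(f, lay, strict = TRUE)),
               "scaffold_7")
})

test_that("write_bed round-trips and orders by layout", {
  lay <- genome_layout(c("chrB", "chrA"), c(1000, 1000))
  f <- withr::local_tempfile()
  write_bed(tibble::tibble(chrom = character(), start = numeric(),
                           end = numeric()), f, lay)
  expect_identical(readLines(f), character(0))

  trk <- tibble::tibble(chrom = c("chrA", "chrB"), start = c(10, 5),
                        end = c(20, 9))
  write_bed(trk, f, lay)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "^chrB")  # layout order, not alphabetical
  expect_equal(dplyr::arrange(read_bed(f, lay), chrom, start),
               dplyr::arrange(trk, chrom, start))
})

test_that("read -> write -> read is the identity on random tracks", {
  withr::local_seed(11)
  lay <- tiny_layout(2000, 3)
  for (i in 1:20) {
    trk <- random_track(lay, n = sample(0:15, 1))
    f <- withr::local_tempfile()
    write_bed(trk, f, lay)
    expect_equal(read_bed(f, lay), trk)
  }
})

test_that("normalization is idempotent and input-order independent", {
  withr::local_seed(12)
  for (i in 1:20) {
    raw <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                          start = sample(0:500, 12),
                          end = 0)
    raw$end <- raw$start + sample(1:100, 12, TRUE)
    norm <- merge_intervals(raw)
    expect_equal(merge_intervals(norm), norm)
    expect_equal(merge_intervals(raw[sample(nrow(raw)), ]), norm)
    # disjoint and sorted
    by_chr <- split(norm, norm$chrom)
    for (x in by_chr) {
      expect_true(all(diff(x$start) > 0))
      expect_true(all(x$start[-1] > x$end[-nrow(x)]))
    }
  }
})

test_that("qc_filter drops tracks with peak-free chromosomes, except Y", {
  lay <- genome_layout(c("chr1", "chr21", "chrY"), c(100, 100, 100))
  full <- tibble::tibble(sample_id = "s1", modification = "H3K4me3",
                         chrom = c("chr1", "chr21"), start = 0, end = 10)
  res <- qc_filter(full, lay)
  expect_equal(nrow(res$excluded), 0L)  # missing Y is exempt

  noy21 <- dplyr::mutate(full[1, ], sample_id = "s2")
  res <- qc_filter(dplyr::bind_rows(full, noy21), lay)
  expect_equal(res$excluded$sample_id, "s2")
  expect_equal(res$excluded$missing_chroms, "chr21")

  three <- dplyr::bind_rows(
    full,
    dplyr::mutate(full, sample_id = "s2"),
    dplyr::mutate(full[full$chrom != "chr1", ], sample_id = "s3"))
  res <- qc_filter(three, lay)
  expect_setequal(unique(res$kept$sample_id), c("s1", "s2"))
  expect_equal(res$excluded$sample_id, "s3")

  # running the filter again on the kept set excludes nothing
  again <- qc_filter(res$kept, lay)
  expect_equal(nrow(again$excluded), 0L)
  expect_equal(again$kept, res$kept)

  # empty input
  empty <- qc_filter(full[0, ], lay)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)

  # a sample listed in the sheet but with no intervals at all is excluded
  res <- qc_filter(full, lay,
                   samples = tibble::tibble(sample_id = c("s1", "ghost"),
                                            modification = "H3K4me3"))
  expect_equal(res$excluded$sample_id, "ghost")
  expect_equal(res$excluded$missing_chroms, "chr1,chr21")
})

test_that("sample sheets and chrom sizes round through their readers", {
  sheet <- tibble::tibble(sample_id = c("a", "b"), cell_type = "Er",
                          tissue = "blood", individual = c("i1", "i2"),
                          subtype = "none", modification = "H3K4me3",
                          bed_path = c("a.bed", "b.bed"))
  f <- withr::local_tempfile()
  readr::write_tsv(sheet, f)
  expect_equal(read_sample_sheet(f), sheet)
  dup <- dplyr::mutate(sheet, sample_id = "a")
  readr::write_tsv(dup, f)
  expect_error(read_sample_sheet(f), "duplicate")

  f <- withr::local_tempfile(lines = c("chr1\t248956422", "chrY\t57227415"))
  lay <- read_chrom_sizes(f)
  expect_equal(lay$length, c(248956422, 57227415))
  expect_equal(epitree:::qc_required_chroms(lay), "chr1")
})
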