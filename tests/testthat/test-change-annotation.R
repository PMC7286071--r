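# small reconstruction shared by the exclusivity tests: two cell types (3
# and 2 samples), so the tree has both inter and intra branches
excl_fixture <- function(patterns, weights = rep(1, nrow(patterns))) {
  samples <- c("A_s1", "A_s2", "A_s3", "B_s1", "B_s2")
  smap <- tibble::tibble(sample_id = samples,
                         cell_type = c("A", "A", "A", "B", "B"))
  ctt <- cell_type_tree("(A,B)root;", smap)
  colnames(patterns) <- samples
  spm <- site_pattern_matrix(samples, patterns, weights)
  resolve_ancestral(ctt, spm)
}

test_that("branch exclusivity classes follow the changed-edge classes", {
  recon <- excl_fixture(rbind(
    c(1L, 1L, 1L, 0L, 0L),   # one change on the inter A-B stem
    c(1L, 0L, 0L, 0L, 0L),   # one change on an intra pendant edge
    c(1L, 1L, 0L, 0L, 0L),   # ACCTRAN: stem gain plus an intra loss
    c(1L, 1L, 1L, 1L, 1L)))  # constant
  cls <- classify_exclusivity(recon)
  expect_equal(cls$exclusivity,
               c("INTER_ONLY", "INTRA_ONLY", "MIXED", "NO_CHANGE"))
  # the three changed classes partition the changed bp
  ch <- map_changes(recon)
  expect_equal(sum(cls$weight[cls$exclusivity != "NO_CHANGE"]),
               length(unique(ch$pattern_id)))
})

test_that("tss_distance applies the strand-aware sign convention", {
  genes <- gene_model(c("g1"), "chr1", "+", 2000, 4000)
  seg <- tibble::tibble(chrom = "chr1", start = 1400, end = 1601)
  ann <- tss_distance(seg, genes)  # midpoint 1500, 500 bp left of + TSS
  expect_equal(ann$tss_distance, -500)

  genes_m <- gene_model("g1", "chr1", "-", 500, 2001)
  ann <- tss_distance(seg, genes_m)  # TSS at 2000; 500 bp left = downstream
  expect_equal(ann$tss_distance, 500)

  # equidistant TSSs resolve to the lexicographically smaller id
  two <- gene_model(c("g2", "g1"), "chr1", c("+", "+"), c(1000, 2000),
                    c(1500, 2500))
  ann <- tss_distance(tibble::tibble(chrom = "chr1", start = 1500, end = 1501),
                      two)
  expect_equal(ann$gene_id, "g1")

  # chromosome without genes: unassigned
  ann <- tss_distance(tibble::tibble(chrom = "chr9", start = 0, end = 10),
                      genes)
  expect_true(is.na(ann$tss_distance))
})

test_that("the 12-category scheme bins distances as documented", {
  expect_equal(as.character(bin_distance(-500)), "upstream 0-1 kb")
  expect_equal(as.character(bin_distance(150000)), "downstream >100 kb")
  expect_equal(as.character(bin_distance(0)), "downstream 0-1 kb")
  expect_equal(as.character(bin_distance(1000)), "downstream 1-3 kb")
  expect_equal(as.character(bin_distance(-1000)), "upstream 1-3 kb")
  expect_equal(levels(bin_distance(0)),
               c(paste("upstream", c(">100 kb", "10-100 kb", "5-10 kb",
                                     "3-5 kb", "1-3 kb", "0-1 kb")),
                 paste("downstream", c("0-1 kb", "1-3 kb", "3-5 kb",
                                       "5-10 kb", "10-100 kb", ">100 kb"))))
})

test_that("category fractions are bp-weighted and sum to one", {
  withr::local_seed(41)
  ann <- tibble::tibble(chrom = "chr1", start = 0, end = 1,
                        tss_distance = c(runif(40, -2e5, 2e5), NA),
                        weight = sample(1:100, 41, TRUE))
  expect_message(d <- tss_distribution(ann), "unassigned")
  expect_equal(nrow(d), 12L)
  expect_equal(sum(d$fraction), 1)
  # permutation invariance
  d2 <- suppressMessages(tss_distribution(ann[sample(41), ]))
  expect_equal(dplyr::arrange(d2, category), dplyr::arrange(d, category))
})

test_that("two-sample KS matches its oracles", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_two_sample(1:3, 4:6)
  expect_equal(disjoint$statistic, 1)
  # exhaustive permutation oracle: D = 1 requires the split {1,2,3}|{4,5,6},
  # 2 of the choose(6,3) equally likely assignments
  expect_equal(disjoint$p_value, 2 / choose(6, 3))

  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  withr::local_seed(42)
  for (i in 1:25) {
    x <- round(rnorm(sample(4:12, 1)), 2)
    y <- round(rnorm(sample(4:12, 1), mean = runif(1, 0, 2)), 2)
    if (anyDuplicated(c(x, y))) next
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }

  # weights equal to 1 reduce the weighted statistic to the unweighted one
  x <- rnorm(20); y <- rnorm(15)
  expect_equal(ks_two_sample(x, y, rep(2, 20), rep(2, 15))$statistic,
               ks_two_sample(x, y)$statistic)
})

test_that("gene models import from GTF and TSS BED", {
  gtf <- c("chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id \"gA\";",
           "chr1\tsrc\tgene\t501\t900\t.\t-\t.\tgene_id \"gB\";")
  f <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  g <- read_gtf_genes(f)
  expect_equal(g$start, c(100, 500))
  expect_equal(g$end, c(300, 900))
  expect_equal(g$tss, c(100, 899))

  f2 <- withr::local_tempfile(
    lines = c("chr1\t100\t300\tgA\t0\t+", "chr1\t500\t900\tgB\t0\t-"))
  g2 <- read_tss_bed(f2)
  expect_equal(g2, g)
})
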