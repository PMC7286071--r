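test_that("fitch_score handles the textbook quartet cases", {
  tr <- quartet()
  expect_equal(fitch_score(tr, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(fitch_score(tr, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_equal(fitch_score(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_error(fitch_score(tr, c(A = 1, B = 1, C = 0)), "leaf")
})

test_that("MPR state sets match exhaustive enumeration on small cases", {
  tr <- quartet()
  sets <- mpr_state_sets(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(sets[1, "root"]), 3L)  # both labelings of length 1 exist
  expect_equal(unname(sets[1, c("ab", "cd")]), c(2L, 1L))

  sets <- mpr_state_sets(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(all(sets == 2L))

  tr3 <- read_newick("((A,B)ab,C)root;")
  sets <- mpr_state_sets(tr3, c(A = 1, B = 0, C = 0))
  expect_equal(unname(sets[1, "ab"]), 1L)  # only OFF at the AB ancestor is minimal
})

test_that("ACCTRAN and DELTRAN resolve as specified", {
  tr <- quartet()
  smap <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         cell_type = c("A", "B", "C", "D"))

  # unique MPR: the two algorithms coincide
  spm <- site_pattern_matrix(c("A", "B", "C", "D"),
                             matrix(c(1L, 1L, 1L, 0L), 1,
                                    dimnames = list(NULL, c("A", "B", "C", "D"))),
                             weight = 1)
  acc <- resolve_ancestral(tr, spm, "ACCTRAN")
  del <- resolve_ancestral(tr, spm, "DELTRAN")
  expect_equal(acc$states, del$states)

  # ambiguous case: both are MPRs; the root tie resolves to OFF for both
  pat <- c(A = 1, B = 0, C = 1, D = 0)
  spm2 <- site_pattern_matrix(names(pat), matrix(pat, 1), weight = 1)
  bf <- brute_force_parsimony(tr, pat)
  acc <- resolve_ancestral(tr, spm2, "ACCTRAN")
  del <- resolve_ancestral(tr, spm2, "DELTRAN")
  for (r in list(acc, del)) {
    hit <- apply(bf$labelings[, colnames(r$states), drop = FALSE], 1L,
                 function(l) all(l == r$states[1, ]))
    expect_true(any(hit))
    expect_equal(r$pattern_length, bf$length)
    expect_equal(unname(r$states[1, "root"]), 0L)
  }

  # internal tie: ACCTRAN pulls the change rootward, DELTRAN delays it.
  # ((X,(Y,Z))n,(P,Q)): X=Y=1, Z=P=Q=0; both length-2 MPRs exist: a gain on
  # the edge into n followed by a loss at Z (ACCTRAN) or two parallel gains
  # at X and Y (DELTRAN).
  tr2 <- read_newick("((X,(Y,Z)yz)n,(P,Q)pq)root;")
  pat2 <- c(X = 1, Y = 1, Z = 0, P = 0, Q = 0)
  spm3 <- site_pattern_matrix(names(pat2), matrix(pat2, 1), weight = 1)
  bf2 <- brute_force_parsimony(tr2, pat2)
  acc2 <- resolve_ancestral(tr2, spm3, "ACCTRAN")
  del2 <- resolve_ancestral(tr2, spm3, "DELTRAN")
  expect_equal(unname(acc2$states[1, c("n", "yz")]), c(1L, 1L))
  expect_equal(unname(del2$states[1, c("n", "yz")]), c(0L, 0L))
  for (r in list(acc2, del2)) {
    expect_equal(labeling_changes(tr2, r$states[1, ]), bf2$length)
  }
})

test_that("change mapping merges the root half-edges and conserves bp", {
  smap <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         cell_type = c("A", "B", "C", "D"))
  ctt <- cell_type_tree("((A,B)ab,(C,D)cd)root;", smap)
  spm <- site_pattern_matrix(c("A", "B", "C", "D"),
                             matrix(c(1L, 1L, 0L, 0L), 1,
                                    dimnames = list(NULL, c("A", "B", "C", "D"))),
                             weight = 100,
                             segments = tibble::tibble(chrom = "chr1",
                                                       start = 0, end = 100,
                                                       pattern_id = 1L))
  recon <- resolve_ancestral(ctt, spm, "ACCTRAN")
  ch <- map_changes(recon)
  expect_equal(nrow(ch), 1L)
  expect_equal(unname(ch$branch), "ab-cd")     # merged root branch
  expect_equal(unname(ch$direction), "GAIN")   # OFF root tie-break puts the gain AB-side
  expect_equal(ch$weight, 100)

  agg <- aggregate_changes(recon)
  expect_equal(sum(agg$bp), recon$score)
  expect_equal(agg$bp[agg$change == "ON" & agg$branch == "ab-cd"], 100)
})

test_that("constant patterns produce no changes anywhere", {
  smap <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         cell_type = c("A", "B", "C", "D"))
  ctt <- cell_type_tree("((A,B)ab,(C,D)cd)root;", smap)
  spm <- site_pattern_matrix(c("A", "B", "C", "D"),
                             matrix(rep(c(1L, 0L), each = 4), 2, byrow = TRUE,
                                    dimnames = list(NULL, c("A", "B", "C", "D"))),
                             weight = c(30, 70))
  recon <- resolve_ancestral(ctt, spm)
  expect_equal(recon$score, 0)
  expect_equal(nrow(map_changes(recon)), 0L)
  expect_true(all(aggregate_changes(recon)$bp == 0))
})

test_that("fitch, MPR sets and both resolutions agree with the oracle", {
  withr::local_seed(31)
  for (i in 1:150) {
    n <- sample(4:10, 1)
    tr <- random_test_tree(n)
    pat <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    bf <- brute_force_parsimony(tr, pat)
    expect_equal(fitch_score(tr, pat), bf$length)
    sets <- mpr_state_sets(tr, pat)
    expect_equal(unname(sets[1, ]), unname(bf$mpr_sets))
    spm <- site_pattern_matrix(names(pat), matrix(pat, 1), weight = 1)
    for (alg in c("ACCTRAN", "DELTRAN")) {
      r <- resolve_ancestral(tr, spm, alg)
      expect_equal(labeling_changes(tr, r$states[1, ]), bf$length)
      hit <- apply(bf$labelings[, colnames(r$states), drop = FALSE], 1L,
                   function(l) all(l == r$states[1, ]))
      expect_true(any(hit))
    }
  }
})

test_that("weighted score is additive over patterns", {
  withr::local_seed(32)
  tr <- random_test_tree(8)
  states <- matrix(sample(0:1, 8 * 30, TRUE), 30,
                   dimnames = list(NULL, tr$tip.label))
  w <- sample(1:50, 30, TRUE)
  spm <- site_pattern_matrix(tr$tip.label, states, w)
  expect_equal(parsimony_score(tr, spm),
               sum(w * fitch_score(tr, states)))
})

test_that("node tracks decode resolved states back to BED intervals", {
  smap <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         cell_type = c("A", "B", "C", "D"))
  ctt <- cell_type_tree("((A,B)ab,(C,D)cd)root;", smap)
  lay <- tiny_layout(60)
  tracks <- tibble::tibble(sample_id = c("A", "B"), chrom = "chr1",
                           start = c(10, 10), end = c(30, 40))
  tracks <- dplyr::bind_rows(tracks,
                             tibble::tibble(sample_id = c("C", "D"),
                                            chrom = "chr1", start = 0,
                                            end = 1)[0, ])
  spm <- encode_patterns(tracks, lay, samples = c("A", "B", "C", "D"))
  recon <- resolve_ancestral(ctt, spm)
  nt <- node_state_tracks(recon)
  ab <- nt[nt$node == "ab", ]
  expect_equal(ab$start, 10)
  expect_equal(ab$end, 30)  # shared A/B interval is ancestral at their MRCA
  expect_false("cd" %in% nt$node)
})
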