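test_that("codon bookkeeping partitions the code correctly", {
  expect_length(sense_codons(), 61L)
  expect_length(syn_codons(), 59L)
  expect_setequal(stop_codons(), c("TAA", "TAG", "TGA"))
  expect_false(any(c("ATG", "TGG") %in% syn_codons()))
  fam <- codon_families()
  expect_length(fam$families, 18L)
  expect_equal(sum(fam$sizes), 59L)
  expect_true(all(colSums(fam$membership) == fam$sizes))
})

test_that("count_codons tallies, drops terminal stops and skips ambiguity", {
  cc <- count_codons("ATGAAA")
  expect_equal(unname(cc["ATG"]), 1L)
  expect_equal(unname(cc["AAA"]), 1L)
  expect_equal(attr(cc, "n_codons"), 2L)

  cc2 <- count_codons("ATGAAATAA")
  expect_equal(as.integer(cc2), as.integer(cc))
  expect_equal(attr(cc2, "n_codons"), 2L)

  ccn <- count_codons("ATGNNNAAA")
  expect_equal(attr(ccn, "skipped"), 1L)
  expect_equal(attr(ccn, "n_codons"), 2L)

  expect_error(count_codons("ATGA"), "multiple of 3")
  expect_error(count_codons("ATGTAAAAA"), "internal stop")
  expect_warning(cct <- count_codons("ATGTAAAAA", internal_stop = "truncate"),
                 "truncating")
  expect_equal(attr(cct, "n_codons"), 1L)
})

test_that("count totals equal floor(len/3) minus dropped codons exactly", {
  set.seed(7)
  for (i in 1:20) {
    s <- simulate_gene(make_usage(runif(1)), sample(100:400, 1))$seq
    cc <- count_codons(s)
    expect_identical(attr(cc, "n_codons") + attr(cc, "skipped") + 1L,
                     nchar(s) %/% 3L) # +1 for the dropped terminal stop
  }
})

test_that("matrix counting agrees with scalar counting", {
  set.seed(11)
  seqs <- vapply(1:10, function(i) simulate_gene(make_usage(0.3), 150)$seq,
                 character(1))
  names(seqs) <- paste0("g", 1:10)
  m <- count_codons_matrix(seqs)
  for (i in c(1, 5, 10))
    expect_equal(unname(m[i, ]), as.integer(count_codons(seqs[[i]])))
})

test_that("matrix counting truncates internal stops like scalar counting", {
  suppressWarnings(m <- count_codons_matrix(c(x = "ATGTAAAAATAA"),
                                            internal_stop = "truncate"))
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "ATG"]), 1L)
  expect_error(count_codons_matrix("ATGTAAAAATAA"), "internal stop")
})

test_that("rscu follows the observed/expected definition", {
  r <- rscu(counts_of(AAA = 3, AAG = 1))
  expect_equal(unname(r["AAA"]), 1.5)
  expect_equal(unname(r["AAG"]), 0.5)

  # perfectly uniform family usage -> RSCU 1 everywhere observed
  cc <- zero_counts()
  cc[syn_codons()] <- 2L
  r2 <- rscu(cc)
  expect_true(all(abs(r2 - 1) < 1e-12))

  # family-sum conservation for fully observed families
  set.seed(3)
  m <- sim_counts(make_usage(0.4), 5, 200, seed = 3)
  fam <- codon_families()
  for (i in 1:5) {
    ri <- rscu(structure(m[i, ], names = sense_codons(),
                         class = "codon_counts"))
    sums <- as.numeric(crossprod(fam$membership,
                                 ifelse(is.na(ri), 0, as.numeric(ri))))
    observed <- as.numeric(crossprod(fam$membership, !is.na(ri))) ==
      fam$sizes
    expect_equal(sums[observed], fam$sizes[observed], tolerance = 1e-9)
  }

  # missing family -> NA, not zero; pseudocount fills it
  r3 <- rscu(counts_of(AAA = 4))
  expect_true(is.na(r3["TTT"]))
  expect_false(anyNA(rscu(counts_of(AAA = 4), pseudocount = 0.5)))
})

test_that("pooled RSCU converges to the generating usage", {
  u <- make_usage(1) # concentrated, CC15-like
  m <- sim_counts(u, 800, 300, seed = 5)
  r <- rscu(colSums(m))
  # expected RSCU of codon c = k * freq(c)
  fam <- codon_families()
  k <- fam$sizes[match(codon_aa(syn_codons()), fam$families)]
  expected <- k * as.numeric(u)
  expect_lt(max(abs(as.numeric(r) - expected)), 0.05)
})

test_that("usage_from_counts normalises within families and is idempotent", {
  cc <- counts_of(AAA = 3, AAG = 1, GGT = 2, GGC = 2)
  p <- usage_from_counts(list(cc))
  expect_equal(unname(p["AAA"]), 0.75)
  expect_equal(unname(p["GGT"]), 0.5)
  p2 <- usage_from_counts(list(cc, cc))
  expect_equal(as.numeric(p2), as.numeric(p))
  expect_error(usage_from_counts(list()), "empty")

  # family sums are 1 where observed
  fam <- codon_families()
  sums <- crossprod(fam$membership, ifelse(is.na(p), 0, as.numeric(p)))
  expect_true(all(abs(sums[c("K", "G"), 1] - 1) < 1e-9))

  # recovery: pooled profile of a homogeneous set
  u <- make_usage(0.6)
  m <- sim_counts(u, 500, 300, seed = 9)
  est <- usage_from_counts(m)
  expect_lt(max(abs(as.numeric(est) - as.numeric(u))), 0.02)
})

test_that("gc_content computes pooled and per-sequence percents", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content(c("GGGG", "AT")), 100 * 4 / 6)
  expect_equal(gc_content(c("GGGG", "AT"), per_sequence = TRUE), 50)
  expect_equal(gc_content("GGNN"), 100) # ambiguity ignored
  expect_error(gc_content("NNN"), "unambiguous")
})

test_that("gc3 respects scope and splitting invariance", {
  expect_equal(gc3(counts_of(AAG = 2, GCC = 3)), 100)
  expect_equal(gc3(counts_of(AAA = 2, GCT = 3)), 0)
  # ATG/TGG included under default scope, excluded under syn scope
  cc <- counts_of(ATG = 1, TGG = 1, AAA = 2)
  expect_equal(gc3(cc), 50)                # ATG and TGG both end in G
  expect_equal(gc3(cc, scope = "syn"), 0)
  expect_error(gc3(zero_counts()), "zero")

  # pooling subsets leaves the pooled gc3 unchanged
  m <- sim_counts(make_usage(0.5), 40, 200, seed = 13)
  whole <- gc3(colSums(m))
  parts <- colSums(m[1:15, ]) + colSums(m[16:40, ])
  expect_equal(gc3(parts), whole)

  # set summary exposes mean and sd
  s <- gc3(m)
  expect_length(s$per_gene, 40)
  expect_equal(s$mean, mean(s$per_gene))
})

test_that("gc3 increases along the ancestry gradient", {
  means <- vapply(c(0, 0.5, 1), function(a) {
    gc3(sim_counts(make_usage(a), 60, 300, seed = 17))$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("delta_rscu is an antisymmetric difference with conservation", {
  m <- sim_counts(make_usage(0.2), 30, 300, seed = 19)
  m2 <- sim_counts(make_usage(0.9), 30, 300, seed = 23)
  ra <- rscu(colSums(m)); rb <- rscu(colSums(m2))
  d <- delta_rscu(ra, rb)
  expect_equal(delta_rscu(ra, ra), setNames(rep(0, 59), syn_codons()))
  expect_equal(delta_rscu(rb, ra), -d)
  # fully observed 2-codon families: entries sum to 0
  two <- c("AAA", "AAG")
  expect_equal(sum(d[two]), 0, tolerance = 1e-9)
  expect_error(delta_rscu(ra[1:10], rb), "59")
})
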