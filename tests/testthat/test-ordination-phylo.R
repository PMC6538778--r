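test_that("CA reproduces the chi-square inertia identity on a toy table", {
  set.seed(137)
  x <- matrix(rpois(30, 8) + 1, 5, 6)
  m <- correspondence_analysis(x)
  # brute force: total inertia = chi-square statistic / grand total
  n <- sum(x)
  E <- outer(rowSums(x), colSums(x)) / n
  chi2 <- sum((x - E)^2 / E)
  expect_equal(m$total_inertia, chi2 / n, tolerance = 1e-12)
  expect_equal(m$total_inertia, sum(m$sv^2), tolerance = 1e-12)
  expect_true(all(diff(m$sv) <= 1e-12))       # descending
  expect_equal(sum(m$row_masses), 1)
  expect_equal(sum(m$col_masses), 1)
})

test_that("CA agrees with an independent implementation on singular values", {
  skip_if_not_installed("vegan")
  set.seed(139)
  x <- matrix(rpois(48, 10) + 1, 8, 6)
  m <- correspondence_analysis(x)
  cca <- vegan::cca(x)
  expect_equal(m$sv^2, unname(cca$CA$eig), tolerance = 1e-8)
})

test_that("CA duality and supplementary projection identities hold", {
  set.seed(149)
  x <- matrix(rpois(60, 12) + 1, 10, 6)
  m <- correspondence_analysis(x)
  # transition formula: projecting each active row's profile reproduces it
  for (i in c(1, 4, 10)) {
    proj <- project_supplementary(m, x[i, ])
    expect_equal(proj, unname(m$row_coords[i, ]), tolerance = 1e-9)
  }
  # the column-mass centroid projects to the origin
  expect_equal(project_supplementary(m, m$col_masses),
               rep(0, length(m$sv)), tolerance = 1e-9)
  expect_error(project_supplementary(m, rep(0, 6)), "zero")
})

test_that("identical rows collapse CA to zero inertia at the origin", {
  x <- matrix(rep(c(3, 1, 2, 2, 4, 1), each = 4), 4, 6)
  m <- correspondence_analysis(x)
  expect_equal(m$total_inertia, 0)
  expect_true(all(abs(m$row_coords) < 1e-9))
})

test_that("CA separates synthetic usage clusters and places modals inside", {
  ua <- make_usage(0.1); ub <- make_usage(0.9)
  ma <- sim_counts(ua, 60, 300, seed = 151)
  mb <- sim_counts(ub, 60, 300, seed = 157)
  r <- rscu_matrix(rbind(ma, mb))
  mod <- correspondence_analysis(r)
  c1 <- mod$row_coords[, 1]
  grp <- rep(c("a", "b"), each = 60)
  # silhouette on C1
  sil <- vapply(seq_along(c1), function(i) {
    own <- mean(abs(c1[i] - c1[grp == grp[i]][-match(i, which(grp == grp[i]))]))
    oth <- mean(abs(c1[i] - c1[grp != grp[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # modal points land inside their cluster's bounding box on (C1, C2)
  fam <- codon_families()
  k <- fam$sizes[match(codon_aa(syn_codons()), fam$families)]
  for (g in c("a", "b")) {
    mm <- if (g == "a") ma else mb
    modal <- modal_codon_usage(mm)$profile
    proj <- project_supplementary(mod, k * as.numeric(modal))[1:2]
    box <- apply(mod$row_coords[grp == g, 1:2], 2, range)
    expect_true(all(proj >= box[1, ] & proj <= box[2, ]))
  }
})

test_that("nj_tree solves the 3-taxon case in closed form", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 9
  d["b", "c"] <- d["c", "b"] <- 10
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
})

test_that("nj_tree recovers an additive 4-taxon tree exactly", {
  # tree ((a:2,b:3):1,(c:4,d:5)); additive distances
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 5; d["a", "c"] <- 7; d["a", "d"] <- 8
  d["b", "c"] <- 8; d["b", "d"] <- 9; d["c", "d"] <- 9
  d <- d + t(d)
  tr <- nj_tree(d)
  # topology: ab | cd
  expect_equal(normalized_rf(tr, ape::read.tree(text = "((a:2,b:3):1,c:4,d:5);")), 0)
  # path lengths reproduce the input distances
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  dn <- d; dn[1, 2] <- NA; dn[2, 1] <- NA
  expect_error(nj_tree(dn), "NA")
})

test_that("nj_tree is label-order invariant and clamps negative lengths", {
  set.seed(163)
  n <- 7
  d <- as.matrix(dist(matrix(rnorm(n * 4), n)))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  t1 <- nj_tree(d)
  perm <- sample(n)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(normalized_rf(t1, t2), 0)
  expect_true(all(t1$edge.length >= 0))
})

test_that("gradient profiles yield a ladder-like usage tree", {
  alphas <- c(0, 0.25, 0.5, 0.75, 1)
  profs <- lapply(alphas, make_usage)
  names(profs) <- paste0("a", alphas * 100)
  d <- distance_matrix(profs)
  tr <- nj_tree(d)
  # a caterpillar ordering leaves by alpha: the ends are maximally separated
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(unname(which.max(pd["a0", ])),
               unname(match("a100", colnames(pd))))
  # the internal split {a0,a25} | rest exists (ladder base)
  expect_equal(normalized_rf(
    tr, ape::read.tree(text = "((a0,a25),a50,(a75,a100));")), 0)
})

test_that("normalized_rf matches brute-force bipartition enumeration", {
  expect_equal(normalized_rf(random_tree(6, 1), random_tree(6, 1)), 0)

  # 5-leaf trees with no shared nontrivial splits -> 1
  ta <- ape::read.tree(text = "((t1,t2),(t3,t4),t5);")
  tb <- ape::read.tree(text = "((t1,t3),(t2,t5),t4);")
  expect_equal(normalized_rf(ta, tb), 1)

  for (s in 1:100) {
    t1 <- random_tree(8, s)
    t2 <- random_tree(8, s + 1000)
    rf <- brute_rf(t1, t2)
    expect_equal(normalized_rf(t1, t2), rf / (2 * (8 - 3)))
  }
  expect_error(normalized_rf(random_tree(6, 2), random_tree(7, 2)),
               "leaf set")
})

test_that("normalized_rf behaves as a metric on sampled topologies", {
  trees <- lapply(1:6, function(s) random_tree(7, s + 40))
  for (i in 1:5) for (j in (i + 1):6) {
    dij <- normalized_rf(trees[[i]], trees[[j]])
    expect_equal(dij, normalized_rf(trees[[j]], trees[[i]]))
    for (k in seq_len(6)[-c(i, j)]) {
      expect_lte(dij, normalized_rf(trees[[i]], trees[[k]]) +
                   normalized_rf(trees[[k]], trees[[j]]) + 1e-12)
    }
  }
})

test_that("phylip distance matrices round-trip", {
  profs <- lapply(c(0, 0.5, 1), make_usage)
  names(profs) <- c("mob", "mid", "core")
  d <- distance_matrix(profs)
  f <- tempfile()
  write_phylip_dist(d, f)
  back <- read_phylip_dist(f)
  expect_equal(back, d, tolerance = 1e-6)
})
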