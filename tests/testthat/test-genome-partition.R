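random_ortholog_table <- function(n_genes, strains, p = 0.8, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * length(strains), 1L, p), n_genes,
              dimnames = list(NULL, strains))
  m[, 1L] <- 1L # reference all-present
  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             replicon = sample(c("chromosome", "pSymA", "pSymB"),
                               n_genes, replace = TRUE),
             m, stringsAsFactors = FALSE)
}

test_that("core_and_singletons matches brute-force row scans", {
  strains <- paste0("S", 1:6)
  tab <- random_ortholog_table(1000, strains, p = 0.8, seed = 167)
  res <- core_and_singletons(tab, strains)

  m <- as.matrix(tab[, strains])
  brute_core <- tab$gene_id[apply(m, 1, function(r) all(r == 1))]
  brute_single <- tab$gene_id[apply(m, 1, function(r)
    r[1] == 1 && sum(r) == 1)]
  expect_identical(res$core, brute_core)
  expect_identical(res$singleton, brute_single)
  expect_length(intersect(res$core, res$singleton), 0)

  # per-replicon split partitions the global sets
  expect_setequal(unlist(lapply(res$by_replicon, `[[`, "core")), res$core)

  # trivial cases
  allp <- tab; allp[strains] <- 1L
  r2 <- core_and_singletons(allp, strains)
  expect_identical(r2$core, allp$gene_id)
  expect_length(r2$singleton, 0)
  expect_error(core_and_singletons(tab, character(0)), "empty")
})

test_that("ancestry_cores are nested and monotone in size", {
  taxa <- paste0("T", 1:8)
  tab <- random_ortholog_table(800, taxa, p = 0.9, seed = 173)
  scheme <- lapply(c(2, 4, 6, 8), function(k) taxa[1:k])
  cc <- ancestry_cores(tab, scheme)
  expect_named(cc, paste0("CC", 1:4))
  for (k in 2:4) {
    expect_true(all(cc[[k]] %in% cc[[k - 1]]))
    expect_lte(length(cc[[k]]), length(cc[[k - 1]]))
  }
  # identical consecutive taxon sets give identical layers
  cc2 <- ancestry_cores(tab, list(taxa[1:3], taxa[1:3]))
  expect_identical(cc2[[1]], cc2[[2]])
  # adding a taxon lacking exactly one gene removes exactly that gene
  tab3 <- tab; tab3[taxa[-1]] <- 1L
  tab3[5, "T8"] <- 0L
  cc3 <- ancestry_cores(tab3, list(taxa[1:7], taxa))
  expect_identical(setdiff(cc3[[1]], cc3[[2]]), tab3$gene_id[5])
  expect_error(ancestry_cores(tab, list(taxa[1:4], taxa[3:5])), "nested")
})

test_that("singleton_density and box statistics follow their definitions", {
  expect_equal(singleton_density(10, 2000), 5)
  expect_equal(singleton_density(0, 500), 0)
  expect_error(singleton_density(3, 0), "positive")

  set.seed(179)
  v <- c(rlnorm(40, 2, 0.5), 60) # one high outlier
  bs <- density_box_stats(v)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  expect_equal(unname(bs["median"]), q[2])
  expect_equal(unname(bs["lower_whisker"]), min(v[v >= q[1] - 1.5 * iqr]))
  expect_equal(unname(bs["upper_whisker"]), max(v[v <= q[3] + 1.5 * iqr]))
  expect_lt(bs["upper_whisker"], 60) # outlier beyond the whisker
})

test_that("contig filtering applies the identity, coverage and length rules", {
  toy <- data.frame(
    contig_id = paste0("c", 1:6),
    length = c(2000, 2000, 500, 2000, 2000, 1500),
    coverage = c(100, 100, 100, 16, 18, 17),
    max_identity_pct = c(96, 50, 50, 50, 50, 50))
  res <- filter_plasmid_contigs(toy, min_len = 1000, max_identity = 95,
                                cov_threshold = 17)
  expect_identical(res$kept$contig_id, c("c2", "c5", "c6"))
  reasons <- setNames(res$removed$reason, res$removed$contig_id)
  expect_equal(unname(reasons["c1"]), "high-identity")
  expect_equal(unname(reasons["c3"]), "short")
  expect_equal(unname(reasons["c4"]), "low-coverage")

  # kept set is independent of filter order: apply single rules sequentially
  keep_by_hand <- toy[toy$max_identity_pct <= 95 & toy$coverage >= 17 &
                        toy$length > 1000, "contig_id"]
  expect_identical(res$kept$contig_id, keep_by_hand)

  # auto threshold = mean + 2 SD of reference coverages
  ref <- c(10, 12, 14, 16)
  auto <- filter_plasmid_contigs(toy, cov_threshold = "auto",
                                 ref_coverages = ref)
  expect_equal(auto$cov_threshold, mean(ref) + 2 * sd(ref))
  expect_error(filter_plasmid_contigs(toy, cov_threshold = "auto",
                                      ref_coverages = 12), ">= 2")
})

test_that("cog machinery tallies, measures and clusters profiles", {
  asg <- setNames(c("J", "J", "K", NA, "L"), paste0("g", 1:5))
  p <- cog_proportions(asg)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["J"]), 0.5)
  expect_equal(attr(p, "unassigned"), 1L)
  expect_error(cog_proportions(setNames(NA_character_, "g1")), "no assigned")

  # seeded random assignment matches brute-force tally
  set.seed(181)
  big <- setNames(sample(LETTERS[1:20], 500, replace = TRUE),
                  paste0("g", 1:500))
  pb <- cog_proportions(big)
  expect_equal(as.numeric(pb), as.numeric(table(factor(big, LETTERS)) / 500))

  expect_equal(cog_distance(p, p), 0)
  q <- cog_proportions(setNames(rep("A", 4), paste0("h", 1:4)))
  expect_equal(cog_distance(p, q), sqrt(sum((as.numeric(p) -
                                               as.numeric(q))^2)))

  # two tight clusters separate at the top split under complete linkage
  set.seed(191)
  base1 <- runif(20); base1 <- base1 / sum(base1)
  base2 <- rev(base1)
  mat <- rbind(t(replicate(4, base1 + runif(20, 0, 0.005))),
               t(replicate(4, base2 + runif(20, 0, 0.005))))
  rownames(mat) <- paste0(rep(c("x", "y"), each = 4), 1:4)
  hc <- cluster_profiles(mat)
  top <- cutree(hc, 2)
  expect_length(unique(top[1:4]), 1)
  expect_length(unique(top[5:8]), 1)
  expect_false(top[1] == top[5])

  # rank-1 toy matrix -> a single informative principal component
  toy <- outer(c(1, 2, 3), c(0.2, 0.3, 0.5))
  sc <- pca_profiles(toy)
  expect_gt(sd(sc[, 1]), 1e-8)
  expect_lt(max(abs(sc[, -1])), 1e-8)
})

test_that("select_phel takes the top-n by abundance with id tie-breaks", {
  ab <- setNames(c(5, 9, 9, 1), c("gB", "gC", "gA", "gD"))
  expect_identical(select_phel(ab, 1), "gA") # tie 9/9 broken by id
  expect_identical(select_phel(ab, 3), c("gA", "gC", "gB"))
  expect_warning(all4 <- select_phel(ab, 10), "exceeds")
  expect_length(all4, 4)

  set.seed(193)
  big <- setNames(runif(300), sprintf("g%03d", 1:300))
  got <- select_phel(big, 25)
  brute <- names(sort(big, decreasing = TRUE))[1:25]
  expect_setequal(got, brute)
})
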