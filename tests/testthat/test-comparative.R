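test_that("profile crosstabs tally ortholog pairs by category combination", {
  profs <- function(genes, cats) data.frame(gene = genes, category = cats,
                                            stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                      one_to_one = TRUE)
  pa <- profs(paste0("a", 1:4), rep("diploid", 4))
  pb <- profs(paste0("b", 1:4), rep("diploid", 4))
  ct <- crosstab_profiles(pairs, pa, pb)
  expect_equal(unname(ct$crosstab["diploid", "diploid"]), 4L)
  expect_equal(sum(ct$crosstab), 4L)
  expect_true(all(c("diploid", "complete_FD", "complete_CNV") %in%
                    rownames(ct$crosstab)))

  # six hand-built pairs over four category combinations
  pairs6 <- data.frame(gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6),
                       one_to_one = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  pa6 <- profs(paste0("a", 1:6),
               c("diploid", "diploid", "complete_FD", "complete_FD",
                 "complete_CNV", "diploid"))
  pb6 <- profs(paste0("b", 1:6),
               c("diploid", "complete_FD", "complete_FD", "complete_FD",
                 "complete_CNV", "diploid"))
  ct6 <- crosstab_profiles(pairs6, pa6, pb6)
  expect_equal(sum(ct6$crosstab), 5L)  # one-to-one only
  expect_equal(unname(ct6$crosstab["complete_FD", "complete_FD"]), 2L)
  expect_equal(unname(ct6$crosstab["diploid", "complete_FD"]), 1L)
  # marginals equal per-species category counts over scored pairs
  expect_equal(unname(rowSums(ct6$crosstab)["diploid"]), 2L)

  # unresolved pairs are reported, duplicates rejected
  pairs_na <- rbind(pairs, data.frame(gene_a = "missing", gene_b = "b1",
                                      one_to_one = TRUE))
  ctna <- crosstab_profiles(pairs_na, pa, pb)
  expect_equal(ctna$n_unresolved, 1L)
  expect_error(crosstab_profiles(rbind(pairs, pairs[1, ]), pa, pb),
               "duplicate")
})

test_that("conservation permutation test excludes diploid pairs and bounds p", {
  # perfectly conserved structure: observed beats every shuffle
  pc <- data.frame(cat_a = rep(c("complete_FD", "complete_CNV"), each = 10),
                   cat_b = rep(c("complete_FD", "complete_CNV"), each = 10))
  res <- permutation_conservation(pc, n_perm = 200L, seed = 4L)
  expect_equal(res$observed, 20L)
  expect_equal(res$p_value, 1 / 201)

  # diploid-diploid pairs are excluded from the retained set
  pc2 <- rbind(pc, data.frame(cat_a = rep("diploid", 30),
                              cat_b = rep("diploid", 30)))
  res2 <- permutation_conservation(pc2, n_perm = 50L, seed = 4L)
  expect_equal(res2$n_pairs, 20L)

  # matching is at FD/CNV class granularity by default
  pc3 <- data.frame(cat_a = c("partial_FD", "composite_CNV", "diploid"),
                    cat_b = c("complete_FD", "partial_CNV", "complete_FD"))
  res3 <- permutation_conservation(pc3, n_perm = 10L, seed = 1L)
  expect_equal(res3$observed, 2L)
  res3e <- permutation_conservation(pc3, n_perm = 10L, seed = 1L,
                                    match = "exact")
  expect_equal(res3e$observed, 0L)

  expect_error(permutation_conservation(
    data.frame(cat_a = "diploid", cat_b = "diploid")), "non-diploid")
})

test_that("disease enrichment permutation detects planted signal", {
  profs <- data.frame(gene = paste0("g", 1:40),
                      category = rep(c("diploid", "complete_FD"), 20))
  # disease set = entire universe: p must be 1
  res <- permutation_disease_enrichment(profs, profs$gene, n_perm = 100L,
                                        seed = 2L)
  expect_equal(res$p_value, 1)
  expect_error(permutation_disease_enrichment(profs, character(0)), "empty")

  # planted 3x enrichment among non-diploid genes is detected (power check)
  set.seed(33)
  hits <- replicate(60, {
    n <- 2000L
    nondip <- rep(c(TRUE, FALSE), c(400L, 1600L))
    p <- ifelse(nondip, 0.3, 0.1)
    disease <- runif(n) < p
    pr <- data.frame(gene = paste0("g", 1:n),
                     category = ifelse(nondip, "complete_CNV", "diploid"))
    r <- permutation_disease_enrichment(pr, pr$gene[disease],
                                        n_perm = 1000L,
                                        seed = sample.int(1e6, 1))
    r$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)

  # profile-change scope counts class changes over ortholog pairs
  pa <- data.frame(gene = c("a1", "a2", "a3"),
                   category = c("diploid", "complete_FD", "complete_CNV"))
  pb <- data.frame(gene = c("b1", "b2", "b3"),
                   category = c("complete_FD", "complete_FD", "diploid"))
  prs <- data.frame(gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"))
  r2 <- permutation_disease_enrichment(pa, c("a1", "a2"),
                                       scope = "profile_change",
                                       pairs = prs, profiles_b = pb,
                                       n_perm = 20L, seed = 1L)
  expect_equal(r2$n_qualifying, 2L)  # a1 and a3 change class
  expect_equal(r2$observed, 1L)      # of which a1 is disease-annotated
})

test_that("disease tables are filtered at the curated-score cutoff", {
  tf <- tempfile(fileext = ".tsv")
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    source = c("DisGeNET", "DisGeNET", "GWAS", "DisGeNET"),
                    score = c(0.05, 0.06, NA, 0.5))
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_disease_table(tf), c("g2", "g3", "g4"))
  expect_equal(read_disease_table(tf, source = "DisGeNET"), c("g2", "g4"))
  unlink(tf)
})
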