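make_table <- function() {
  m <- rbind(before = c(40, 30, 20, 10, 0),
             after = c(90, 0, 5, 0, 5))
  colnames(m) <- paste0("ASV", 1:5)
  m
}

test_that("rarefaction conserves depth, is seed-deterministic, and validates", {
  m <- make_table()
  r <- rarefy(m, depth = 50, seed = 1)
  expect_equal(unname(rowSums(r)), c(50, 50))
  expect_true(all(r <= m))                         # subsample of the original
  expect_identical(rarefy(m, 50, seed = 1), r)     # same seed, same table
  expect_false(identical(rarefy(m, 50, seed = 2), r))
  # a sample already at depth is unchanged
  r2 <- rarefy(m, 100, seed = 3)
  expect_equal(r2["before", ], m["before", ])
  expect_error(rarefy(m, 101, seed = 1), "before, after")
  expect_error(rarefy(m, 120, seed = 1), "after")
})

test_that("rarefaction is unbiased: mean counts approach depth * p_i", {
  m <- matrix(c(500, 300, 200), nrow = 1,
              dimnames = list("s", paste0("a", 1:3)))
  draws <- t(sapply(1:200, function(s) rarefy(m, 100, seed = s)[1, ]))
  expect_equal(unname(colMeans(draws)), c(50, 30, 20), tolerance = 0.05)
})

test_that("alpha diversity matches closed forms", {
  u <- alpha_diversity(setNames(rep(25, 4), paste0("a", 1:4)))
  expect_equal(u$richness, 4)
  expect_equal(u$shannon, log(4))
  expect_equal(u$inv_simpson, 4)

  one <- alpha_diversity(c(a = 17))
  expect_equal(unlist(one[, -1]), c(richness = 1, shannon = 0, inv_simpson = 1))

  d <- alpha_diversity(c(a = 50, b = 30, c = 20))
  p <- c(0.5, 0.3, 0.2)
  expect_equal(d$shannon, -sum(p * log(p)))
  expect_equal(d$inv_simpson, 1 / sum(p^2))
  expect_error(alpha_diversity(c(a = 0, b = 0)), "zero")
})

test_that("alpha diversity agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  m <- matrix(rpois(60, 20), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("a", 1:15)))
  d <- alpha_diversity(m)
  expect_equal(d$richness, unname(vegan::specnumber(m)))
  expect_equal(d$shannon, unname(vegan::diversity(m, "shannon")))
  expect_equal(d$inv_simpson, unname(vegan::diversity(m, "invsimpson")))
})

test_that("diversity indices are permutation-invariant and maximal at uniformity", {
  x <- c(a = 50, b = 30, c = 15, d = 5)
  shuffled <- x[c(3, 1, 4, 2)]
  expect_equal(alpha_diversity(x)[, -1], alpha_diversity(shuffled)[, -1])
  unif <- alpha_diversity(setNames(rep(25, 4), names(x)))
  skew <- alpha_diversity(x)
  expect_gt(unif$shannon, skew$shannon)
  expect_gt(unif$inv_simpson, skew$inv_simpson)
})

test_that("genus composition pools reads per genus and sums to 100", {
  m <- matrix(c(889, 61, 50), nrow = 1,
              dimnames = list("after", paste0("ASV", 1:3)))
  tax <- tibble::tibble(asv_id = paste0("ASV", 1:3),
                        genus = c("Burkholderia", "Burkholderia", "Klebsiella"))
  comp <- genus_composition(m, tax)
  expect_equal(comp$pct[comp$genus == "Burkholderia"], 95)
  expect_equal(sum(comp$pct), 100, tolerance = 1e-9)

  m2 <- matrix(c(889, 111), nrow = 1,
               dimnames = list("after", c("ASV1", "ASV2")))
  tax2 <- tibble::tibble(asv_id = c("ASV1", "ASV2"),
                         genus = c("Burkholderia", "Klebsiella"))
  comp2 <- genus_composition(m2, tax2)
  expect_equal(comp2$pct[comp2$genus == "Burkholderia"], 88.9)
})

test_that("unassigned ASVs fall into the NA category; missing taxonomy errors", {
  m <- make_table()
  tax <- tibble::tibble(asv_id = paste0("ASV", 1:5), genus = NA_character_)
  comp <- genus_composition(m, tax)
  expect_equal(unique(comp$genus), "NA")
  expect_equal(comp$pct, c(100, 100))

  expect_error(genus_composition(m, tax[1:3, ]), "ASV4")
})

test_that("rare genera collapse into Other only when below threshold everywhere", {
  m <- matrix(c(980, 15, 5, 500, 450, 50), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("ASV", 1:3)))
  tax <- tibble::tibble(asv_id = paste0("ASV", 1:3),
                        genus = c("A", "B", "C"))
  full <- genus_composition(m, tax)
  disp <- collapse_rare_genera(full, threshold = 2)
  # B exceeds 2% in s2, so stays; C is 0.5% and 5%: stays too (max rule)
  expect_setequal(unique(disp$genus), c("A", "B", "C"))
  disp2 <- collapse_rare_genera(full, threshold = 10)
  expect_true("Other" %in% disp2$genus)
  # pooled percentages still sum to 100 per sample
  sums <- tapply(disp2$pct, disp2$sample_id, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
})

test_that("Venn overlap counts shared and exclusive ASVs", {
  m <- make_table()
  v <- venn_overlap(m, "before", "after")
  expect_equal(v$shared, 2)   # ASV1, ASV3
  expect_equal(v$only_a, 2)   # ASV2, ASV4
  expect_equal(v$only_b, 1)   # ASV5
  expect_equal(v$union, v$shared + v$only_a + v$only_b)

  # 2 shared of union 32 -> 6.25%
  big <- rbind(a = c(rep(1, 2 + 21), rep(0, 9)),
               b = c(rep(1, 2), rep(0, 21), rep(1, 9)))
  colnames(big) <- paste0("x", 1:32)
  expect_equal(venn_overlap(big, "a", "b")$pct_shared, 6.25)

  # 23 shared of union 148 is reported unrounded
  big2 <- rbind(a = c(rep(1, 23 + 88), rep(0, 37)),
                b = c(rep(1, 23), rep(0, 88), rep(1, 37)))
  colnames(big2) <- paste0("x", 1:148)
  expect_equal(venn_overlap(big2, "a", "b")$pct_shared, 100 * 23 / 148)

  same <- venn_overlap(rbind(a = m[1, ], b = m[1, ]) , "a", "b")
  expect_equal(same$pct_shared, 100)
  disjoint <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  colnames(disjoint) <- paste0("x", 1:4)
  expect_equal(venn_overlap(disjoint, "a", "b")$pct_shared, 0)
  expect_error(venn_overlap(m, "before", "nope"), "Unknown sample")
})

test_that("QIIME2 lineages parse with empty and missing ranks as NA", {
  tx <- parse_qiime2_taxonomy(c(
    "d__Bacteria; p__Pseudomonadota; c__Gamma; o__Burkholderiales; f__Burkholderiaceae; g__Burkholderia",
    "d__Bacteria; p__Firmicutes; g__",
    "Unassigned"))
  expect_equal(tx$genus, c("Burkholderia", NA, NA))
  expect_equal(tx$phylum, c("Pseudomonadota", "Firmicutes", NA))
})

test_that("count containers are validated and data frames are accepted", {
  df <- tibble::tibble(sample_id = c("s1", "s2"),
                       ASV1 = c(5L, 2L), ASV2 = c(0L, 7L))
  m <- as_asv_matrix(df)
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m), c("s1", "s2"))
  expect_error(as_asv_matrix(matrix(-1, 1, 1, dimnames = list("s", "a"))),
               "non-negative")
  bad <- matrix(c(1.5, 2), 1, 2, dimnames = list("s", c("a", "b")))
  expect_error(as_asv_matrix(bad), "integer")
  empty <- matrix(0, 1, 2, dimnames = list("s", c("a", "b")))
  expect_error(as_asv_matrix(empty), "positive total")
})
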