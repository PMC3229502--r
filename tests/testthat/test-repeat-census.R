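test_that("overlap clustering joins true overlaps and respects the 100-bp boundary", {
  set.seed(61)
  base <- rand_dna(400)
  ten <- rec(sprintf("c%02d", 1:10), rep(base, 10))
  cl <- greedy_overlap_cluster(ten)
  expect_equal(unique(cl$cluster_size), 10L)
  expect_equal(length(unique(cl$cluster)), 1L)

  # overlap of exactly 99 bases at 100% identity must NOT cluster at 100
  shared99 <- rand_dna(99)
  pair99 <- rec(c("l", "r"), c(paste0(rand_dna(200), shared99),
                               paste0(shared99, rand_dna(200))))
  cl99 <- greedy_overlap_cluster(pair99, cluster_params(min_overlap = 100))
  expect_equal(cl99$cluster_size, c(1L, 1L))
  shared100 <- rand_dna(100)
  pair100 <- rec(c("l", "r"), c(paste0(rand_dna(200), shared100),
                                paste0(shared100, rand_dna(200))))
  cl100 <- greedy_overlap_cluster(pair100, cluster_params(min_overlap = 100))
  expect_equal(cl100$cluster_size, c(2L, 2L))

  # reverse-complement overlaps count as overlaps
  rcpair <- rec(c("f", "r"), c(paste0(rand_dna(150), shared100),
                               revcomp(paste0(shared100, rand_dna(150)))))
  expect_equal(greedy_overlap_cluster(rcpair)$cluster_size, c(2L, 2L))
})

test_that("a planted read family separates from unique background", {
  set.seed(62)
  fam_read <- rand_dna(600)
  noisy <- vapply(1:25, function(i) {
    v <- strsplit(fam_read, "")[[1]]
    hit <- which(runif(600) < 0.02)
    v[hit] <- chartr("ACGT", "CATG", v[hit])
    paste(v, collapse = "")
  }, character(1))
  reads <- rec(sprintf("r%02d", 1:55),
               c(noisy, vapply(1:30, function(i) rand_dna(600), character(1))))
  cl <- greedy_overlap_cluster(reads)
  sizes <- sort(unique(cl$cluster_size), decreasing = TRUE)
  expect_equal(sizes, c(25L, 1L))
  expect_equal(sum(cl$cluster_size == 25), 25L)
  # every read in exactly one cluster
  expect_equal(sum(table(cl$cluster)), 55L)
})

test_that("cluster membership is invariant to input order", {
  set.seed(63)
  g <- generate_gss_reads(60, seed = 63)
  cl1 <- greedy_overlap_cluster(g$records)
  perm <- sample(nrow(g$records))
  cl2 <- greedy_overlap_cluster(g$records[perm, ])
  part <- function(cl) {
    unname(lapply(split(cl$id, cl$cluster), sort)[
      order(vapply(split(cl$id, cl$cluster), min, character(1)))])
  }
  expect_identical(part(cl1), part(cl2))
  # cluster numbering itself is also reproducible
  expect_identical(cl1$cluster, cl2$cluster[match(cl1$id, cl2$id)])
})

test_that("repetitiveness classes split at the >20-read boundary", {
  cl <- tibble::tibble(id = c("a", "b", "c"), cluster = 1:3,
                       cluster_size = c(21L, 20L, 1L))
  out <- classify_repetitiveness(cl)
  expect_equal(out$category, c("highly_repetitive", "repetitive", "unique"))
})

test_that("simple repeat finder reports primitive units in minimal rotation", {
  set.seed(64)
  s <- paste0(rand_dna(50), strrep("CACG", 6), rand_dna(50))
  hit <- find_simple_repeats(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "ACGC")          # minimal rotation of CACG
  # span covers the planted run; chance in-phase flank bases may extend it
  expect_lte(hit$start, 50L)
  expect_gte(hit$end, 74L)
  expect_lte(hit$length, 24L + 8L)

  at <- find_simple_repeats(paste0(rand_dna(30), strrep("AT", 10), rand_dna(30)))
  expect_equal(at$unit, "AT")             # smallest period, not A or T or ATAT

  # tolerate one substitution inside a planted run
  noisy <- paste0(rand_dna(40), swap_at(strrep("CTG", 10), 14), rand_dna(40))
  expect_gte(sum(find_simple_repeats(noisy)$length), 12)
})

test_that("simple repeat content of random sequence stays below 5%", {
  set.seed(65)
  for (i in 1:5) {
    s <- rand_dna(1000)
    hits <- find_simple_repeats(s)
    expect_lt(sum(hits$length) / 1000, 0.05)
  }
})

test_that("entropy masking flags skewed tracts with dominant-base labels", {
  c100 <- find_low_complexity(strrep("C", 100))
  expect_equal(nrow(c100), 1L)
  expect_equal(c100$label, "C-rich")
  expect_equal(c(c100$start, c100$end), c(0L, 100L))

  ga <- find_low_complexity(strrep("GA", 50))
  expect_equal(unique(ga$label), "AG-rich")

  set.seed(66)
  s <- rand_dna(10000)
  flagged <- find_low_complexity(s)
  expect_lt(sum(flagged$end - flagged$start) / 10000, 0.01)
})

test_that("feature census implements the pie-vs-actual double accounting", {
  # one read, one feature: both percentages are 100
  cen1 <- feature_census(rec("a", "ACGTACGT"),
                         tibble::tibble(id = "a", feature = "genes"))
  expect_equal(cen1$pct_pie, 100)
  expect_equal(cen1$pct_actual, 100)

  # a read under two features doubles the pie denominator, not the actual one
  reads <- tibble::tibble(id = c("a", "b"), length = c(600L, 400L))
  ann <- tibble::tibble(id = c("a", "a", "b"),
                        feature = c("simple_repeats", "low_complexity",
                                    "simple_repeats"))
  cen <- feature_census(reads, ann)
  expect_equal(attr(cen, "actual_total_bp"), 1000L)
  expect_equal(attr(cen, "pie_total_bp"), 1600L)
  expect_equal(sum(cen$pct_pie), 100)
  sr <- cen[cen$feature == "simple_repeats", ]
  expect_equal(sr$pct_actual, 100)
  expect_equal(sr$pct_pie, 62.5)

  # unannotated reads land in no_feature and actual percentages of a
  # partition sum to 100
  cen2 <- feature_census(tibble::tibble(id = c("x", "y"), length = c(1L, 3L)),
                         tibble::tibble(id = "x", feature = "genes"))
  expect_setequal(cen2$feature, c("genes", "no_feature"))
  expect_equal(sum(cen2$pct_actual), 100)
})

test_that("genome-size arithmetic follows the pg formula", {
  expect_equal(genome_size_from_pg(1), 9.21e8)
  expect_equal(sample_fraction(2e6, 10), 2 * sample_fraction(1e6, 10))
  expect_error(genome_size_from_pg(0), "positive")
  expect_error(sample_fraction(-1, 10), "positive")
})

test_that("census recovers a planted composition within 15% relative", {
  comp <- c(repeat_2 = 0.25, repeat_4 = 0.25, simple_repeat = 0.15,
            low_complexity = 0.10, unique = 0.25)
  fam <- aost_repeat_units()[c(2, 4), ]
  g <- generate_gss_reads(300, composition = comp, families = fam, seed = 67)
  arr <- annotate_arrays(g$records)
  feats <- annotate_read_features(g$records, arrays = arr)
  by_read <- split(feats$feature, feats$id)
  classify <- function(f) {
    if ("tandem_array" %in% f) "tandem"
    else if ("simple_repeats" %in% f) "simple_repeat"
    else if ("low_complexity" %in% f) "low_complexity"
    else "unique"
  }
  recovered <- setNames(rep("unique", nrow(g$records)), g$records$id)
  recovered[names(by_read)] <- vapply(by_read, classify, character(1))
  planted <- table(g$truth$category)
  found <- table(factor(recovered[g$truth$id], levels = names(planted)))
  for (catg in names(planted)) {
    expect_lt(abs(found[[catg]] - planted[[catg]]) / planted[[catg]], 0.15)
  }
})
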