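test_that("detect_period recovers the unit length of exact and noisy arrays", {
  units <- aost_repeat_units()
  for (i in 1:4) {
    expect_equal(detect_period(strrep(units$unit[i], 5)), units$unit_length[i])
  }
  set.seed(51)
  u <- rand_dna(64)
  noisy <- paste(replicate(4, {
    v <- strsplit(u, "")[[1]]
    hit <- which(runif(64) < 0.05)
    v[hit] <- chartr("ACGT", "CATG", v[hit])
    paste(v, collapse = "")
  }), collapse = "")
  expect_equal(detect_period(noisy), 64L)
})

test_that("detect_period returns none on random sequence, matching a lag-scan oracle", {
  set.seed(52)
  for (i in 1:5) {
    s <- rand_dna(500)
    v <- strsplit(s, "")[[1]]
    oracle <- max(vapply(20:250, function(p) {
      mean(v[1:(500 - p)] == v[(p + 1):500])
    }, numeric(1)))
    expect_lt(oracle, 0.85)
    expect_true(is.na(detect_period(s)))
  }
})

test_that("detect_period is exact for whole-unit tilings over random units", {
  set.seed(53)
  for (i in 1:10) {
    p <- sample(20:300, 1)
    u <- rand_dna(p)
    k <- sample(3:5, 1)
    expect_equal(detect_period(strrep(u, k), max_p = 300), p)
  }
})

test_that("extract_unit_consensus recovers units and flags divergent copies", {
  r3 <- aost_repeat_units()$unit[3]
  ex <- extract_unit_consensus(strrep(r3, 5), 88)
  expect_identical(ex$consensus, r3)
  expect_equal(ex$per_unit_identity, rep(1, 5))
  expect_equal(ex$n_units, 5L)

  # one copy carrying ~10% substitutions is itself ~0.90 to the consensus
  copies <- rep(r3, 6)
  copies[3] <- swap_at(r3, seq(1, 88, by = 10))
  ex2 <- extract_unit_consensus(paste(copies, collapse = ""), 88)
  expect_identical(ex2$consensus, r3)
  expect_equal(ex2$per_unit_identity[3], 1 - 9 / 88)
  expect_true(all(ex2$per_unit_identity[-3] == 1))

  # symmetric 2% noise over >= 6 copies: majority vote recovers the unit,
  # cross-checked against a per-column tally oracle
  set.seed(54)
  u <- rand_dna(60)
  noisy <- vapply(1:8, function(j) {
    v <- strsplit(u, "")[[1]]
    hit <- which(runif(60) < 0.02)
    v[hit] <- chartr("ACGT", "CATG", v[hit])
    paste(v, collapse = "")
  }, character(1))
  ex3 <- extract_unit_consensus(paste(noisy, collapse = ""), 60)
  mat <- do.call(rbind, strsplit(noisy, ""))
  oracle <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  })
  expect_identical(ex3$consensus, paste(oracle, collapse = ""))
  expect_identical(ex3$consensus, u)
  expect_error(extract_unit_consensus("ACGTACGT", 5), "2 complete units")
})

test_that("annotate_arrays finds flanked arrays and nothing in random reads", {
  r2 <- aost_repeat_units()$unit[2]
  set.seed(55)
  s <- paste0(rand_dna(100), strrep(r2, 4), rand_dna(100))
  arr <- annotate_arrays(rec("x", s))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$unit_length, 79L)
  expect_equal(arr$n_units, 4L)
  expect_lte(abs(arr$start - 100), 79)      # span correct to one unit boundary
  expect_lte(abs(arr$end - (100 + 4 * 79)), 79)

  expect_equal(nrow(annotate_arrays(rec("r", rand_dna(800)))), 0L)

  r1 <- aost_repeat_units()$unit[1]
  two <- paste0(strrep(r2, 3), rand_dna(200), strrep(r1, 3))
  arr2 <- annotate_arrays(rec("y", two))
  expect_equal(nrow(arr2), 2L)
  expect_setequal(arr2$unit_length, c(79L, 97L))
})

test_that("family fraction implements n_units x unit_length x n_reads / total", {
  one <- tibble::tibble(id = "c1", n_units = 10L, unit_length = 100L,
                        n_reads = 5L, family = "f")
  expect_equal(estimate_family_fraction(one, 1e5)$fraction_pct, 5.0)
  # linear in n_units and n_reads
  twice_units <- dplyr::mutate(one, n_units = n_units * 2L)
  twice_reads <- dplyr::mutate(one, n_reads = n_reads * 2L)
  expect_equal(estimate_family_fraction(twice_units, 1e5)$fraction_pct, 10.0)
  expect_equal(estimate_family_fraction(twice_reads, 1e5)$fraction_pct, 10.0)
  empty <- one[0, ]
  expect_equal(nrow(estimate_family_fraction(empty, 1e5)), 0L)
  expect_error(estimate_family_fraction(one, 0), "positive")
})

test_that("shared_segment reports the published repeat 3/4 overlap and self-identity", {
  u <- aost_repeat_units()
  ss <- shared_segment(u$unit[3], u$unit[4], min_len = 40)
  expect_equal(ss$length, 60L)
  expect_equal(ss$identity, 56 / 60)
  expect_equal(round(100 * ss$identity), 93)
  expect_equal(ss$start_a, 28L)
  expect_equal(ss$start_b, 0L)

  self <- shared_segment(u$unit[1], u$unit[1], min_len = 40)
  expect_equal(self$length, 97L)
  expect_equal(self$identity, 1.0)
})

test_that("shared_segment finds nothing between random units (window-scan oracle)", {
  set.seed(56)
  a <- rand_dna(88); b <- rand_dna(88)
  va <- strsplit(a, "")[[1]]
  oracle_best <- 0
  for (bb in c(b, revcomp(b))) {
    vb <- strsplit(bb, "")[[1]]
    for (o in -(88 - 40):(88 - 40)) {
      ia <- max(1, 1 + o); ib <- max(1, 1 - o)
      len <- min(88 - ia, 88 - ib) + 1
      if (len < 40) next
      mm <- va[ia:(ia + len - 1)] == vb[ib:(ib + len - 1)]
      for (w in 40:len) for (st in 1:(len - w + 1)) {
        oracle_best <- max(oracle_best, mean(mm[st:(st + w - 1)]))
      }
    }
  }
  expect_lt(oracle_best, 0.80)
  expect_null(shared_segment(a, b, min_len = 40))
})

test_that("in_silico_digest cuts once per repeat into a unit ladder", {
  set.seed(57)
  site <- "GGGTT"  # non-palindromic so strand handling is visible
  make_unit <- function() paste0(rand_dna(40), site, rand_dna(52))
  unit <- make_unit()                              # one site per 97-bp unit
  while (length(gregexpr(site, strrep(unit, 2), fixed = TRUE)[[1]]) != 2 ||
         grepl(revcomp(site), strrep(unit, 2), fixed = TRUE)) {
    unit <- make_unit()
  }
  frags <- in_silico_digest(strrep(unit, 10), site)
  expect_equal(sum(frags == 97), 9)
  expect_equal(length(frags), 11L)
  expect_equal(sum(frags[frags != 97]), 97)
  expect_equal(in_silico_digest("ACGTACGTAA", "GGCC"), 10L)
})

test_that("digest fragments match a naive occurrence-scan oracle on random input", {
  set.seed(58)
  for (i in 1:10) {
    s <- rand_dna(2000)
    site <- rand_dna(4)
    naive_hits <- function(seq, pat) {
      m <- nchar(pat)
      which(vapply(1:(nchar(seq) - m + 1),
                   function(j) substr(seq, j, j + m - 1) == pat, logical(1)))
    }
    cuts <- sort(unique(c(naive_hits(s, site), naive_hits(s, revcomp(site))))) - 1L
    cuts <- cuts[cuts > 0]
    oracle <- sort(diff(c(0L, cuts, 2000L)))
    frags <- in_silico_digest(s, site)
    expect_identical(frags, as.integer(oracle))
    expect_equal(sum(frags), 2000L)
  }
})

test_that("reference-seeded family assignment groups rotated and reversed units", {
  u <- aost_repeat_units()
  set.seed(59)
  # arrays whose consensus is a rotation / reverse complement of a reference
  rot <- paste0(substr(u$unit[1], 31, 97), substr(u$unit[1], 1, 30))
  arrays <- tibble::tibble(
    id = c("a", "b", "c"), start = 0L, end = c(291L, 291L, 316L),
    unit_length = c(97L, 97L, 79L), n_units = 3L,
    unit_consensus = c(rot, revcomp(u$unit[1]), u$unit[2]),
    mean_identity = 1, min_identity = 1,
    per_unit_identity = replicate(3, rep(1, 3), simplify = FALSE))
  fam <- assign_repeat_families(arrays, ref_units = u)
  expect_equal(fam$family, c("repeat_1", "repeat_1", "repeat_2"))
})
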