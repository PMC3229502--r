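test_that("sl_config derives the relict motif from the consensus", {
  cfg <- sl_config()
  expect_equal(nchar(cfg$sl_consensus), 22L)
  expect_identical(cfg$relict_motif, substr(cfg$sl_consensus, 8, 22))
  expect_error(sl_config(sl_consensus = "ACGT"), "22")
  expect_error(sl_config(relict_floor = 0), "relict_floor")
})

test_that("find_canonical_sl finds planted leaders and scores mismatches", {
  cfg <- sl_config()
  sl <- resolved_sl(cfg)
  set.seed(41)
  ests <- rec(c("clean", "mut2", "offset"),
              c(paste0(sl, rand_dna(200)),
                paste0(swap_at(sl, c(3, 12)), rand_dna(200)),
                paste0(rand_dna(10), sl, rand_dna(150))))
  m <- find_canonical_sl(ests, cfg)
  expect_equal(m$sl_start[m$id == "clean"], 0L)
  expect_equal(m$sl_identity[m$id == "clean"], 1.0)
  expect_equal(m$sl_identity[m$id == "mut2"], 20 / 22)
  expect_equal(m$sl_start[m$id == "offset"], 10L)
})

test_that("find_canonical_sl agrees with an exhaustive window oracle on SL-free ESTs", {
  cfg <- sl_config()
  set.seed(42)
  for (i in 1:10) {
    s <- rand_dna(200)
    oracle <- max(vapply(0:(60 - 22), function(p) {
      iupac_identity(cfg$sl_consensus, substr(s, p + 1, p + 22))
    }, numeric(1)))
    hit <- find_canonical_sl(rec("x", s), cfg)
    if (oracle >= cfg$canonical_min_identity) {
      expect_equal(nrow(hit), 1L)
    } else {
      expect_equal(nrow(hit), 0L)
    }
  }
})

test_that("dedupe_and_trim trims at the SL and collapses near-duplicates", {
  cfg <- sl_config()
  sl <- resolved_sl(cfg)
  set.seed(43)
  body <- rand_dna(300)
  ests <- rec(c("a", "b"), rep(paste0(rand_dna(5), sl, body), 2))
  m <- find_canonical_sl(ests, cfg)
  u <- dedupe_and_trim(ests, m)
  expect_equal(attr(u, "n_unique"), 1L)
  expect_equal(u$n_members, 2L)
  # trimming removes exactly the bases 5' of the SL interval
  expect_identical(u$seq[1], paste0(sl, body))

  # 10 ESTs from 4 transcripts with 1% resequencing noise -> 4 uniques
  transcripts <- replicate(4, paste0(sl, rand_dna(400)))
  reads <- vapply(c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4), function(t) {
    full <- transcripts[t]
    v <- strsplit(full, "")[[1]]
    hit <- which(stats::runif(length(v)) < 0.01)
    v[hit] <- chartr("ACGT", "CATG", v[hit])
    paste(v, collapse = "")
  }, character(1))
  ests10 <- rec(sprintf("e%02d", 1:10), reads)
  u10 <- dedupe_and_trim(ests10, find_canonical_sl(ests10, cfg))
  expect_equal(attr(u10, "n_unique"), 4L)
})

test_that("scan_relict_chain follows the greedy contract on constructed cascades", {
  cfg <- sl_config()
  sl <- resolved_sl(cfg)
  motif <- substr(sl, 8, 22)
  inert <- strrep("GC", 100)  # no 15-window reaches the 0.5 floor
  worst <- max(vapply(0:20, function(p) {
    iupac_identity(cfg$relict_motif, substr(inert, p + 1, p + 15))
  }, numeric(1)))
  expect_lt(worst, cfg$relict_floor)

  ch1 <- scan_relict_chain(rec("x", paste0(sl, motif, inert)), cfg)
  expect_equal(ch1$k, 1L)
  expect_equal(ch1$identities[[1]], 1.0)
  expect_equal(ch1$starts[[1]], 22L)

  # 6 substitutions -> identity 9/15 = 0.60, accepted; 7 leave 8/15 = 0.533,
  # still at or above the 0.50 floor; 8 fall below it
  ch6 <- scan_relict_chain(rec("x", paste0(sl, swap_at(motif, 1:6), inert)), cfg)
  expect_equal(ch6$k, 1L)
  expect_equal(ch6$identities[[1]], 9 / 15)
  ch7 <- scan_relict_chain(rec("x", paste0(sl, swap_at(motif, 1:7), inert)), cfg)
  expect_equal(ch7$k, 1L)
  expect_equal(ch7$identities[[1]], 8 / 15)
  dead <- swap_at(motif, seq(1, 15, by = 2))       # 8 substitutions
  s8 <- paste0(sl, dead, inert)
  oracle8 <- vapply(0:3, function(o) {
    iupac_identity(cfg$relict_motif, substr(s8, 23 + o, 37 + o))
  }, numeric(1))
  expect_true(all(oracle8 < cfg$relict_floor))
  ch8 <- scan_relict_chain(rec("x", s8), cfg)
  expect_equal(ch8$k, 0L)

  # two stacked relicts, the second shifted by 2 bases of slack
  s2 <- paste0(sl, motif, "GC", motif, inert)
  ch2 <- scan_relict_chain(rec("x", s2), cfg)
  expect_equal(ch2$k, 2L)
  expect_equal(ch2$starts[[1]], c(22L, 39L))

  short <- scan_relict_chain(rec("x", substr(sl, 1, 22)), cfg)
  expect_equal(short$k, 0L)
  expect_equal(short$flag, "too_short")
})

test_that("relict scan rarely undercalls planted depth and identities decay by rank", {
  g <- generate_sl_ests(300, depth_probs = c(0.1, 0.2, 0.3, 0.2, 0.2),
                        per_cycle_sub_rate = 0.05, seed = 44)
  ch <- scan_relict_chain(g$records)
  # undercalls need an off-offset window to outscore a true copy: rare
  expect_lte(mean(ch$k < g$truth$depth), 0.02)
  cs <- classify_chain_counts(ch)
  ranks <- cs$ranks[cs$ranks$n >= 20, ]
  expect_true(all(diff(ranks$mean_identity) <= 0.02))
})

test_that("null chain acceptance matches the binomial-union prediction", {
  g0 <- generate_sl_ests(2000, depth_probs = c(1, 0, 0, 0, 0), seed = 45)
  ch0 <- scan_relict_chain(g0$records)
  rate <- mean(ch0$k > 0)
  # one accept chance per record: max over 4 near-independent 15-nt windows,
  # each clearing 8/15 matches with prob 1 - pbinom(7, 15, 0.25)
  pred <- 1 - pbinom(7, 15, 0.25)^4
  se <- sqrt(pred * (1 - pred) / 2000)
  expect_lt(abs(rate - pred), 4 * se + 0.01)
})

test_that("chain summaries normalise and track planted depth distributions", {
  flat <- tibble::tibble(id = letters[1:5], k = 0L,
                         identities = replicate(5, numeric(0), simplify = FALSE),
                         starts = replicate(5, integer(0), simplify = FALSE),
                         flag = NA_character_)
  cs <- classify_chain_counts(flat)
  expect_equal(cs$histogram$n, 5L)
  expect_equal(sum(cs$histogram$fraction), 1)

  probs <- c(0.74, 0.21, 0.04, 0.008, 0.002)
  g <- generate_sl_ests(500, depth_probs = probs, seed = 46)
  truth_chains <- tibble::tibble(id = g$truth$id, k = g$truth$depth)
  hist <- classify_chain_counts(truth_chains)$histogram
  expect_equal(sum(hist$fraction), 1)
  for (d in 0:1) {
    se <- sqrt(probs[d + 1] * (1 - probs[d + 1]) / 500)
    expect_lt(abs(hist$fraction[hist$k == d] - probs[d + 1]), 4 * se)
  }
  gl <- glance(classify_chain_counts(truth_chains))
  expect_equal(gl$n_records, 500L)
  expect_equal(gl$n_with_relict, sum(g$truth$depth > 0))
})
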