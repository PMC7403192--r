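fix <- nmdarSharedClonotypeCells()
fix_heavy <- fix[fix$locus == "IGH", ]

test_that("gene usage counts families with fractional tie weighting", {
  one <- fix_heavy[1, ]
  u <- geneUsage(one, "V", "family")
  expect_equal(u$label, "IGHV1")
  expect_equal(u$count, 1)
  expect_equal(u$frequency, 1)
  u13 <- geneUsage(fix_heavy, "V", "family")
  expect_equal(u13$count[u13$label == "IGHV1"], 11)
  expect_equal(u13$frequency[u13$label == "IGHV1"], 11 / 13, tolerance = 1e-9)
  expect_equal(u13$frequency[u13$label == "IGHV4"], 2 / 13, tolerance = 1e-9)
  expect_equal(sum(u13$frequency), 1)
  # tied multi-calls split their weight: total weight stays one per record
  ud <- geneUsage(fix_heavy, "D", "allele")
  expect_equal(sum(ud$count), 13)
  expect_equal(ud$count[ud$label == "IGHD1-26*01"], 11 / 3, tolerance = 1e-9)
  expect_error(geneUsage(fix_heavy[0, ], "V"), "no records")
})

test_that("zero-filling exposes germline families absent from the records", {
  u <- geneUsage(fix_heavy, "V", "family", locus = "IGH", zero_fill = toy_db)
  expect_true(all(c("IGHV3", "IGHV5") %in% u$label))
  expect_equal(u$count[u$label == "IGHV5"], 0)
})

test_that("the V-J matrix holds exactly the observed combinations with usage-consistent margins", {
  m <- vjMatrix(fix_heavy, level = "allele")
  expect_equal(sum(m > 0), 2)
  expect_equal(m["IGHV1-18*04", "IGHJ3*02"], 11)
  expect_equal(m["IGHV4-39*01", "IGHJ4*02"], 2)
  expect_equal(sum(m), 13)
  # cross-module consistency: margins equal geneUsage counts at same level
  sim <- simulateCohort(simulationConfig(n_patients = 2,
                                         cells_per_patient = 8,
                                         shm_rate = 0.01, seed = 61), toy_db)
  rec <- annotateVdj(sim$sequences, toy_db, verbose = FALSE)
  heavy <- rec[rec$locus == "IGH" & nzchar(rec$j_call), ]
  m2 <- vjMatrix(heavy, level = "allele")
  uv <- geneUsage(heavy, "V", "allele")
  uj <- geneUsage(heavy, "J", "allele")
  expect_equal(rowSums(m2)[uv$label], setNames(uv$count, uv$label),
               tolerance = 1e-9)
  expect_equal(colSums(m2)[uj$label], setNames(uj$count, uj$label),
               tolerance = 1e-9)
})

test_that("CDR3 length distribution reports histogram, modes and normality", {
  d <- cdr3LengthDistribution(fix_heavy)
  expect_equal(d$modes, 14)
  expect_equal(d$histogram$count[d$histogram$length == 14], 11)
  expect_equal(d$n, 13)
  # all-identical lengths: test undefined, histogram still returned
  same <- fix_heavy[fix_heavy$cdr3_aa == "ARVGSKYGFETFDI", ]
  ds <- cdr3LengthDistribution(same)
  expect_true(is.na(ds$shapiro_w))
  expect_match(ds$note, "undefined")
  expect_equal(ds$histogram, data.frame(length = 14L, count = 11L))
  # order invariance
  d2 <- cdr3LengthDistribution(fix_heavy[rev(seq_len(13)), ])
  expect_equal(d2$histogram, d$histogram)
})

test_that("the normality gate accepts normal samples and rejects skewed ones", {
  # note: integer-rounded lengths at large n are reliably rejected by
  # Shapiro-Wilk (discreteness), so the gate is exercised on continuous
  # draws for the accept case and on log-normal draws for the reject case
  pass <- rej <- 0
  set.seed(62)
  for (r in 1:100) {
    if (cdr3LengthDistribution(rnorm(200, 15, 2))$shapiro_p > 0.05)
      pass <- pass + 1
    if (cdr3LengthDistribution(exp(rnorm(200, 2.7, 0.5)))$shapiro_p <= 0.05)
      rej <- rej + 1
  }
  expect_gte(pass, 90)
  expect_gte(rej, 90)
})

test_that("the Shapiro-Wilk routine matches an independent reference to 1e-4", {
  # W and p frozen from an independent implementation (scipy.stats.shapiro)
  v1 <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  v2 <- c(2.1, 3.4, 1.9, 2.8, 3.0, 2.2, 2.5, 3.1, 2.9, 2.4, 2.6, 3.3, 2.0, 2.7)
  expect_equal(unname(shapiro.test(v1)$statistic), 0.788815, tolerance = 1e-4)
  expect_equal(shapiro.test(v1)$p.value, 0.00670381, tolerance = 1e-3)
  expect_equal(unname(shapiro.test(v2)$statistic), 0.967015, tolerance = 1e-4)
})

test_that("mutation rate summaries give the five-number box-plot statistics", {
  rec <- data.frame(sequence_id = letters[1:5],
                    v_mutation_count = c(0L, 3L, 6L, 9L, 12L),
                    v_germline_aligned_length = 300L,
                    stringsAsFactors = FALSE)
  s <- mutationRateSummary(rec)
  expect_equal(unname(s$summary["median"]), 0.02)
  expect_equal(unname(s$summary["min"]), 0)
  expect_equal(unname(s$summary["max"]), 0.04)
  rec0 <- rec; rec0$v_mutation_count <- 0L
  expect_true(all(mutationRateSummary(rec0)$summary == 0))
  # zero aligned length excluded with a message
  rec$v_germline_aligned_length[2] <- 0L
  expect_message(s2 <- mutationRateSummary(rec), "excluded")
  expect_equal(s2$n, 4)
})

test_that("test selection is gated on per-group normality", {
  set.seed(63)
  a <- rnorm(30, 10, 1)
  b <- rnorm(30, 10.5, 1)
  skew <- exp(rnorm(30, 0, 1.5))
  expect_equal(compareGroups(a, b)$test, "t")
  expect_equal(compareGroups(a, skew)$test, "wilcoxon")
  # identical groups are never significant and degenerate ones report p = 1
  same <- compareGroups(a, a)
  expect_equal(same$test, "t")
  expect_gte(same$p_value, 0.99)
  deg <- compareGroups(rep(1, 5), rep(1, 5))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_false(deg$significant)
  expect_error(compareGroups(a, c(1, 2)), "n >= 3")
  # three groups route to ANOVA / Kruskal-Wallis
  expect_equal(compareGroups(a, b, rnorm(30, 9))$test, "anova")
  expect_equal(compareGroups(a, b, skew)$test, "kruskal")
})

test_that("light-chain class counts test the lambda excess binomially", {
  lights <- fix[fix$locus != "IGH", ]
  lc <- lightChainClassCounts(lights)
  expect_equal(lc$lambda_fraction, 1)
  expect_equal(lc$lambda, 13)
  fake <- data.frame(locus = rep(c("IGK", "IGL"), c(25, 25)))
  expect_equal(lightChainClassCounts(fake)$p_value, 1)
  skewed <- data.frame(locus = rep(c("IGK", "IGL"), c(10, 90)))
  lcs <- lightChainClassCounts(skewed)
  expect_lt(lcs$p_value, 0.05)
  expect_equal(lcs$p_value, binom.test(90, 100, 0.5)$p.value)
  expect_error(lightChainClassCounts(fix_heavy), "no light-chain")
})
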