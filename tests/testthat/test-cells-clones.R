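fix <- nmdarSharedClonotypeCells()
fix_cells <- assembleCells(fix)

test_that("the four completeness cardinality cases classify as stated", {
  expect_equal(classifyCompleteness(1, 1), "complete")
  expect_equal(classifyCompleteness(1, 2), "complete")
  expect_equal(classifyCompleteness(3, 1), "complete")
  expect_equal(classifyCompleteness(2, 2), "incomplete")
  expect_equal(classifyCompleteness(1, 0), "incomplete")
  expect_equal(classifyCompleteness(0, 2), "incomplete")
})

test_that("cells assemble one per (patient, cell) with chains split by class", {
  expect_equal(nCells(fix_cells), 13)
  info <- cellInfo(fix_cells)
  expect_true(all(info$n_heavy == 1 & info$n_light == 1))
  expect_true(all(info$completeness == "complete"))
  # complete + incomplete always partition the cells
  expect_equal(sum(info$completeness == "complete") +
                 sum(info$completeness == "incomplete"), nCells(fix_cells))
  expect_equal(nCells(assembleCells(fix[0, ])), 0)
})

test_that("a cell_id shared by two patients is an error", {
  bad <- fix
  bad$patient_id[2] <- "PA99"
  expect_error(assembleCells(bad), "more than one patient")
})

test_that("clone clustering groups same V/J/junction across patients and splits on one residue", {
  rec <- data.frame(
    sequence_id = c("a", "b", "c"),
    patient_id = c("PA1", "PA2", "PA3"),
    locus = "IGH",
    v_call = "IGHV1-18*04", d_call = "",
    j_call = "IGHJ3*02",
    junction_aa = c("CARVGSKYGFETFDIW", "CARVGSKYGFETFDIW",
                    "CARVGSKYGFETFDVW"),
    productive = TRUE, stringsAsFactors = FALSE)
  cl <- clusterClones(rec)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$n_records), c(1, 2))
  big <- cl[cl$n_records == 2, ]
  expect_equal(big$n_patients, 2)
  expect_equal(big$cdr3_aa, "ARVGSKYGFETFDI")
})

test_that("clustering equals the brute-force pairwise-closure oracle on random records", {
  for (seed in c(51, 52, 53)) {
    rec <- random_records(50, seed)
    cl <- clusterClones(rec)
    mem <- attr(cl, "members")
    got <- canonical_partition(split(mem$sequence_id, mem$clone_id))
    want <- canonical_partition(oracle_clone_partition(rec))
    expect_equal(got, want, info = paste("seed", seed))
    # partition property: every usable record in exactly one clone
    expect_setequal(mem$sequence_id, rec$sequence_id)
  }
})

test_that("gene-level matching merges alleles of the same gene", {
  rec <- data.frame(
    sequence_id = c("a", "b"), patient_id = c("PA1", "PA2"), locus = "IGL",
    v_call = c("IGLV1-40*01", "IGLV1-40*02"), d_call = "",
    j_call = c("IGLJ3*01", "IGLJ3*02"),
    junction_aa = "CQSYDRSLSGYWVF", productive = TRUE,
    stringsAsFactors = FALSE)
  expect_equal(nrow(clusterClones(rec, level = "allele")), 2)
  expect_equal(nrow(clusterClones(rec, level = "gene")), 1)
})

test_that("the bundled cohort carries one heavy common clone spanning 7 patients", {
  cl <- clusterClones(fix)
  cc <- findCommonClones(cl, min_patients = 2)
  heavy <- cc[cc$locus == "IGH", ]
  # two heavy clones recur across patients; sorted by patient span, the
  # convergent one comes first
  expect_equal(nrow(heavy), 2)
  top <- heavy[1, ]
  expect_equal(top$n_patients, 7)
  expect_equal(strsplit(top$patients, ",")[[1]],
               sort(c("PA8", "PA21", "PA22", "PA23", "PA25", "PA29", "PA30")))
  expect_equal(top$cdr3_aa, "ARVGSKYGFETFDI")
  # occurrence matrix row: PA22 contributed three cells to this clone
  expect_equal(top$PA22, 3L)
  expect_equal(sum(top[, grep("^PA", names(top))] > 0), 7)
})

test_that("all-unique junctions give no common clones", {
  rec <- random_records(10, 54)
  rec$junction_aa <- sprintf("CARX%02dW", 1:10)
  cc <- findCommonClones(clusterClones(rec))
  expect_equal(nrow(cc), 0)
})

test_that("a clone planted across k patients is detected in exactly those k", {
  junction <- revTranslate("CARVGSKYGFETFDIW")
  pc <- list(id = "shared1", patients = c("P02", "P05", "P07", "P09", "P11"),
             heavy = list(v = "IGHV1-18*04", j = "IGHJ3*02",
                          junction = junction),
             light = list(v = "IGLV1-44*01", j = "IGLJ3*02",
                          junction = revTranslate("CAAWDDSLNGPVF")))
  cfg <- simulationConfig(n_patients = 12, cells_per_patient = 4,
                          shm_rate = 0, trim_max = 4, n_insert_max = 6,
                          incomplete_fraction = 0,
                          planted_clones = list(pc), seed = 55)
  sim <- simulateCohort(cfg, toy_db)
  rec <- annotateVdj(sim$sequences, toy_db,
                     patient_id = sim$truth$patient_id,
                     cell_id = sim$truth$cell_id, verbose = FALSE)
  cc <- findCommonClones(clusterClones(rec), min_patients = 2)
  heavy <- cc[cc$locus == "IGH", ]
  expect_equal(nrow(heavy), 1)
  expect_equal(strsplit(heavy$patients, ",")[[1]], pc$patients)
})

test_that("shared clonotypes: worked example, light-chain split, invariance", {
  ct <- findSharedClonotypes(fix_cells)
  expect_equal(nrow(ct), 4)
  expect_equal(sum(ct$heavy_cdr3 == "ARVGSKYGFETFDI"), 3)
  # same heavy, different light CDR3 -> distinct clonotypes
  lights <- ct$light_cdr3[ct$heavy_cdr3 == "ARVGSKYGFETFDI"]
  expect_setequal(lights, c("AAWDDSLNGPV", "QSYDRSLSGYWV", "AAWDDSLTGVV"))
  # invariant under permutation of the input record order
  perm <- fix[rev(seq_len(nrow(fix))), ]
  ct2 <- findSharedClonotypes(assembleCells(perm))
  expect_equal(ct2[order(ct2$clonotype_id), -1], ct[order(ct$clonotype_id), -1],
               ignore_attr = TRUE)
})

test_that("a cell with two lights joins through either pairing but is counted once", {
  rec <- data.frame(
    sequence_id = c("h1", "l1", "l2", "h2", "l3"),
    patient_id = c(rep("PA1", 3), rep("PA2", 2)),
    cell_id = c(rep("PA1_c1", 3), rep("PA2_c1", 2)),
    locus = c("IGH", "IGL", "IGL", "IGH", "IGL"),
    v_call = c("IGHV1-18*04", "IGLV1-44*01", "IGLV2-11*01",
               "IGHV1-18*04", "IGLV1-44*01"),
    d_call = "",
    j_call = c("IGHJ3*02", "IGLJ3*02", "IGLJ3*02", "IGHJ3*02", "IGLJ3*02"),
    junction = "", junction_aa = c("CARVGSKYGFETFDIW", "CAAWDDSLNGPVF",
                                   "CSSYVRAWVF", "CARVGSKYGFETFDIW",
                                   "CAAWDDSLNGPVF"),
    productive = TRUE, stringsAsFactors = FALSE)
  rec$cdr3_aa <- junctionToCdr3(rec$junction_aa)
  ct <- findSharedClonotypes(assembleCells(rec))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_cells, 2)
  expect_equal(ct$n_patients, 2)
})

test_that("CDR3 search finds exact and Hamming-1 hits, verified exhaustively", {
  pool <- c(x1 = "ARVGSKYGFETFDI", x2 = "ARVGSKYGFETFDV",
            x3 = "ARVGSKYGFEAFDV", x4 = "SHORTCDR", x5 = "ARVGSKYGFETFDI")
  expect_equal(nrow(searchCdr3("ARVGSKYGFETFDI", c(y = "TOTALLYELSE"))), 0)
  hits0 <- searchCdr3("ARVGSKYGFETFDI", pool)
  expect_setequal(hits0$id, c("x1", "x5"))
  # MiXCR-style anchored target normalises to the same thing
  expect_equal(searchCdr3("CARVGSKYGFETFDIW", pool)$id, hits0$id)
  hits1 <- searchCdr3("ARVGSKYGFETFDI", pool, max_mismatch = 1)
  target <- "ARVGSKYGFETFDI"
  brute <- names(pool)[vapply(pool, function(s) {
    nchar(s) == nchar(target) &&
      sum(strsplit(s, "")[[1]] != strsplit(target, "")[[1]]) <= 1
  }, logical(1))]
  expect_setequal(hits1$id, brute)
  expect_false("x3" %in% hits1$id)  # distance 2
  expect_error(searchCdr3("AR", pool, max_mismatch = -1), ">= 0")
})

test_that("overlap counts follow set algebra and refuse mixed levels", {
  a <- data.frame(v_call = sprintf("IGHV1-%d*01", 1:44),
                  j_call = "IGHJ3*02", cdr3_aa = sprintf("AR%02d", 1:44),
                  stringsAsFactors = FALSE)
  b <- data.frame(v_call = sprintf("IGHV2-%d*01", 1:10),
                  j_call = "IGHJ4*02", cdr3_aa = sprintf("XX%02d", 1:10),
                  stringsAsFactors = FALSE)
  ov <- overlapCounts(cloneKeys(a), cloneKeys(b))
  expect_equal(ov[c("a_only", "b_only", "shared")],
               list(a_only = 44L, b_only = 10L, shared = 0L))
  ov2 <- overlapCounts(cloneKeys(a), cloneKeys(a))
  expect_equal(ov2[c("a_only", "b_only", "shared")],
               list(a_only = 0L, b_only = 0L, shared = 44L))
  set.seed(56)
  ka <- cloneKeys(a[sample(44, 20), ])
  kb <- cloneKeys(a[sample(44, 20), ])
  ov3 <- overlapCounts(ka, kb)
  expect_equal(ov3$shared, length(intersect(ka, kb)))
  expect_equal(ov3$a_only + ov3$shared, length(unique(ka)))
  expect_equal(ov3$b_only + ov3$shared, length(unique(kb)))
  expect_error(overlapCounts(cloneKeys(a, "allele"), cloneKeys(b, "gene")),
               "mixed key levels")
})
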