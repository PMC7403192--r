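# Independent oracles and small generators used across the suite.

toy_db <- syntheticGermline()

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap Smith-Waterman, written independently of the
# package's alignment path. A gap of length L costs open + L * extend.
oracle_local_align <- function(a, b, match = 2, mismatch = -2,
                               open = 5, extend = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      sub <- if (ac[i - 1] == bc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force clone partition: pairwise matching rule plus transitive
# closure, independent of the package's union-find path.
oracle_clone_partition <- function(records, level = "allele") {
  rec <- records[records$productive & nzchar(records$junction_aa), ,
                 drop = FALSE]
  n <- nrow(rec)
  if (n == 0) return(list())
  sets <- function(x) {
    lapply(strsplit(x, ","), function(v) {
      v <- v[nzchar(v)]
      if (!length(v)) character() else unique(collapseAllele(v, level))
    })
  }
  vs <- sets(rec$v_call)
  js <- sets(rec$j_call)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      match_ij <- rec$locus[i] == rec$locus[j] &&
        rec$junction_aa[i] == rec$junction_aa[j] &&
        length(intersect(vs[[i]], vs[[j]])) > 0 &&
        length(intersect(js[[i]], js[[j]])) > 0
      if (match_ij && lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(rec$sequence_id, lab), function(x) sort(x)))
}

canonical_partition <- function(groups) {
  groups <- unname(lapply(groups, sort))
  groups[order(vapply(groups, `[`, "", 1))]
}

# random chain records over a tiny key space, to provoke clone collisions
random_records <- function(n, seed) {
  set.seed(seed)
  v <- c("IGHV1-18*04", "IGHV1-18*04,IGHV1-69*01", "IGHV1-69*01",
         "IGHV3-23*01")
  j <- c("IGHJ3*02", "IGHJ3*02,IGHJ4*02", "IGHJ4*02")
  jx <- c("CARAAAW", "CARAATW", "CARCCCW")
  data.frame(sequence_id = sprintf("r%03d", seq_len(n)),
             patient_id = sample(sprintf("PA%d", 1:4), n, replace = TRUE),
             locus = "IGH",
             v_call = sample(v, n, replace = TRUE),
             d_call = "",
             j_call = sample(j, n, replace = TRUE),
             junction_aa = sample(jx, n, replace = TRUE),
             productive = TRUE, stringsAsFactors = FALSE)
}
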