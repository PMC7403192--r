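## Repertoire statistics: usage preference, V-J combinations, CDR3 length
## distributions with normality testing, mutation-rate summaries, and the
## normality-gated two-group comparison rule.

.callColumn <- function(segment_type) {
  switch(segment_type, V = "v_call", D = "d_call", J = "j_call",
         stop("segment_type must be V, D or J"))
}

#' Segment usage table
#'
#' Counts segment usage at family, gene or allele level. Records with tied
#' multi-calls contribute fractionally (1 / number of tied calls), so each
#' record carries total weight 1; records without a call of the requested
#' type (e.g. light chains have no D) contribute nothing.
#'
#' @param records data.frame of annotated chain records.
#' @param segment_type `"V"`, `"D"` or `"J"`.
#' @param level `"family"`, `"gene"` or `"allele"`.
#' @param locus optional locus filter applied first.
#' @param zero_fill optional [GermlineDb-class]; labels present in the
#'   germline but absent from the records are listed with count 0, which
#'   makes unused families visible.
#' @return data.frame with columns `label`, `count`, `frequency`
#'   (frequencies sum to 1 over non-zero-filled entries).
#' @export
geneUsage <- function(records, segment_type = c("V", "D", "J"),
                      level = c("family", "gene", "allele"),
                      locus = NULL, zero_fill = NULL) {
  segment_type <- match.arg(segment_type)
  level <- match.arg(level)
  if (!is.null(locus)) records <- records[records$locus %in% locus, , drop = FALSE]
  if (nrow(records) == 0) stop("no records to tabulate")
  calls <- splitCalls(records[[.callColumn(segment_type)]])
  w <- numeric(); lab <- character()
  for (cs in calls) {
    if (!length(cs)) next
    lab <- c(lab, collapseAllele(cs, level))
    w <- c(w, rep(1 / length(cs), length(cs)))
  }
  if (!length(lab)) stop("no ", segment_type, " calls in the records")
  counts <- tapply(w, lab, sum)
  out <- data.frame(label = names(counts), count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / sum(out$count)
  if (!is.null(zero_fill)) {
    a <- anchorInfo(zero_fill)
    keep <- a$segment_type == segment_type
    if (!is.null(locus)) keep <- keep & a$locus %in% locus
    all_lab <- unique(collapseAllele(a$allele_id[keep], level))
    miss <- setdiff(all_lab, out$label)
    if (length(miss))
      out <- rbind(out, data.frame(label = miss, count = 0, frequency = 0,
                                   stringsAsFactors = FALSE))
  }
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' V-J combination matrix
#'
#' The V-by-J count matrix underlying the three-dimensional combination
#' plots. Tied multi-calls contribute fractionally (1 / (|V ties| * |J
#' ties|) per combination), so row sums equal the V usage counts and
#' column sums the J usage counts of the same records at the same level.
#'
#' @param records data.frame of annotated chain records (filter to one
#'   locus first for a per-locus matrix).
#' @param level `"allele"`, `"gene"` or `"family"`.
#' @param top_k how many top combinations to report in
#'   `attr(, "top_combinations")`.
#' @return numeric matrix (rows: V labels, columns: J labels).
#' @export
vjMatrix <- function(records, level = c("allele", "gene", "family"),
                     top_k = 5) {
  level <- match.arg(level)
  v_sets <- .callSetsAtLevel(records$v_call, level)
  j_sets <- .callSetsAtLevel(records$j_call, level)
  has <- lengths(v_sets) > 0 & lengths(j_sets) > 0
  vlab <- sort(unique(unlist(v_sets[has])))
  jlab <- sort(unique(unlist(j_sets[has])))
  m <- matrix(0, length(vlab), length(jlab), dimnames = list(vlab, jlab))
  for (i in which(has)) {
    w <- 1 / (length(v_sets[[i]]) * length(j_sets[[i]]))
    for (v in v_sets[[i]]) for (j in j_sets[[i]]) m[v, j] <- m[v, j] + w
  }
  nz <- which(m > 0, arr.ind = TRUE)
  top <- data.frame(v = vlab[nz[, 1]], j = jlab[nz[, 2]],
                    count = m[nz], stringsAsFactors = FALSE)
  top <- head(top[order(-top$count, top$v, top$j), , drop = FALSE], top_k)
  rownames(top) <- NULL
  attr(m, "top_combinations") <- top
  attr(m, "level") <- level
  m
}

#' CDR3 amino-acid length distribution
#'
#' Integer histogram of CDR3 lengths (anchors already stripped), all modal
#' lengths, and a Shapiro-Wilk normality test on the per-record length
#' vector. The test is reported as undefined (`NA` with a note) when fewer
#' than 3 records carry a CDR3 or the lengths have zero variance.
#'
#' @param records data.frame with a `cdr3_aa` column, or an integer vector
#'   of lengths.
#' @return list with `histogram` (data.frame `length`, `count`), `modes`,
#'   `n`, `shapiro_w`, `shapiro_p`, and `note` when the test is undefined.
#' @export
cdr3LengthDistribution <- function(records) {
  lens <- if (is.data.frame(records)) {
    cdr3 <- records$cdr3_aa
    nchar(cdr3[!is.na(cdr3) & nzchar(cdr3)])
  } else {
    as.numeric(records)
  }
  tab <- table(lens)
  hist <- data.frame(length = as.numeric(names(tab)), count = as.integer(tab))
  modes <- hist$length[hist$count == max(hist$count)]
  note <- NULL
  w <- p <- NA_real_
  if (length(lens) >= 3 && stats::var(lens) > 0) {
    sw <- shapiro.test(lens)
    w <- unname(sw$statistic); p <- sw$p.value
  } else {
    note <- "normality test undefined (n < 3 or zero variance)"
  }
  list(histogram = hist, modes = if (length(lens)) modes else integer(),
       n = length(lens), shapiro_w = w, shapiro_p = p, note = note)
}

#' Per-record mutation rates and the box-plot five-number summary
#'
#' Rate = `v_mutation_count / v_germline_aligned_length` per record;
#' records with zero or missing aligned length are excluded with a
#' message. The summary is the minimum, first quartile, median, third
#' quartile and maximum displayed by the usual box-and-whisker plots.
#'
#' @param records data.frame with `v_mutation_count` and
#'   `v_germline_aligned_length` columns.
#' @return list with `rates` (data.frame `sequence_id`, `rate`),
#'   `summary` (named five-number vector), `mean`, `n`, `n_excluded`.
#' @export
mutationRateSummary <- function(records) {
  ok <- !is.na(records$v_germline_aligned_length) &
    records$v_germline_aligned_length > 0
  if (any(!ok))
    message(sum(!ok), " record(s) excluded (zero aligned germline length)")
  r <- records[ok, , drop = FALSE]
  rate <- r$v_mutation_count / r$v_germline_aligned_length
  fn <- if (length(rate)) fivenum(rate) else rep(NA_real_, 5)
  list(rates = data.frame(sequence_id = r$sequence_id, rate = rate,
                          stringsAsFactors = FALSE),
       summary = setNames(fn, c("min", "q1", "median", "q3", "max")),
       mean = if (length(rate)) mean(rate) else NA_real_,
       n = length(rate), n_excluded = sum(!ok))
}

.groupNormalP <- function(x) {
  if (length(x) < 3 || length(x) > 5000 || stats::var(x) == 0)
    return(NA_real_)
  shapiro.test(x)$p.value
}

#' Compare continuous values between groups
#'
#' Implements the normality-gated test selection used for repertoire
#' comparisons: Shapiro-Wilk per group at alpha = 0.05; for two groups a
#' two-sample Student's t test when both groups are compatible with
#' normality, otherwise the Wilcoxon rank-sum test; for three or more
#' groups one-way ANOVA (all normal) or Kruskal-Wallis. Groups whose
#' normality test is undefined (n < 3 in-test or zero variance) are
#' treated as non-normal. All p values are two-tailed; when every value in
#' every group is identical the comparison is degenerate and reported with
#' statistic 0 and p = 1 by convention.
#'
#' @param ... two or more numeric vectors (or a single list of them),
#'   each of length >= 3.
#' @param alpha significance level for both the normality gate and the
#'   reported decision (default 0.05).
#' @return list with `group_n`, `means`, `medians`, `normality_p`,
#'   `test` (`"t"`, `"wilcoxon"`, `"anova"` or `"kruskal"`), `statistic`,
#'   `p_value`, `alpha`, `significant`.
#' @export
compareGroups <- function(..., alpha = 0.05) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 3)) stop("each group needs n >= 3")
  norm_p <- vapply(groups, .groupNormalP, 0)
  all_normal <- all(!is.na(norm_p) & norm_p > alpha)
  pooled <- unlist(groups)
  res <- list(group_n = lengths(groups),
              means = vapply(groups, mean, 0),
              medians = vapply(groups, median, 0),
              normality_p = norm_p, alpha = alpha)
  if (all(pooled == pooled[1])) {
    res$test <- if (length(groups) == 2) {
      if (all_normal) "t" else "wilcoxon"
    } else {
      if (all_normal) "anova" else "kruskal"
    }
    res$statistic <- 0
    res$p_value <- 1
  } else if (length(groups) == 2) {
    if (all_normal) {
      tt <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      res$test <- "t"
      res$statistic <- unname(tt$statistic)
      res$p_value <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                         exact = FALSE, correct = TRUE))
      res$test <- "wilcoxon"
      res$statistic <- unname(wt$statistic)
      res$p_value <- wt$p.value
    }
  } else {
    values <- unlist(groups)
    fac <- factor(rep(seq_along(groups), lengths(groups)))
    if (all_normal) {
      fit <- summary(aov(values ~ fac))[[1]]
      res$test <- "anova"
      res$statistic <- fit[["F value"]][1]
      res$p_value <- fit[["Pr(>F)"]][1]
    } else {
      kt <- kruskal.test(values, fac)
      res$test <- "kruskal"
      res$statistic <- unname(kt$statistic)
      res$p_value <- kt$p.value
    }
  }
  res$significant <- res$p_value < alpha
  res
}

#' Kappa/lambda light-chain class counts
#'
#' Counts light-chain records by locus and tests the lambda fraction
#' against 0.5 with a two-sided exact binomial test.
#'
#' @param records data.frame of chain records; only loci IGK and IGL are
#'   counted (an error if there are none).
#' @return list with `kappa`, `lambda`, `ratio` (lambda / kappa),
#'   `lambda_fraction`, `p_value`.
#' @export
lightChainClassCounts <- function(records) {
  lr <- records[records$locus %in% c("IGK", "IGL"), , drop = FALSE]
  if (nrow(lr) == 0) stop("no light-chain records")
  k <- sum(lr$locus == "IGK"); l <- sum(lr$locus == "IGL")
  bt <- binom.test(l, k + l, p = 0.5, alternative = "two.sided")
  list(kappa = k, lambda = l, ratio = l / k, lambda_fraction = l / (k + l),
       p_value = bt$p.value)
}
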