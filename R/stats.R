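#' Per-group blebbing contingency table
#'
#' Tallies blebbing and non-blebbing cells per experimental group,
#' preserving the group order of a factor `group` column (or first
#' appearance order for character input). Excluded cells should be
#' removed before tabulation.
#'
#' @param records data frame with `group` and logical `blebbing` columns.
#' @return data frame of class `blebbing_table` with columns `group`,
#'   `blebbing`, `non_blebbing`, `n`, `frequency`.
#' @export
blebbing_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("group", "blebbing") %in% names(records)))
  g <- records$group
  levels <- if (is.factor(g)) levels(g) else unique(as.character(g))
  g <- factor(as.character(g), levels = levels)
  empty <- levels[!levels %in% as.character(g)]
  if (length(empty))
    stop(sprintf("group '%s' has no cells", empty[1]))
  bl <- tapply(records$blebbing, g, sum)
  n <- tapply(records$blebbing, g, length)
  out <- data.frame(group = levels, blebbing = as.integer(bl),
                    non_blebbing = as.integer(n - bl), n = as.integer(n),
                    frequency = as.numeric(bl / n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("blebbing_table", "data.frame")
  out
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Point-probability ("minlike") convention: at fixed margins, the sum of
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed the observed one (ties included up to a 1e-12 relative
#' tolerance).
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_p <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 2), all(m >= 0), all(m == round(m)))
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
  x <- lo:hi
  p <- stats::dhyper(x, r1, N - r1, c1)
  p_obs <- stats::dhyper(a, r1, N - r1, c1)
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Pairwise Fisher's exact tests with FDR adjustment
#'
#' For every unordered pair of groups, the two-sided Fisher's exact test
#' on the 2x2 sub-table of (blebbing, non-blebbing) counts. Two-sided
#' p-values follow the point-probability convention: the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' likely than the observed one. P-values are adjusted across all pairs
#' by the Benjamini-Hochberg step-up procedure.
#'
#' @param table a [blebbing_table()] (or any data frame with `group`,
#'   `blebbing`, `non_blebbing`).
#' @return list with `results` (one row per pair: `group_a`, `group_b`,
#'   `odds_ratio`, `p_raw`, `p_adjusted`, `method`), and symmetric
#'   matrices `p_raw_matrix` and `p_adjusted_matrix` with unit diagonal.
#' @export
fisher_pairwise_fdr <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "blebbing", "non_blebbing") %in% names(table)))
  k <- nrow(table)
  if (k < 2) stop("need at least 2 groups")
  pairs <- utils::combn(k, 2)
  res <- data.frame(group_a = character(0), group_b = character(0),
                    odds_ratio = numeric(0), p_raw = numeric(0),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    m <- rbind(c(table$blebbing[i1], table$non_blebbing[i1]),
               c(table$blebbing[i2], table$non_blebbing[i2]))
    if (sum(m[1, ]) == 0 || sum(m[2, ]) == 0)
      stop(sprintf("pair (%s, %s) has a group with zero total",
                   table$group[i1], table$group[i2]))
    or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    res <- rbind(res, data.frame(group_a = as.character(table$group[i1]),
                                 group_b = as.character(table$group[i2]),
                                 odds_ratio = or,
                                 p_raw = fisher_exact_p(m),
                                 stringsAsFactors = FALSE))
  }
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res$method <- "fisher_fdr"
  g <- as.character(table$group)
  praw <- padj <- matrix(1, k, k, dimnames = list(g, g))
  for (j in seq_len(nrow(res))) {
    a <- res$group_a[j]; b <- res$group_b[j]
    praw[a, b] <- praw[b, a] <- res$p_raw[j]
    padj[a, b] <- padj[b, a] <- res$p_adjusted[j]
  }
  list(results = res, p_raw_matrix = praw, p_adjusted_matrix = padj)
}

#' Two-way group comparison of focal-adhesion counts
#'
#' Per-cell focal-adhesion counts (after cutoffs) are log10-transformed
#' to bring their distribution closer to Gaussian, then analysed by
#' two-way fixed-effects ANOVA with interaction and Tukey's HSD across
#' the four factor-combination groups. A distribution-free alternative
#' (pairwise Mann-Whitney U tests with Benjamini-Hochberg adjustment) is
#' emitted alongside.
#'
#' When the response has (numerically) zero variance the comparisons are
#' reported as a no-variance condition with p = 1 rather than an error.
#'
#' @param records data frame with `fa_count` (all >= 1; log-defined) and
#'   two factor columns named by `factors`.
#' @param factors length-2 character vector naming the two design factors.
#' @return list with `anova` (the two-way ANOVA table as a data frame),
#'   `tukey` (data frame of pairwise group contrasts, method
#'   `anova_tukey`), `rank` (pairwise Mann-Whitney + BH, method
#'   `rank_mw_fdr`), and `no_variance` flag.
#' @export
fa_group_test <- function(records, factors = c("genotype", "treatment")) {
  stopifnot(is.data.frame(records), "fa_count" %in% names(records),
            length(factors) == 2, all(factors %in% names(records)))
  if (any(records$fa_count < 1))
    stop("fa_count must be >= 1 after cutoffs (log-defined)")
  f1 <- factor(records[[factors[1]]])
  f2 <- factor(records[[factors[2]]])
  combos <- table(f1, f2)
  if (any(combos == 0)) stop("empty design cell in the two-way layout")
  y <- log10(records$fa_count)
  grp <- interaction(f1, f2, sep = ":", lex.order = TRUE)

  pair_idx <- utils::combn(levels(grp), 2)
  if (stats::var(y) < 1e-24) {
    tukey <- data.frame(group_a = pair_idx[1, ], group_b = pair_idx[2, ],
                        diff = 0, p_adjusted = 1, method = "anova_tukey",
                        stringsAsFactors = FALSE)
    rank <- data.frame(group_a = pair_idx[1, ], group_b = pair_idx[2, ],
                       p_raw = 1, p_adjusted = 1, method = "rank_mw_fdr",
                       stringsAsFactors = FALSE)
    return(list(anova = NULL, tukey = tukey, rank = rank, no_variance = TRUE))
  }

  dat <- data.frame(y = y, A = f1, B = f2, grp = grp)
  fit <- stats::aov(y ~ A * B, data = dat)
  an <- as.data.frame(summary(fit)[[1]])
  an$term <- trimws(rownames(an))
  names(an) <- c("df", "sum_sq", "mean_sq", "F", "p", "term")
  rownames(an) <- NULL

  fit_g <- stats::aov(y ~ grp, data = dat)
  tk <- stats::TukeyHSD(fit_g)$grp
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group_a = vapply(cmp, `[`, "", 1),
                      group_b = vapply(cmp, `[`, "", 2),
                      diff = unname(tk[, "diff"]),
                      p_adjusted = unname(tk[, "p adj"]),
                      method = "anova_tukey", stringsAsFactors = FALSE)
  rownames(tukey) <- NULL

  p_mw <- apply(pair_idx, 2, function(pp) {
    a <- y[grp == pp[1]]; b <- y[grp == pp[2]]
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  })
  rank <- data.frame(group_a = pair_idx[1, ], group_b = pair_idx[2, ],
                     p_raw = p_mw,
                     p_adjusted = stats::p.adjust(p_mw, method = "BH"),
                     method = "rank_mw_fdr", stringsAsFactors = FALSE)
  list(anova = an, tukey = tukey, rank = rank, no_variance = FALSE)
}

#' Cells aggregated into one spreading data point
#'
#' The spreading assay samples a fixed number of the most-spread cells
#' per field, across randomly selected fields per plate and plates per
#' time point; one data point aggregates their product (8 x 3 x 3 = 72
#' cells under the default protocol).
#'
#' @param cells_per_field,fields_per_plate,plates_per_point positive counts.
#' @return integer count of cells per data point.
#' @export
spreading_sample_size <- function(cells_per_field, fields_per_plate,
                                  plates_per_point) {
  stopifnot(cells_per_field >= 1, fields_per_plate >= 1, plates_per_point >= 1)
  as.integer(cells_per_field) * as.integer(fields_per_plate) *
    as.integer(plates_per_point)
}
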