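#' Wilcoxon signed-rank test at an arbitrary location shift
#'
#' Signed-rank test of the symmetry point of paired differences against a
#' hypothesized location \code{shift}: differences equal to the shift are
#' dropped (standard signed-rank convention), absolute differences are
#' mid-ranked in the presence of ties, and the statistic is the positive
#' rank sum V. For n <= 25 the exact permutation distribution of V is used,
#' computed by dynamic programming over the (possibly tied) mid-ranks — with
#' distinct ranks this reduces to the classical signed-rank distribution;
#' beyond that, a tie-corrected normal approximation with continuity
#' correction (the conventions of \code{stats::wilcox.test}).
#'
#' @param diffs numeric vector of paired differences.
#' @param shift hypothesized location (default 0).
#' @return list with \code{statistic} (V), \code{n} (pairs retained),
#'   \code{p_greater}, \code{p_less}, \code{p_two_sided}, \code{exact}.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.1, -0.3, 0.7, 2.0, -0.2, 0.9, 1.4, 0.5))
wilcoxon_signed_rank <- function(diffs, shift = 0) {
  d <- diffs[!is.na(diffs)] - shift
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("wilcoxon_signed_rank: degenerate sample (all differences equal ",
         "the hypothesized shift)")
  }
  if (n < 5) {
    stop("wilcoxon_signed_rank: need at least 5 nonzero differences, got ", n)
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  exact <- n <= 25
  if (exact) {
    # exact sign-flip permutation distribution of 2V (integer-valued even
    # with mid-ranks), by convolution of (1 + z^(2 r_i))/2
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[seq_len(tot + 1 - ri)]
      f <- g / 2
    }
    V2 <- as.integer(round(2 * V))
    p_greater <- sum(f[(V2 + 1):(tot + 1)])
    p_less <- sum(f[seq_len(V2 + 1)])
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (s2 <= 0) {
      stop("wilcoxon_signed_rank: degenerate sample (zero variance of ranks)")
    }
    sd_v <- sqrt(s2)
    p_greater <- pnorm((V - mu - 0.5) / sd_v, lower.tail = FALSE)
    p_less <- pnorm((V - mu + 0.5) / sd_v)
  }
  list(statistic = V, n = n, p_greater = p_greater, p_less = p_less,
       p_two_sided = min(1, 2 * min(p_greater, p_less)), exact = exact)
}

# Hodges-Lehmann estimate and (1 - 2*alpha) confidence interval from Walsh
# averages, mirroring the wilcox.test conf.int conventions.
hl_interval <- function(d, alpha) {
  n <- length(d)
  w <- outer(d, d, "+")[lower.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  m <- length(w)
  k <- if (n <= 25 && anyDuplicated(abs(d)) == 0) {
    qsignrank(alpha, n)
  } else {
    round(n * (n + 1) / 4 - qnorm(alpha, lower.tail = FALSE) *
            sqrt(n * (n + 1) * (2 * n + 1) / 24))
  }
  k <- min(max(k, 1), m)
  list(estimate = median(w), lower = w[k], upper = w[m + 1 - k])
}

#' Wilcoxon TOST equivalence test between two sets of ROI medians
#'
#' Two one-sided Wilcoxon tests against the equivalence bounds, plus a
#' two-sided difference test at shift 0. With \code{paired = TRUE} (the
#' default; left/right and sub-compartment comparisons are within-subject)
#' the signed-rank procedure of [wilcoxon_signed_rank()] is used; with
#' \code{paired = FALSE} the samples are treated as independent and the
#' rank-sum test is used. Equivalence is declared when both one-sided tests
#' reject, i.e. max(p_lower, p_upper) < alpha; a "different" verdict is
#' p_diff < alpha. The two verdicts are not mutually exclusive: a tiny but
#' consistent offset can be both statistically nonzero and within the
#' equivalence bounds.
#'
#' @param a,b numeric vectors of per-subject ROI medians (S/m); equal length
#'   and subject-matched when \code{paired = TRUE}.
#' @param bounds equivalence bounds in S/m, default \code{c(-0.05, 0.05)}.
#' @param alpha level of each one-sided test (default 0.05); the reported
#'   interval is the matching (1 - 2*alpha) confidence interval.
#' @param paired pair observations by position (default TRUE).
#' @return object of class \code{equivalence_result}: \code{n},
#'   \code{median_diff}, \code{estimate} (Hodges-Lehmann), \code{ci_lower},
#'   \code{ci_upper}, \code{p_diff}, \code{p_lower}, \code{p_upper},
#'   \code{equivalent}, \code{different}, \code{bounds}, \code{alpha},
#'   \code{paired}.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(50, 0.45, 0.02)
#' tost_equivalence(a, a + 0.001)$equivalent
tost_equivalence <- function(a, b, bounds = c(-0.05, 0.05), alpha = 0.05,
                             paired = TRUE) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            alpha > 0, alpha < 0.5)
  if (paired && length(a) != length(b)) {
    stop("tost_equivalence: paired samples must have equal length (",
         length(a), " vs ", length(b), ")")
  }
  if (paired) {
    d <- a - b
    p_lower <- wilcoxon_signed_rank(d, shift = bounds[1])$p_greater
    p_upper <- wilcoxon_signed_rank(d, shift = bounds[2])$p_less
    p_diff <- wilcoxon_signed_rank(d, shift = 0)$p_two_sided
    hl <- hl_interval(d[d != 0], alpha)
    median_diff <- median(d)
    n <- length(d)
  } else {
    p_lower <- suppressWarnings(
      wilcox.test(a, b, mu = bounds[1], alternative = "greater"))$p.value
    p_upper <- suppressWarnings(
      wilcox.test(a, b, mu = bounds[2], alternative = "less"))$p.value
    wt <- suppressWarnings(
      wilcox.test(a, b, conf.int = TRUE, conf.level = 1 - 2 * alpha))
    p_diff <- wt$p.value
    hl <- list(estimate = unname(wt$estimate), lower = wt$conf.int[1],
               upper = wt$conf.int[2])
    median_diff <- median(a) - median(b)
    n <- min(length(a), length(b))
  }
  structure(list(
    n = n, median_diff = median_diff, estimate = hl$estimate,
    ci_lower = hl$lower, ci_upper = hl$upper,
    p_diff = p_diff, p_lower = p_lower, p_upper = p_upper,
    equivalent = max(p_lower, p_upper) < alpha,
    different = p_diff < alpha,
    bounds = bounds, alpha = alpha, paired = paired
  ), class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    paste0("<equivalence_result> n=%d, median diff %.4f S/m ",
           "[%.4f, %.4f]\n  TOST p = %.3g (bounds %g..%g): %s; ",
           "difference p = %.3g: %s\n"),
    x$n, x$median_diff, x$ci_lower, x$ci_upper,
    max(x$p_lower, x$p_upper), x$bounds[1], x$bounds[2],
    if (x$equivalent) "equivalent" else "not equivalent",
    x$p_diff, if (x$different) "different" else "not different"))
  invisible(x)
}

#' Default comparison roster
#'
#' The paired comparisons analyzed by the study design: body vs genu and
#' body vs splenium of the corpus callosum, inferior vs superior cerebellar
#' peduncle, left vs right cingulum, the five bilateral subcortical pairs
#' (amygdala, pallidum, putamen, thalamus, and the hippocampal CA1, CA2-3,
#' CA4-DG subfields), anterior vs posterior cingulate, and pre vs
#' postcentral cortex.
#'
#' @return data.frame with columns \code{roi_a}, \code{roi_b}.
#' @export
default_roster <- function() {
  pairs <- rbind(
    c("cc_body", "cc_genu"),
    c("cc_body", "cc_splenium"),
    c("cerebellar_peduncle_inferior", "cerebellar_peduncle_superior"),
    c("cingulum_left", "cingulum_right"),
    c("amygdala_left", "amygdala_right"),
    c("hippocampus_ca1_left", "hippocampus_ca1_right"),
    c("hippocampus_ca23_left", "hippocampus_ca23_right"),
    c("hippocampus_ca4dg_left", "hippocampus_ca4dg_right"),
    c("pallidum_left", "pallidum_right"),
    c("putamen_left", "putamen_right"),
    c("thalamus_left", "thalamus_right"),
    c("cingulate_anterior", "cingulate_posterior"),
    c("precentral", "postcentral")
  )
  data.frame(roi_a = pairs[, 1], roi_b = pairs[, 2], stringsAsFactors = FALSE)
}

#' Run the equivalence roster over a cohort table
#'
#' For every model present in the table and every ROI pair of the roster,
#' pairs the per-subject medians of the two ROIs and runs
#' [tost_equivalence()].
#'
#' @param table a \code{cohort_table} (see [cohort_table()]).
#' @param roster data.frame with columns \code{roi_a}, \code{roi_b}
#'   (default [default_roster()]). An empty roster yields an empty result.
#' @param bounds,alpha,paired passed to [tost_equivalence()].
#' @return data.frame with one row per (model, pair): verdicts, p-values,
#'   median difference and confidence interval.
#' @export
run_comparison_roster <- function(table, roster = default_roster(),
                                  bounds = c(-0.05, 0.05), alpha = 0.05,
                                  paired = TRUE) {
  empty <- data.frame(model = character(), roi_a = character(),
                      roi_b = character(), n = integer(),
                      median_diff = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), p_diff = numeric(),
                      p_lower = numeric(), p_upper = numeric(),
                      equivalent = logical(), different = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(roster) == 0) return(empty)
  missing <- setdiff(unique(c(roster$roi_a, roster$roi_b)),
                     unique(table$roi_name))
  if (length(missing) > 0) {
    stop("run_comparison_roster: ROI(s) absent from the table: ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  for (model in unique(table$model)) {
    mt <- table[table$model == model, ]
    for (i in seq_len(nrow(roster))) {
      ta <- mt[mt$roi_name == roster$roi_a[i], ]
      tb <- mt[mt$roi_name == roster$roi_b[i], ]
      common <- intersect(ta$subject, tb$subject)
      a <- ta$median[match(common, ta$subject)]
      b <- tb$median[match(common, tb$subject)]
      res <- tost_equivalence(a, b, bounds = bounds, alpha = alpha,
                              paired = paired)
      rows[[length(rows) + 1]] <- data.frame(
        model = model, roi_a = roster$roi_a[i], roi_b = roster$roi_b[i],
        n = res$n, median_diff = res$median_diff,
        ci_lower = res$ci_lower, ci_upper = res$ci_upper,
        p_diff = res$p_diff, p_lower = res$p_lower, p_upper = res$p_upper,
        equivalent = res$equivalent, different = res$different,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
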