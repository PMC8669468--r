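# Differential protein abundance on log2 scales.
#
# The test statistic divides the between-condition difference in mean log2
# abundance by the SUM of the two per-condition total uncertainties (as the
# statistic is defined for this assay -- not a pooled root-sum-of-squares
# across conditions). Each condition's total uncertainty is the root-square
# sum of (i) the SD of the protein's abundance across biological replicates
# and (ii) the mean within-replicate standard error. Z maps to two-sided
# standard-normal p-values and q-values control the false discovery rate.

#' Per-protein Z statistic between two conditions
#'
#' @param means named length-2 numeric: mean log2 abundance per condition
#' @param rep_sds named length-2: SD across biological replicates
#' @param within_ses named length-2: mean within-replicate standard error
#' @return Z = (mean1 - mean2) / (u1 + u2) with
#'   u_c = sqrt(rep_sd_c^2 + within_se_c^2)
#' @export
protein_z <- function(means, rep_sds, within_ses) {
  u <- sqrt(rep_sds^2 + within_ses^2)
  if (sum(u) == 0) stop("undefined Z: zero total uncertainty in both conditions")
  unname((means[1] - means[2]) / (u[1] + u[2]))
}

#' Storey q-values
#'
#' pi0 is estimated on a lambda grid with a smoothing spline (the standard
#' smoother approach), then q(p) = min over p' >= p of pi0 * m * p' / rank.
#'
#' @param p p-values
#' @param lambda tuning grid (default seq(0.05, 0.95, 0.05))
#' @param pi0_method `"smoother"` or `"fixed"` (lambda = 0.5)
#' @return q-values in [0, 1], same order as `p`
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05),
                          pi0_method = c("smoother", "fixed")) {
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (m < 20 || pi0_method == "fixed") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    if (is.na(pi0) || pi0 <= 0) pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Benjamini-Hochberg alternative
#' @param p p-values
#' @return adjusted values
#' @export
bh_qvalue <- function(p) stats::p.adjust(p, method = "BH")

#' Differential protein abundance table
#'
#' @param table long data.frame: `protein`, `condition`, `replicate`,
#'   `log2_abundance`, `within_se`
#' @param cond1,cond2 condition labels; the fold change convention is
#'   cond1 - cond2
#' @param alpha significance level on q (default 0.05)
#' @param min_reps minimum finite replicates per condition for a testable
#'   protein (default 2); below it the protein is demoted to presence/absence
#' @param method multiplicity control, `"storey"` (default) or `"bh"`
#' @return data.frame per protein: log2fc, z, p, q, significant, status in
#'   {both, cond1_only, cond2_only, untestable}
#' @export
differential_proteins <- function(table, cond1, cond2, alpha = 0.05,
                                  min_reps = 2, method = c("storey", "bh")) {
  method <- match.arg(method)
  prots <- unique(table$protein)
  rows <- lapply(prots, function(pr) {
    d <- table[table$protein == pr & is.finite(table$log2_abundance), ]
    d1 <- d[d$condition == cond1, ]; d2 <- d[d$condition == cond2, ]
    n1 <- nrow(d1); n2 <- nrow(d2)
    if (n1 >= min_reps && n2 >= min_reps) {
      z <- protein_z(c(mean(d1$log2_abundance), mean(d2$log2_abundance)),
                     c(stats::sd(d1$log2_abundance), stats::sd(d2$log2_abundance)),
                     c(mean(d1$within_se), mean(d2$within_se)))
      data.frame(protein = pr, status = "both",
                 log2fc = mean(d1$log2_abundance) - mean(d2$log2_abundance),
                 z = z, p = 2 * stats::pnorm(-abs(z)))
    } else if (n1 >= min_reps) {
      data.frame(protein = pr, status = "cond1_only", log2fc = NA_real_,
                 z = NA_real_, p = NA_real_)
    } else if (n2 >= min_reps) {
      data.frame(protein = pr, status = "cond2_only", log2fc = NA_real_,
                 z = NA_real_, p = NA_real_)
    } else {
      data.frame(protein = pr, status = "untestable", log2fc = NA_real_,
                 z = NA_real_, p = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$q <- NA_real_
  if (any(tested))
    out$q[tested] <- if (method == "storey") storey_qvalue(out$p[tested])
                     else bh_qvalue(out$p[tested])
  out$significant <- !is.na(out$q) & out$q <= alpha
  out
}
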