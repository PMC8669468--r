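# Natural-abundance correction for carbon isotopologue data.
#
# Measured isotopologue fractions include the contribution of naturally
# occurring 13C (~1.07%). The forward effect is a binomial convolution over
# the unlabeled carbon positions; correction inverts that matrix, clips small
# negatives and renormalizes. Only the carbon skeleton is corrected (the
# tracer experiments here are 13C-only).

#' Binomial natural-abundance convolution matrix
#'
#' Entry (i, j) is the probability that a molecule with j tracer-labeled
#' carbons is observed at mass M+i, i.e. `dbinom(i - j, n - j, abundance)`.
#'
#' @param carbon_count number of carbons n
#' @param abundance natural 13C abundance (default 0.0107)
#' @return (n+1) x (n+1) lower-triangular-in-j matrix
#' @export
natural_abundance_matrix <- function(carbon_count, abundance = 0.0107) {
  n <- carbon_count
  C <- matrix(0, n + 1, n + 1)
  for (j in 0:n) for (i in j:n)
    C[i + 1, j + 1] <- stats::dbinom(i - j, n - j, abundance)
  C
}

#' Forward-convolve a MID with natural abundance
#'
#' @param mid abundance-free MID (M+0..M+n)
#' @param abundance natural 13C abundance
#' @return observed-scale MID
#' @export
convolve_natural_abundance <- function(mid, abundance = 0.0107) {
  n <- length(mid) - 1
  as.vector(natural_abundance_matrix(n, abundance) %*% mid)
}

#' Correct a measured MID for natural 13C abundance
#'
#' @param raw measured MID (length carbon_count + 1)
#' @param carbon_count number of carbons
#' @param abundance natural 13C abundance (default 0.0107); must be < 0.5 for
#'   a well-conditioned inversion
#' @return corrected MID (clipped at 0 and renormalized)
#' @export
correct_natural_abundance <- function(raw, carbon_count, abundance = 0.0107) {
  if (length(raw) != carbon_count + 1)
    stop("MID length must be carbon_count + 1")
  if (abundance < 0 || abundance >= 0.5)
    stop("abundance must lie in [0, 0.5) for an invertible correction")
  if (abundance == 0) return(raw)
  C <- natural_abundance_matrix(carbon_count, abundance)
  x <- solve(C, raw)
  x[x < 0] <- 0
  s <- sum(x)
  if (s <= 0) stop("correction produced a degenerate (all-zero) MID")
  x / s
}
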