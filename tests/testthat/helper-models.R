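# Shared fixtures: small models and an independent matrix-rank oracle.

# Gaussian-elimination rank, independent of base qr()
rank_oracle <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  r <- 0
  for (col in seq_len(ncol(M))) {
    if (r == nrow(M)) break
    piv <- which.max(abs(M[(r + 1):nrow(M), col])) + r
    if (abs(M[piv, col]) < tol) next
    if (piv != r + 1) M[c(piv, r + 1), ] <- M[c(r + 1, piv), ]
    r <- r + 1
    M[r, ] <- M[r, ] / M[r, col]
    for (i in seq_len(nrow(M))[-r]) M[i, ] <- M[i, ] - M[i, col] * M[r, ]
  }
  r
}

# draw a random feasible flux assignment (net + exchange) for a toy model
random_toy_fluxes <- function(model, fixed = NULL, exch_max = 30) {
  v <- sample_true_fluxes(model, fixed)
  rev_ids <- names(Filter(function(r) r$reversible && !is.null(r$transitions),
                          model$reactions))
  exch <- stats::setNames(stats::runif(length(rev_ids), 0, exch_max), rev_ids)
  list(net = v, exch = exch)
}

toy_tracer_branch <- function()
  tracer_spec("S_ext", list(list(pattern = "111", fraction = 0.5),
                            list(pattern = "000", fraction = 0.5)), purity = 0.99)

# hand-balanced truth for the branch toy: vA = 100 - vB, vP = vE = vB - vC,
# outT = vA + vC
toy_branch_truth <- function(vB = 40, vC = 25) {
  c(upt = 100, vA = 100 - vB, vB = vB, vC = vC,
    vP = vB - vC, vE = vB - vC, outT = (100 - vB) + vC)
}

# noisy branch-toy experiment: T/P/Q MIDs plus a rate measurement on the
# cleavage leak vP (which identifies vB)
toy_branch_experiment <- function(noise_sd = 0.01, seed = 1, vB = 40, vC = 25,
                                  rate_sd = 1.5, replicates = 2) {
  m <- toy_model_branch()
  truth <- toy_branch_truth(vB, vC)
  tr <- list(tb = toy_tracer_branch())
  mids <- make_mid_dataset(m, list(net = truth), tr,
                           targets = c("T", "P", "Q"),
                           replicates = replicates, noise_sd = noise_sd,
                           seed = seed)
  set.seed(seed + 1e6)
  rates <- data.frame(reaction = "vP",
                      value = truth[["vP"]] + stats::rnorm(1, 0, rate_sd),
                      sd = rate_sd, type = "secretion")
  list(model = m, truth = truth, tracers = tr,
       measurements = measurement_set(mids$mids, rates), fixed = c(upt = 100))
}
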