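## Shared fixtures. The default cohort is expensive (30 agents x 144 trials
## with an online belief filter), so it is built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$coh)) {
    .fixtures$coh <- simulate_cohort(30, default_schedule(), seed = 202)
    .fixtures$tab <- derive_measures(.fixtures$coh$trials)
  }
  .fixtures$coh
}

default_cohort_table <- function() {
  default_cohort()
  .fixtures$tab
}

small_participant <- function(seed = 11) {
  key <- paste0("p", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_participant(default_schedule(),
                                             agent_params(), seed = seed)
  .fixtures[[key]]
}

## brute-force dense-grid posterior for the Control-Other context
## (independent of the sequential filter: direct summation over a uniform
## product grid, one pass, no reset machinery)
oracle_control_other <- function(feedback, is_ad, self_level, prior,
                                 n = 200, sig_lo = 1, sig_hi = 18,
                                 sd_floor = 0.5, sigma_self = 5) {
  og <- seq(0, 100, length.out = n)
  cg <- seq(0, 1, length.out = n)
  sg <- seq(sig_lo, sig_hi, length.out = n)
  w_sig <- stats::dnorm(sg, 0, prior$sigma_scale)
  w_o <- stats::dnorm(og, prior$other_mean, prior$other_sd)
  w_c <- stats::dnorm(cg, prior$control_mean, prior$control_sd)
  acc <- matrix(0, n, n)    # (other, control), sigma_other summed out
  for (k in seq_len(n)) {
    L <- outer(og, cg, function(o, cc) {
      l <- rep(1, length(o))
      for (t in seq_along(feedback)) {
        if (is_ad[t]) {
          mu <- o * (1 - cc)
          sd <- pmax(sg[k] * (1 - cc), sd_floor)
        } else {
          mu <- self_level * cc + o * (1 - cc)
          sd <- pmax(sqrt(sigma_self^2 * cc^2 + sg[k]^2 * (1 - cc)^2), sd_floor)
        }
        l <- l * stats::dnorm(feedback[t], mu, sd)
      }
      l
    })
    acc <- acc + (w_o %o% w_c) * L * w_sig[k]
  }
  Z <- sum(acc)
  list(other_mean = sum(rowSums(acc) * og) / Z,
       control_mean = sum(colSums(acc) * cg) / Z)
}
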