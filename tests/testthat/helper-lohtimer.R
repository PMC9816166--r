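# shared fixtures built in code

toy_path <- function(f) system.file("extdata", f, package = "lohtimer")

# a small clonal-only simulation on one gained chromosome
sim_one_segment <- function(major, minor, pi_true, n = 2000,
                            purity = 0.7, depth = 60, seed = 1,
                            subclonal_frac = 0) {
  simulate_tumor(sim_params(
    purity = purity, depth = depth, n_mutations = n,
    subclonal_frac = subclonal_frac,
    segments = data.frame(chrom = "17", start = 0, end = 81195210,
                          major = major, minor = minor,
                          clonal_fraction = 1, pi_true = pi_true,
                          stringsAsFactors = FALSE)),
    seed = seed)
}

# forward lineage simulation: expected pre/post counts from explicit
# copy-time accounting (one ancestral copy contributes rate*time per
# phase), independent of the closed-form estimator algebra
lineage_forward_sim <- function(major, minor, pi_true, lambda = 5e4) {
  state <- paste0(major, "+", minor)
  if (state == "2+0") {
    n2 <- rpois(1, lambda * pi_true)
    n1 <- rpois(1, 2 * lambda * (1 - pi_true))
  } else if (state == "2+1") {
    n2 <- rpois(1, lambda * pi_true)
    n1 <- rpois(1, lambda * pi_true + 3 * lambda * (1 - pi_true))
  } else if (state == "2+2") {
    n2 <- rpois(1, 2 * lambda * pi_true)
    n1 <- rpois(1, 4 * lambda * (1 - pi_true))
  } else stop("unsupported state")
  list(n2 = n2, n1 = n1)
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
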