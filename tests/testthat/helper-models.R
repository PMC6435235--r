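# Baseline vital rates shared by all worked examples: symmetric sexes,
# juvenile mortality 0.5, adult mortality 0.1, maturation 0.5, k = 20.
baseline_model <- function(h = 1, d = 0.1, E = 0, s_h = 0.5, ...) {
  two_sex_model(h = h, mu_m1 = 0.5, mu_f1 = 0.5, mu_m2 = 0.1, mu_f2 = 0.1,
                alpha_m = 0.5, alpha_f = 0.5, d = d, k = 20, s1 = 0.5,
                E = E, s_h = s_h, ...)
}

# A random admissible parameter set (rates positive, ratios in [0, 1]).
random_model <- function(h) {
  two_sex_model(h = h,
                mu_m1 = runif(1, 0, 1), mu_f1 = runif(1, 0, 1),
                mu_m2 = runif(1, 0, 1), mu_f2 = runif(1, 0, 1),
                alpha_m = runif(1, 0, 1), alpha_f = runif(1, 0, 1),
                d = runif(1, 0, 2), k = runif(1, 0, 30),
                s1 = runif(1), E = 0)
}
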