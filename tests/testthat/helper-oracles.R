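# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# population (divide-by-n) sd, written out longhand
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Benjamini-Hochberg step-up, closed form: sort ascending, multiply by n/i,
# enforce monotonicity by a cumulative minimum from the largest p down.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# textbook one-way ANOVA from sums of squares
anova_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       msw = ssw / dfw, dfw = dfw)
}

# random well-conditioned thermal summation parameters + size range
random_params_and_range <- function() {
  k <- runif(1, 50, 5000)
  se <- runif(1, 0.005, 0.1) * k
  m <- sample(2:12, 1)
  l_min <- runif(1, 1, 20)
  l_max <- l_min + runif(1, 0.5, 15)
  list(params = thermal_summation_params(k, se, m),
       range = size_range(l_min, l_max))
}

nl_params <- function() thermal_summation_params(469.89, 24.59, 8, d0 = 8.5)
cm_params <- function() thermal_summation_params(405.156, 14.63, 8, d0 = 11.7)
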