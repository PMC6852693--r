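# Brute-force likelihood oracle: enumerates every latent occupancy sequence
# explicitly, with the observation probabilities written out directly.
# Deliberately independent of the package's forward recursion.
bruteForceSiteLik <- function(codes, season, psi, gamma, epsilon,
                              p10, p11, b) {
  seasons <- sort(unique(season))
  S <- length(seasons)
  obsP <- function(code, z) {
    if (z == 1) {
      switch(code + 1L, 1 - p11, p11 * (1 - b), p11 * b)
    } else {
      switch(code + 1L, 1 - p10, p10, 0)
    }
  }
  total <- 0
  for (k in 0:(2^S - 1)) {
    z <- as.integer(intToBits(k)[1:S])
    pr <- if (z[1] == 1) psi else 1 - psi
    if (S > 1) {
      for (s in 2:S) {
        pr <- pr * if (z[s - 1] == 1) {
          if (z[s] == 1) 1 - epsilon else epsilon
        } else {
          if (z[s] == 1) gamma else 1 - gamma
        }
      }
    }
    for (j in seq_along(codes)) {
      pr <- pr * obsP(codes[j], z[match(season[j], seasons)])
    }
    total <- total + pr
  }
  total
}

randomMillerParams <- function() {
  MillerParams(psi = runif(1, 0.1, 0.9), gamma = runif(1, 0.05, 0.5),
               epsilon = runif(1, 0.05, 0.5), p10 = runif(1, 0.02, 0.3),
               p11 = runif(1, 0.3, 0.9), b = runif(1, 0.05, 0.5))
}

# all code sequences of length n over {0, 1, 2}
allHistories <- function(n) {
  as.matrix(expand.grid(rep(list(0:2), n)))
}
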