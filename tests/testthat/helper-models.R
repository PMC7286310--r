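# Random stable MOU instances and small planted-structure fixtures used
# across the suite. All randomness is locally seeded.

rand_mou <- function(n, density = 0.3, tau = 2, seed = 1, sigma = 1) {
  set.seed(seed)
  C <- matrix(0, n, n)
  off <- which(row(C) != col(C))
  links <- sample(off, round(density * length(off)))
  C[links] <- rlnorm(length(links), meanlog = log(0.5 / (tau * max(1, n * density))),
                     sdlog = 0.5)
  repeat {
    m <- mou(C, sigma = sigma, tau = tau)
    if (is_stable(m) && attr(is_stable(m), "margin") <= -0.1 / tau) return(m)
    C <- C * 0.75
  }
}

# Two 5-region blocks with strong within-block EC and no between-block links.
two_block_mou <- function(w = 0.15, tau = 2, seed = 1, jitter = 0) {
  set.seed(seed)
  n <- 10
  C <- matrix(0, n, n)
  for (b in list(1:5, 6:10))
    for (i in b) for (j in b)
      if (i != j) C[i, j] <- w * (1 + jitter * rnorm(1))
  C[C < 0] <- 0
  repeat {
    m <- mou(C, sigma = 1, tau = tau)
    if (is_stable(m)) return(m)
    C <- C * 0.75
  }
}

# Gaussian feature cohort with planted condition effects on given columns.
synthetic_features <- function(n_subjects = 10, sessions_per = c(rest = 2, task = 3),
                               n_features = 50, informative = integer(0),
                               shift = 0, seed = 1, subject_sd = 0) {
  set.seed(seed)
  subject <- condition <- character(0)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    base <- rnorm(n_features, sd = subject_sd)
    for (cn in names(sessions_per)) for (r in seq_len(sessions_per[[cn]])) {
      x <- rnorm(n_features) + base
      if (cn != "rest" && length(informative) > 0)
        x[informative] <- x[informative] + shift
      rows[[length(rows) + 1]] <- x
      subject <- c(subject, sprintf("sub%02d", s))
      condition <- c(condition, cn)
    }
  }
  cohort_features(do.call(rbind, rows), subject = subject, condition = condition)
}
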