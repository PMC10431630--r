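# Independent brute-force references used as oracles against the optimized
# implementations, plus small fixture builders.

# direct enumeration of consecutive-pair counts
count_transitions_naive <- function(path) {
  counts <- new.env(parent = emptyenv())
  for (t in seq_len(length(path) - 1L)) {
    key <- paste(path[t], path[t + 1L])
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  out <- sapply(ls(counts), function(k) counts[[k]])
  data.frame(
    from = as.integer(vapply(strsplit(names(out), " "), `[`, "", 1L)),
    to = as.integer(vapply(strsplit(names(out), " "), `[`, "", 2L)),
    weight = as.integer(out)
  )
}

# one-edge-at-a-time summation of the mean edge weight (Eq. of Definition 5)
score_naive <- function(graph, path, i, l) {
  total <- 0
  for (k in i:(i + l - 1L)) {
    e <- graph$edges
    w <- e$weight[e$from == path[k + 1L] & e$to == path[k + 2L]]
    total <- total + (if (length(w)) w else 0)
  }
  total / l
}

# centered windowed mean with symmetric boundary shrinkage
moving_avg_naive <- function(s, w) {
  h <- w %/% 2L
  L <- length(s)
  vapply(seq_len(L), function(i) {
    he <- min(h, i - 1L, L - i)
    mean(s[(i - he):(i + he)])
  }, 0)
}

random_walk <- function(n, seed) {
  set.seed(seed)
  cumsum(rnorm(n))
}

# the recurrent-anomaly fixture used across scoring tests
twin_fixture <- function(seed, shape = "inverted", cycles = c(8, 18, 30, 42),
                         length = 110, n_cycles = 50) {
  synth_series(n_cycles, period = 100,
               anomalies = data.frame(cycle = cycles, length = length,
                                      shape = shape),
               noise_sd = 0.02, seed = seed)
}
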