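# Independent oracles and small fixture builders shared across tests.

# Build an epoch_tensor from a list of trials, each a channels x samples
# matrix.
make_epochs <- function(trials, sampling_rate = 1000,
                        labels = paste0("ch", seq_len(nrow(trials[[1]]))),
                        band = "beta", window = c(-3, 0)) {
  n_tr <- length(trials)
  d <- dim(trials[[1]])
  a <- array(0, c(n_tr, d[1], d[2]))
  for (t in seq_len(n_tr)) a[t, , ] <- trials[[t]]
  structure(a, class = "epoch_tensor", window = window,
            sampling_rate = sampling_rate, channel_labels = labels,
            trial_ids = seq_len(n_tr), subject_id = 1L, condition = "test",
            band = band)
}

# Ideal FFT band-pass (independent of the package's FIR path).
fft_bandpass <- function(x, low, high, fs) {
  n <- length(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  X <- stats::fft(x)
  X[f < low | f > high] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Literal term-by-term transcription of the WPLI definition for a single
# channel pair, written with explicit loops over trials and samples.
wpli_pair_oracle <- function(za, zb, average = "pooled") {
  n_tr <- nrow(za)
  if (average == "pooled") {
    num <- 0; den <- 0
    for (t in seq_len(n_tr)) {
      for (s in seq_len(ncol(za))) {
        im <- Im(za[t, s] * Conj(zb[t, s]))
        num <- num + abs(im) * sign(im)
        den <- den + abs(im)
      }
    }
    if (den == 0) return(0)
    return(abs(num / (n_tr * ncol(za))) / (den / (n_tr * ncol(za))))
  }
  vals <- numeric(n_tr)
  for (t in seq_len(n_tr)) {
    num <- 0; den <- 0
    for (s in seq_len(ncol(za))) {
      im <- Im(za[t, s] * Conj(zb[t, s]))
      num <- num + abs(im) * sign(im)
      den <- den + abs(im)
    }
    vals[t] <- if (den == 0) 0 else abs(num) / den
  }
  mean(vals)
}

# Hilbert analytic signal of one series via the textbook FFT recipe.
hilbert_oracle <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::fft(X * h, inverse = TRUE) / n
}

# All-pairs shortest paths by min-plus matrix closure over inverse-weight
# lengths -- independent of Dijkstra.
minplus_distances <- function(w) {
  n <- nrow(w)
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  D <- L
  for (rep in seq_len(n)) {            # n rounds of min-plus closure
    for (i in seq_len(n)) for (j in seq_len(n))
      D[i, j] <- min(D[i, j], min(D[i, ] + L[, j]))
  }
  D
}

# Exhaustive simple-path enumeration (tiny graphs only).
enum_distances <- function(w) {
  n <- nrow(w)
  L <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n); diag(best) <- 0
  paths <- function(from, to, visited, len) {
    if (from == to) { best[visited[1], to] <<- min(best[visited[1], to], len); return(invisible()) }
    for (nxt in seq_len(n)) {
      if (nxt %in% visited) next
      if (!is.finite(L[from, nxt])) next
      paths(nxt, to, c(visited, nxt), len + L[from, nxt])
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    paths(i, j, i, 0)
  best
}

global_efficiency_oracle <- function(w) {
  d <- minplus_distances(w)
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v), 1 / v, 0))
}

local_efficiency_oracle <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2)
      out[i] <- global_efficiency_oracle(w[nb, nb, drop = FALSE])
  }
  out
}

clustering_oracle <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    c_i[i] <- acc / (k * (k - 1))
  }
  c_i
}

eigencentrality_oracle <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

random_weighted_graph <- function(n, density = 1) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  w[up] <- vals
  w + t(w)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n_a + n_b, n_a) group assignments of the pooled ranks.
wilcoxon_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # observed U
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Hand step-up BH adjustment.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# A tiny cohort configuration for fast pipeline tests; any sim_config
# argument can be overridden.
tiny_config <- function(...) {
  args <- list(n_subjects = 2, conditions = c("control", "noise"),
               shots_per_condition = 8, sampling_rate = 200,
               rest_duration = 10, artifact_rate = 0, seed = 11L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
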