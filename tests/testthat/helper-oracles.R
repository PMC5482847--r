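# Independent oracles used to cross-check the package's vectorized /
# optimized implementations. These deliberately use naive formulations.

# scalar-loop PLV (naive accumulation of unit phasors)
plv_loop <- function(phi, psi) {
  s <- 0 + 0i
  for (t in seq_along(phi)) s <- s + exp(1i * (phi[t] - psi[t]))
  Mod(s) / length(phi)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in m:1) adj[i] <- min(if (i < m) adj[i + 1] else 1, ranked[i] * m / i)
  padj <- numeric(m)
  padj[o] <- pmin(adj, 1)
  list(p_fdr = padj, significant = padj < q)
}

# OLS via the normal equations, with overall F test
ols_oracle <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% b
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  k <- ncol(X) - 1L
  n <- length(y)
  Fstat <- ((tss - rss) / k) / (rss / (n - k - 1L))
  list(beta = drop(b), r2 = 1 - rss / tss, F = Fstat,
       p = pf(Fstat, k, n - k - 1L, lower.tail = FALSE))
}

# textbook FFT-domain analytic signal
hilbert_ref <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# dominant fluctuation frequency by smoothed periodogram
peak_freq <- function(x, rate, lo = 0.5, hi = 12, spans = 11) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = rate),
                          taper = 0, spans = spans, plot = FALSE)
  sel <- sp$freq >= lo & sp$freq <= hi
  sp$freq[sel][which.max(sp$spec[sel])]
}

# small shared world for module tests: 3 channels, 2 bands, 8-s epochs
tiny_bands <- function() list(band_spec("theta", 4, 8), band_spec("alpha", 9, 12))

tiny_cfg <- function(...) {
  args <- list(n_dyads = 2, n_channels = 3, epoch_len = 8, n_topics = 2,
               bands = tiny_bands(), seed = 42)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# epoch_set built from a named list of channels x T matrices (one per
# topic) plus a rest matrix
make_es <- function(topic_mats, rest, rate = 250, role = "listen") {
  eps <- c(
    lapply(names(topic_mats), function(tp) list(role = role, topic = tp,
                                                data = topic_mats[[tp]])),
    list(list(role = "rest", topic = "rest", data = rest))
  )
  epoch_set(eps, rate, sprintf("ch%02d", seq_len(nrow(rest))))
}
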