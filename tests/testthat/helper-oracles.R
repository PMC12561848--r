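# Independent brute-force oracles the analysis code is checked against.
# They deliberately use plain per-observation loops over explicitly
# computed group means, sharing no code with the package's vectorized
# stratum decompositions.

# activity table from a g x e x r value array
at_from_array <- function(a, gl = NULL, el = NULL, bl = NULL) {
  d <- dim(a)
  if (is.null(gl)) gl <- paste0("G", seq_len(d[1]))
  if (is.null(el)) el <- paste0("E", seq_len(d[2]))
  if (is.null(bl)) bl <- paste0("B", seq_len(d[3]))
  idx <- expand.grid(g = seq_len(d[1]), e = seq_len(d[2]), p = seq_len(d[3]))
  activity_table(gl[idx$g], el[idx$e], bl[idx$p], a[as.matrix(idx)],
                 genotype_order = gl, environment_order = el, block_order = bl)
}

random_table <- function(g, e, r, sd = 1, mu = 0) {
  at_from_array(array(rnorm(g * e * r, mu, sd), dim = c(g, e, r)))
}

# Brute-force split-plot stratum SS: every stratum as a direct sum of
# squared deviations of fitted means, observation by observation.
sp_oracle <- function(tab) {
  g <- as.integer(tab$genotype); e <- as.integer(tab$environment)
  p <- as.integer(tab$block); y <- tab$value
  grand <- mean(y)
  mean_of <- function(keys) {
    vapply(seq_along(y), function(i) {
      sel <- rep(TRUE, length(y))
      if ("g" %in% keys) sel <- sel & g == g[i]
      if ("e" %in% keys) sel <- sel & e == e[i]
      if ("p" %in% keys) sel <- sel & p == p[i]
      mean(y[sel])
    }, numeric(1))
  }
  m_p <- mean_of("p"); m_e <- mean_of("e"); m_g <- mean_of("g")
  m_ep <- mean_of(c("e", "p")); m_ge <- mean_of(c("g", "e"))
  c(blocks = sum((m_p - grand)^2),
    main = sum((m_e - grand)^2),
    mpe = sum((m_ep - m_e - m_p + grand)^2),
    sub = sum((m_g - grand)^2),
    int = sum((m_ge - m_g - m_e + grand)^2),
    spe = sum((y - m_ep - m_ge + m_e)^2),
    total = sum((y - grand)^2))
}

# Brute-force double-centering: interaction residuals and SS on the
# cell-mean scale, computed with explicit loops.
dc_oracle <- function(tab) {
  gl <- levels(tab$genotype); el <- levels(tab$environment)
  g <- length(gl); e <- length(el)
  cm <- matrix(NA_real_, g, e)
  for (i in seq_len(g)) for (j in seq_len(e))
    cm[i, j] <- mean(tab$value[tab$genotype == gl[i] & tab$environment == el[j]])
  grand <- mean(cm)
  resid <- matrix(NA_real_, g, e)
  for (i in seq_len(g)) for (j in seq_len(e))
    resid[i, j] <- cm[i, j] - mean(cm[i, ]) - mean(cm[, j]) + grand
  r <- nlevels(tab$block)
  list(resid = resid, interaction_ss = r * sum(resid^2))
}
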