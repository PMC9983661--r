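# Fixtures are built in code; nothing binary is stored.

# Small random count matrix with dimnames.
randomCounts <- function(genes = 6, samples = 3, max = 50) {
  m <- matrix(sample.int(max, genes * samples, replace = TRUE),
              nrow = genes,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("S", seq_len(samples))))
  storage.mode(m) <- "double"
  m
}

writeTempCounts <- function(m, format = "tsv") {
  path <- tempfile(fileext = paste0(".", format))
  writeCounts(m, path, format = format)
  path
}

# Minimal valid sample sheet for a 3-dose x 3-rep design.
doseSheet <- function(ids = sprintf("S%02d", 1:9),
                      doses = rep(c(0, 0.001, 0.01), each = 3),
                      strain = "p50") {
  data.frame(sample_id = ids, strain = strain,
             treatment = ifelse(doses > 0, "mulberry", "control"),
             dose = doses, time_h = 90, stringsAsFactors = FALSE)
}

# Random occupation profile (strictly positive unless zeros requested).
randomProfile <- function(k, zeros = 0) {
  p <- runif(k)
  if (zeros > 0) p[sample.int(k, zeros)] <- 0
  p / sum(p)
}

# Brute-force least-squares oracle: refining dense grid search,
# independent of the centred-sums implementation. Parameterized as
# y ~ mu + b * (x - mean(x)) so the two axes decouple and the zoomed
# grid always brackets the optimum.
gridSearchOLS <- function(x, y, iters = 60) {
  xc <- x - mean(x)
  b0 <- 0; m0 <- mean(y)
  span <- max(1, diff(range(y)) / max(diff(range(xc)), 1e-9)) * 4
  spanM <- max(1, diff(range(y))) * 2
  for (i in seq_len(iters)) {
    bs <- seq(b0 - span, b0 + span, length.out = 21)
    ms <- seq(m0 - spanM, m0 + spanM, length.out = 21)
    r0 <- y - m0 - b0 * xc
    # SSE difference vs the grid centre, elementwise, so the constant
    # SSE floor cancels before summation and the comparison stays
    # meaningful at machine precision
    dsse <- matrix(NA_real_, length(ms), length(bs))
    for (im in seq_along(ms)) for (ib in seq_along(bs)) {
      d <- (ms[im] - m0) + (bs[ib] - b0) * xc
      dsse[im, ib] <- sum(d * d - 2 * r0 * d)
    }
    idx <- arrayInd(which.min(dsse), dim(dsse))
    m0 <- ms[idx[1]]; b0 <- bs[idx[2]]
    span <- span * 0.5; spanM <- spanM * 0.5
  }
  c(intercept = m0 - b0 * mean(x), slope = b0)
}

# Vectorized OLS slope test over many simulated responses: x length n,
# Y an n x R matrix. Returns list of vectors (beta, se, t, p).
olsMany <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  Yc <- sweep(Y, 2, colMeans(Y))
  beta <- as.numeric(crossprod(xc, Yc)) / Sxx
  sse <- colSums(Yc^2) - beta^2 * Sxx
  sse[sse < 0] <- 0
  se <- sqrt(sse / (n - 2) / Sxx)
  t <- beta / se
  list(beta = beta, se = se, t = t,
       p = studentTTwoSidedP(t, n - 2))
}

# Entropy in bits of each column of a count matrix, written directly
# from the definition (independent re-computation oracle).
entropyByDefinition <- function(m) {
  apply(m, 2, function(cc) {
    p <- cc / sum(cc)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}
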