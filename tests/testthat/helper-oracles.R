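# Independent oracles: definition-level computations on raw symbol vectors,
# sharing no code path with the package's entropy engine.

rand_aln <- function(n, L, nsym = 21, seed = 1) {
  set.seed(seed)
  encoded_alignment(matrix(sample.int(nsym, n * L, replace = TRUE), n, L))
}

# brute-force joint entropy: enumerate symbol tuples, sum -p log2 p
o_H <- function(...) {
  key <- do.call(paste, c(list(...), sep = ","))
  p <- as.numeric(table(key)) / length(key)
  -sum(p * log2(p))
}

# definition-level MI: sum p(a,b) log2[p(a,b) / (p(a) p(b))]
o_MI <- function(x, y) {
  n <- length(x)
  pj <- table(x, y) / n
  px <- rowSums(pj)
  py <- colSums(pj)
  s <- 0
  for (a in seq_len(nrow(pj))) for (b in seq_len(ncol(pj))) {
    if (pj[a, b] > 0)
      s <- s + pj[a, b] * log2(pj[a, b] / (px[a] * py[b]))
  }
  as.numeric(s)
}

# weighted per-stratum MI over the values of one conditioning vector
o_CMI1 <- function(x, y, z) {
  s <- 0
  for (v in unique(z)) {
    w <- mean(z == v)
    s <- s + w * o_MI(x[z == v], y[z == v])
  }
  s
}

# weighted per-stratum MI over the joint values of two conditioning vectors
o_CMI2 <- function(x, y, z, w) {
  key <- paste(z, w)
  s <- 0
  for (v in unique(key)) {
    p <- mean(key == v)
    s <- s + p * o_MI(x[key == v], y[key == v])
  }
  s
}

# direct-formula APC on a plain matrix (NA diagonal)
o_apc <- function(s) {
  diag(s) <- NA
  mi <- rowMeans(s, na.rm = TRUE)
  mall <- mean(s[row(s) != col(s)], na.rm = TRUE)
  out <- s
  for (i in seq_len(nrow(s))) for (j in seq_len(ncol(s)))
    if (i != j) out[i, j] <- s[i, j] - mi[i] * mi[j] / mall
  out
}

# direct two-sided z-product ZPX2 (sample sd; both-negative -> negative)
o_zpx2 <- function(s) {
  diag(s) <- NA
  L <- nrow(s)
  z <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    v <- s[i, -i]
    z[i, -i] <- (s[i, -i] - mean(v)) / sd(v)
  }
  out <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    p <- z[i, j] * z[j, i]
    if (z[i, j] < 0 && z[j, i] < 0) p <- -abs(p)
    out[i, j] <- p
  }
  out
}

# brute-force transitivity: enumerate all node triples
o_transitivity <- function(A) {
  L <- nrow(A)
  closed <- 0
  open <- 0
  for (i in seq_len(L - 2)) for (j in seq(i + 1, L - 1)) for (k in seq(j + 1, L)) {
    e <- A[i, j] + A[i, k] + A[j, k]
    if (e == 3) closed <- closed + 1
    if (e == 2) open <- open + 1
  }
  # connected triples = 3 per triangle + 1 per open triad
  denom <- 3 * closed + open
  if (denom == 0) return(0)
  3 * closed / denom
}

# a symmetric random map with NA diagonal
rand_map <- function(L, seed = 1, method = "external") {
  set.seed(seed)
  s <- matrix(rnorm(L * L), L, L)
  s <- (s + t(s)) / 2
  covariation_map(s, method = method)
}
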