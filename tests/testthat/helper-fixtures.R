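# shared fixtures built in code at test time

# long-format map file for an nx x ny grid with `axis` wavenumbers;
# intensity defaults to a deterministic function of (pixel, channel) so
# round trips are checkable. Returns the path.
write_toy_map <- function(nx, ny, axis = c(100, 200, 300),
                          path = tempfile(fileext = ".txt"),
                          intensity = NULL, shuffle = FALSE, sep = "\t") {
  nw <- length(axis)
  np <- nx * ny
  if (is.null(intensity)) {
    intensity <- outer(seq_len(np), seq_len(nw),
                       function(p, w) p * 10 + w)
  }
  ix <- ((seq_len(np) - 1) %% nx) + 1
  iy <- ((seq_len(np) - 1) %/% nx) + 1
  df <- data.frame(
    x = rep((ix - 1) * 1.5, each = nw),
    y = rep((iy - 1) * 1.5, each = nw),
    wn = rep(axis, times = np),
    iv = as.vector(t(intensity)))
  if (shuffle) df <- df[sample.int(nrow(df)), ]
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  path
}

table1_grid <- function() {
  read_similarity_table(example_similarity_table())
}

# dense-algebra AsLS oracle: identical model solved with base solve()
als_oracle <- function(y, lambda, p, iterations) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iterations)) {
    z <- solve(P + diag(w), w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

# small deterministic non-negative test matrix
random_nonneg <- function(n, m, seed) {
  set.seed(seed)
  matrix(stats::runif(n * m), n, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
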