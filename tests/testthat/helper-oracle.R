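# Independent quadratic-time affine-gap DP oracle (pure R, score + traceback).
# Same scoring convention as the package: gap of length L costs open + L*ext,
# N mismatches everything. Used only on short strings.

oracleAlign <- function(query, target, mode = c("local", "semi-global"),
                        match = 1, mismatch = -2, gap_open = -2,
                        gap_ext = -1) {
  mode <- match.arg(mode)
  q <- strsplit(toupper(query), "")[[1]]
  t <- strsplit(toupper(target), "")[[1]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in target (consumes query)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query  (consumes target)
  H[1, ] <- 0                      # free leading target
  if (mode == "local") {
    H[, 1] <- 0
  } else {
    for (i in seq_len(n)) {
      X[i + 1, 1] <- gap_open + i * gap_ext
      H[i + 1, 1] <- X[i + 1, 1]
    }
  }
  s <- function(a, b) if (a == "N" || b == "N") mismatch else
    if (a == b) match else mismatch
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M <- H[i, j] + s(q[i], t[j])
    X[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_ext,
                           X[i, j + 1] + gap_ext)
    Y[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_ext,
                           Y[i + 1, j] + gap_ext)
    h <- max(M, X[i + 1, j + 1], Y[i + 1, j + 1])
    if (mode == "local") h <- max(h, 0)
    H[i + 1, j + 1] <- h
  }
  if (mode == "local") {
    best <- max(H)
  } else {
    best <- max(H[n + 1, ])
  }
  # n_matches by greedy traceback from the best cell
  if (mode == "local") {
    idx <- which(H == best, arr.ind = TRUE)[1, ]
  } else {
    j <- which.max(H[n + 1, ])
    idx <- c(n + 1, j)
  }
  i <- idx[1] - 1; j <- idx[2] - 1
  nm <- 0
  state <- "H"
  while (i > 0 || j > 0) {
    if (state == "H") {
      if (i == 0 || j == 0) break
      h <- H[i + 1, j + 1]
      if (mode == "local" && h == 0) break
      if (h == H[i, j] + s(q[i], t[j])) {
        if (q[i] == t[j] && q[i] != "N") nm <- nm + 1
        i <- i - 1; j <- j - 1
      } else if (h == X[i + 1, j + 1]) state <- "X"
      else state <- "Y"
    } else if (state == "X") {
      if (i == 0) break
      opening <- X[i + 1, j + 1] == H[i, j + 1] + gap_open + gap_ext
      i <- i - 1
      if (opening) state <- "H"
    } else {
      if (j == 0) break
      opening <- Y[i + 1, j + 1] == H[i + 1, j] + gap_open + gap_ext
      j <- j - 1
      if (opening) state <- "H"
    }
  }
  list(score = best, n_matches = nm)
}

# brute-force maximum clique by subset enumeration (n <= 15)
oracleMaxClique <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) >= 2L) {
      pr <- combn(members, 2)
      ok <- all(adj[cbind(pr[1, ], pr[2, ])] == 1L)
    }
    if (ok) best <- length(members)
  }
  best
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
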