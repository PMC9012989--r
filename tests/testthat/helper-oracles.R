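# Shared fixtures and independent oracles for the test suite.

# small, fast phantom used across tests
small_spec <- function(...) phantom_spec(rows = 128L, cols = 168L, ...)

# optimal 1-D K-means by dynamic programming over contiguous partitions of
# the sorted values (contiguity is optimal in 1-D); returns sorted cluster
# means of the exactly-K-cluster optimum
contiguous_kmeans_oracle <- function(values, K) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {           # cost of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    q <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, K, n)
  B <- matrix(NA_integer_, K, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (K > 1) for (k in 2:K) for (j in k:n) for (i in k:j) {
    v <- D[k - 1, i - 1] + sse(i, j)
    if (v < D[k, j] - 1e-12) { D[k, j] <- v; B[k, j] <- i }
  }
  bounds <- integer(0); j <- n
  for (k in K:2) { i <- B[k, j]; bounds <- c(i, bounds); j <- i - 1 }
  starts <- c(1, bounds); ends <- c(bounds - 1, n)
  sort(vapply(seq_len(K), function(k) mean(x[starts[k]:ends[k]]), numeric(1)))
}

# textbook scalar even-odd point-in-polygon with boundary inclusion,
# written independently of the package's vectorized version
pip_oracle <- function(r, c, verts) {
  n <- nrow(verts)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    y1 <- verts[j, 1]; x1 <- verts[j, 2]
    y2 <- verts[i, 1]; x2 <- verts[i, 2]
    cross <- (c - x1) * (y2 - y1) - (r - y1) * (x2 - x1)
    if (abs(cross) < 1e-9 &&
        c >= min(x1, x2) - 1e-9 && c <= max(x1, x2) + 1e-9 &&
        r >= min(y1, y2) - 1e-9 && r <= max(y1, y2) + 1e-9) return(TRUE)
    if ((y1 > r) != (y2 > r)) {
      xint <- x1 + (r - y1) * (x2 - x1) / (y2 - y1)
      if (c < xint) inside <- !inside
    }
  }
  inside
}

# brute-force local-maximum scan (no prominence logic) for peak tests
local_maxima_oracle <- function(f) {
  which(vapply(seq_along(f), function(i) {
    l <- if (i > 1) f[i - 1] else -Inf
    r <- if (i < length(f)) f[i + 1] else -Inf
    f[i] > l && f[i] > r
  }, logical(1)))
}

# mirror a phantom: flip the field left-right and swap the side anchors
mirror_phantom <- function(ph) {
  C <- ph$field$cols
  vals <- ph$field$values[, C:1, drop = FALSE]
  a <- unclass(ph$anchors)
  a[, "col"] <- C + 1 - a[, "col"]
  swap <- c(Pur_1 = "Pur_5", Pur_2 = "Pur_6", Pur_3 = "Pur_7", Pur_4 = "Pur_8",
            Pur_5 = "Pur_1", Pur_6 = "Pur_2", Pur_7 = "Pur_3", Pur_8 = "Pur_4")
  nm <- rownames(a)
  rownames(a) <- ifelse(nm %in% names(swap), swap[nm], nm)
  list(field = temperature_field(vals), anchors = anchor_set(a))
}

roi_mirror_pairs <- function() {
  rbind(c("ROI1", "ROI5"), c("ROI2", "ROI6"), c("ROI3", "ROI7"),
        c("ROI4", "ROI8"), c("ROI9", "ROI10"), c("ROI11", "ROI12"),
        c("ROI13", "ROI14"), c("ROI15", "ROI16"), c("ROI17", "ROI18"))
}

# random binary context with informative dimnames
random_context <- function(n_obj, n_attr, p = 0.5) {
  m <- matrix(rbinom(n_obj * n_attr, 1, p), n_obj, n_attr,
              dimnames = list(paste0("o", seq_len(n_obj)),
                              paste0("a", seq_len(n_attr))))
  m
}
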