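# Independent brute-force oracles and tiny fixture builders.

# Double-loop windowed min/max with border clipping and mask exclusion;
# deliberately naive so it stays independent of the package implementation.
oracle_morph <- function(values, valid, size, op = min) {
  nr <- nrow(values); nc <- ncol(values)
  r <- (size - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && valid[ii, jj])
        vals <- c(vals, values[ii, jj])
    }
    if (length(vals)) out[i, j] <- op(vals)
  }
  out
}

oracle_open <- function(values, valid, size) {
  ero <- oracle_morph(values, valid, size, min)
  oracle_morph(ero, valid & !is.na(ero), size, max)
}

# Tukey whiskers by direct enumeration (sorting-based type-7 quartiles).
oracle_whiskers <- function(x) {
  x <- sort(x)
  q7 <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75); iqr <- q3 - q1
  inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
  c(min(inside), max(inside))
}

# Scalar re-implementations of every index formula, written directly from the
# published definitions (independent of the registry).
oracle_index <- function(name, b) {
  switch(name,
    PKI_raw = (b["red_edge"] + b["blue"]) / (2.5 * b["green"]),
    RI = b["red"] / b["green"],
    NDVI = (b["nir"] - b["red"]) / (b["nir"] + b["red"]),
    NDRE = (b["nir"] - b["red_edge"]) / (b["nir"] + b["red_edge"]),
    GNDVI = (b["nir"] - b["green"]) / (b["nir"] + b["green"]),
    CIRE = b["nir"] / b["red_edge"] - 1,
    CIG = b["nir"] / b["green"] - 1,
    ARI = 1 / b["green"] - 1 / b["red_edge"],
    stop("unknown index"))
}

# Constant-band scene builder for pointwise formula checks.
const_scene <- function(vals, nr = 3, nc = 3) {
  scene(lapply(vals, function(v) matrix(v, nr, nc)))
}

# Per-pixel persistence category by direct enumeration of a presence-year
# logical vector, following the published typology.
oracle_persistence <- function(present, merge_short = TRUE) {
  yrs <- which(present)
  if (length(yrs) == 0) return("never")
  gap <- length(yrs) > 1 && any(diff(yrs) > 1)
  if (gap) return("recurrent")
  if (length(yrs) == 1) return("ephemeral")
  if (length(yrs) == 2) return(if (merge_short) "continuous" else "short_continuous")
  "continuous"
}
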