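# Shared fixtures, built in code.

# small worlds are expensive; cache per test run
.world_cache <- new.env(parent = emptyenv())
cachedWorld <- function(key, config) {
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generateWorld(config)
  .world_cache[[key]]
}

tinyTable <- function() {
  ObservationTable(matrix(c(1, 0, 2, 3), 2, 2, byrow = TRUE,
                          dimnames = list(c("f1", "f2"), c("s1", "s2"))))
}

threeTipTree <- function() readTree("((A:1,B:1):1,C:2);")

# Brute-force NODF oracle: literal loop over ordered pairs. Overlaps are
# accumulated as integers per lower-fill member before the single exact
# integer-ratio division, so agreement with the library is bitwise.
bruteNodf <- function(p) {
  axis <- function(m) {
    n <- nrow(m)
    if (n < 2) return(NA_real_)
    fills <- rowSums(m)
    ord <- order(fills, decreasing = TRUE)   # stable, like the library
    m <- m[ord, , drop = FALSE]
    fills <- fills[ord]
    terms <- numeric(0)
    for (j in seq_len(n)) {
      num <- 0L   # integer shared-presence total with all denser partners
      for (i in seq_len(n)) {
        if (fills[i] > fills[j]) num <- num + sum(m[i, ] & m[j, ])
      }
      if (any(fills > fills[j])) terms <- c(terms, num / fills[j])
    }
    sum(terms) / (n * (n - 1) / 2)
  }
  r <- axis(p); c <- axis(t(p))
  nr <- nrow(p); nc <- ncol(p)
  w <- c(nr * (nr - 1) / 2, nc * (nc - 1) / 2)
  vals <- c(r, c)
  ok <- !is.na(vals)
  c(rows = r, cols = c, overall = sum(w[ok] * vals[ok]) / sum(w[ok]))
}

randomPresence <- function(nr, nc, fill = 0.4) {
  repeat {
    p <- matrix(stats::runif(nr * nc) < fill, nr, nc)
    if (all(rowSums(p) > 0) && all(colSums(p) > 0)) return(p)
  }
}
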