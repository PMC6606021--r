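# Independent reference implementations used to cross-check the package.

# Reference 3-D connected-component labeling: plain R flood fill over an
# explicit neighbour-offset list. Deliberately written without reference to
# the package's C++ implementation.
flood_label <- function(vol, connectivity = 26) {
  dims <- dim(vol)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  for (v in which(vol)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ijk <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1L) || any(nb > dims)) next
        li <- nb[1] + dims[1] * (nb[2] - 1L) + dims[1] * dims[2] * (nb[3] - 1L)
        if (vol[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# labelings are equal up to renumbering when they induce the same partition
same_partition <- function(a, b) {
  fa <- split(which(a != 0), a[a != 0])
  fb <- split(which(b != 0), b[b != 0])
  setequal(lapply(fa, sort), lapply(fb, sort))
}

# FIML normal log-likelihood over per-subject observed submatrices,
# via mvtnorm as an independent density oracle
mvn_loglik_rows <- function(Y, mu, Sig) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    if (!length(obs)) next
    ll <- ll + mvtnorm::dmvnorm(Y[i, obs], mu[obs],
                                Sig[obs, obs, drop = FALSE], log = TRUE)
  }
  ll
}
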