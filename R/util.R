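# Small numerical utilities shared across modules.

# contract dimension k of array A with matrix M (dim(A)[k] x m)
.ctr_dim <- function(A, M, k) {
  d <- dim(A)
  perm <- c(setdiff(seq_along(d), k), k)
  B <- aperm(A, perm)
  B <- matrix(B, prod(d[-k]), d[k]) %*% M
  B <- array(B, c(d[-k], ncol(M)))
  aperm(B, match(seq_along(d), perm))
}

# transform a 4-index Dirac AO tensor to MO blocks
.mo4 <- function(T_ao, C1, C2, C3, C4) {
  T1 <- .ctr_dim(T_ao, C1, 1)
  T1 <- .ctr_dim(T1, C2, 2)
  T1 <- .ctr_dim(T1, C3, 3)
  .ctr_dim(T1, C4, 4)
}

# compensated (Kahan) accumulator so batch partitions are order-invariant
.kahan_new <- function() list(s = 0, c = 0)
.kahan_add <- function(k, x) {
  y <- x - k$c
  t <- k$s + y
  k$c <- (t - k$s) - y
  k$s <- t
  k
}
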