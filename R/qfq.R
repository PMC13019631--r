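# Operator algebra of the strong-orthogonality projector: the expansion of
# Q12 f1 Q12 into operator/projector combinations, its reduction by projector
# idempotency, commutation and the Brillouin-type annihilation rules
# (o f v = v f o = 0, o v = v o = 0), and matrix evaluators used by the
# reduction oracle and the dense reference.
#
# Q12 = (1 - o1)(1 - o2)(1 - v1 v2) = 1 - o1 - o2 + o1 o2 - v1 v2.

#' Projector term table for Q12 f1 Q12
#'
#' Returns the raw expansion of Q12 f1 Q12 (left factor x f1 x right factor,
#' with signs), the annihilation marks from o v = 0 and o f v = 0, and the
#' reduced final term list in which the transpose operator T collects each
#' term with its adjoint.  The reduction is fixed data, not run-time symbol
#' manipulation.
#'
#' @return object of class `f12_qfq` with `expansion` (data frame) and
#'   `terms` (reduced list: name, coef, transpose flag)
#' @export
reduce_qfq <- function() {
  facs <- c("1", "o1", "o2", "o1o2", "v1v2")
  sgn <- c(1, -1, -1, 1, -1)
  expansion <- expand.grid(left = facs, right = facs,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expansion$sign <- sgn[match(expansion$left, facs)] *
    sgn[match(expansion$right, facs)]
  # annihilation: o2 ... f1 ... v2 vanishes through o2 v2 = 0 (electron 2
  # operators commute past f1); o1 f1 v1 and v1 f1 o1 vanish through the
  # Brillouin-type identity o f v = 0
  has <- function(x, p) grepl(p, x, fixed = TRUE)
  expansion$annihilated <-
    (has(expansion$left, "o2") & has(expansion$right, "v2")) |
    (has(expansion$left, "v2") & has(expansion$right, "o2")) |
    (has(expansion$left, "o1") & has(expansion$right, "v1")) |
    (has(expansion$left, "v1") & has(expansion$right, "o1"))
  terms <- list(
    list(name = "f1",       coef =  1, transpose = FALSE),
    list(name = "f1o2",     coef = -1, transpose = FALSE),
    list(name = "f1o1",     coef = -1, transpose = TRUE),
    list(name = "f1o1o2",   coef =  1, transpose = TRUE),
    list(name = "f1v1v2",   coef = -1, transpose = TRUE),
    list(name = "o1f1o1",   coef =  1, transpose = FALSE),
    list(name = "o1f1o1o2", coef = -1, transpose = FALSE),
    list(name = "v1f1v1v2", coef =  1, transpose = FALSE)
  )
  structure(list(expansion = expansion, terms = terms), class = "f12_qfq")
}

# one-electron operator matrices on the two-electron product space
.kron2 <- function(a, b) kronecker(b, a)  # electron 1 fastest

.qfq_op_matrix <- function(name, f, o, v) {
  n <- nrow(f)
  I <- diag(n)
  switch(name,
    f1       = .kron2(f, I),
    f1o2     = .kron2(f, o),
    f1o1     = .kron2(f %*% o, I),
    f1o1o2   = .kron2(f %*% o, o),
    f1v1v2   = .kron2(f %*% v, v),
    o1f1o1   = .kron2(o %*% f %*% o, I),
    o1f1o1o2 = .kron2(o %*% f %*% o, o),
    v1f1v1v2 = .kron2(v %*% f %*% v, v),
    stop("unknown Q f Q term: ", name))
}

#' Evaluate the reduced Q f Q term list as matrices
#'
#' @param qfq result of [reduce_qfq()]
#' @param f Hermitian one-electron operator matrix
#' @param o,v orthogonal projector matrices with `o v = 0`
#' @return the term-list matrix on the two-electron product space
#' @export
qfq_eval_terms <- function(qfq, f, o, v) {
  acc <- 0
  for (tm in qfq$terms) {
    m <- .qfq_op_matrix(tm$name, f, o, v)
    if (tm$transpose) m <- m + t(m)
    acc <- acc + tm$coef * m
  }
  acc
}

#' Direct evaluation of Q12 f1 Q12 on the two-electron product space
#' @inheritParams qfq_eval_terms
#' @export
qfq_direct <- function(f, o, v) {
  n <- nrow(f)
  I <- diag(n)
  I2 <- diag(n * n)
  Q <- (I2 - .kron2(o, I)) %*% (I2 - .kron2(I, o)) %*% (I2 - .kron2(v, v))
  Q %*% .kron2(f, I) %*% Q
}
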