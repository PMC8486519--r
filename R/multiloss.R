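# The joint-learning multiloss: softmax, cross-entropy, cosine similarity
# between the two heads' softmax outputs, the combined objective
# kappa = L1 + L2 + L3 - lambda * L4 (literal mode; a diversity mode with
# +lambda * L4 is also provided), and early-fusion probability averaging.

#' Numerically stable softmax
#'
#' `y_c = exp(s_c) / sum_j exp(s_j)`, computed shift-invariantly (the
#' maximum is subtracted first) so scores up to `|s| = 1e4` do not
#' overflow. For a matrix, columns are treated as independent score
#' vectors.
#'
#' @param s Numeric vector of class scores (logits), or a C x N matrix.
#' @return Probability vector (or matrix) of the same shape; entries in
#'   `[0, 1]` summing to 1 per vector/column.
#' @examples
#' softmax(c(log(2), 0))  # 2/3, 1/3
#' @export
softmax <- function(s) {
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (is.matrix(s)) {
    z <- exp(sweep(s, 2, apply(s, 2, max)))
    sweep(z, 2, colSums(z), "/")
  } else {
    z <- exp(s - max(s))
    z / sum(z)
  }
}

check_onehot <- function(t) {
  if (!is.numeric(t) || any(!t %in% c(0, 1)) || sum(t) != 1) {
    stop("`t` must be one-hot: exactly one entry equal to 1", call. = FALSE)
  }
}

#' Cross-entropy (softmax loss) against a one-hot target
#'
#' `-sum_c t_c log(max(y_c, epsilon))`; the epsilon floor inside the log
#' guards against `log(0)`.
#'
#' @param y Probability vector of length C.
#' @param t One-hot vector of length C.
#' @param epsilon Floor inside the log, in `(0, 1e-3]`.
#' @return Nonnegative scalar; ~0 iff `y` matches `t`.
#' @examples
#' cross_entropy(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
cross_entropy <- function(y, t, epsilon = 1e-7) {
  stopifnot(epsilon > 0, epsilon <= 1e-3)
  check_onehot(t)
  if (length(y) != length(t)) stop("length mismatch", call. = FALSE)
  -sum(t * log(pmax(y, epsilon)))
}

#' Cosine similarity of two probability vectors
#'
#' `<p, q> / (||p|| ||q||)`; lies in `[0, 1]` for probability vectors and
#' equals 1 iff they are proportional.
#'
#' @param p,q Nonzero numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) stop("zero vector has no direction", call. = FALSE)
  sum(p * q) / (np * nq)
}

#' Early fusion of two heads' probabilities
#'
#' Elementwise average; the ensemble's final prediction is the argmax of
#' the fused vector.
#'
#' @param p1,p2 Probability vectors (or C x N matrices) of equal shape.
#' @return The elementwise mean, a valid probability vector/matrix.
#' @export
fuse_probs <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("length mismatch", call. = FALSE)
  (p1 + p2) / 2
}

#' The joint-learning multiloss
#'
#' `L1` is the cross-entropy of the fused (early-fusion averaged)
#' prediction against the ground truth, `L2`/`L3` the per-head
#' cross-entropies, and `L4` the cosine similarity between the two heads'
#' softmax outputs. In literal mode `kappa = L1 + L2 + L3 - lambda * L4`
#' (the printed objective, which rewards similar heads at its minimum); in
#' diversity mode `kappa = L1 + L2 + L3 + lambda * L4` (penalizing head
#' similarity, matching the stated intent of maximal difference between
#' heads). Batches (C x N matrices, plus a one-hot matrix `t`) are handled
#' by computing every component per sample and averaging.
#'
#' @param t One-hot target vector, or C x N one-hot matrix for a batch.
#' @param p1,p2 Head probability vectors (or C x N matrices).
#' @param lambda Nonnegative coupling weight on the cosine term
#'   (default 3).
#' @param sign_mode `"literal"` or `"diversity"`.
#' @param epsilon Cross-entropy log floor.
#' @return A `multiloss_value`: list with `L1`, `L2`, `L3`, `L4`, `kappa`,
#'   `lambda`, `sign_mode`.
#' @examples
#' multiloss(c(1, 0), c(0.8, 0.2), c(0.6, 0.4))
#' @export
multiloss <- function(t, p1, p2, lambda = 3,
                      sign_mode = c("literal", "diversity"),
                      epsilon = 1e-7) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(lambda >= 0)
  if (!is.matrix(t)) {
    t <- matrix(t); p1 <- matrix(p1); p2 <- matrix(p2)
  }
  stopifnot(identical(dim(t), dim(p1)), identical(dim(t), dim(p2)))
  for (j in seq_len(ncol(t))) check_onehot(t[, j])
  pf <- fuse_probs(p1, p2)
  ce_cols <- function(y) -colSums(t * log(pmax(y, epsilon)))
  L1 <- mean(ce_cols(pf))
  L2 <- mean(ce_cols(p1))
  L3 <- mean(ce_cols(p2))
  n1 <- sqrt(colSums(p1^2)); n2 <- sqrt(colSums(p2^2))
  if (any(n1 == 0) || any(n2 == 0)) {
    stop("zero vector has no direction", call. = FALSE)
  }
  L4 <- mean(colSums(p1 * p2) / (n1 * n2))
  kappa <- L1 + L2 + L3 + if (sign_mode == "literal") -lambda * L4 else
    lambda * L4
  structure(list(L1 = L1, L2 = L2, L3 = L3, L4 = L4, kappa = kappa,
                 lambda = lambda, sign_mode = sign_mode),
            class = "multiloss_value")
}

#' @export
print.multiloss_value <- function(x, ...) {
  cat(sprintf(
    "<multiloss> kappa=%.5f (L1=%.5f L2=%.5f L3=%.5f L4=%.5f, lambda=%g, %s)\n",
    x$kappa, x$L1, x$L2, x$L3, x$L4, x$lambda, x$sign_mode))
  invisible(x)
}

#' Gradient of the multiloss with respect to the head logits
#'
#' Analytic reverse-mode gradient of the batch-mean `kappa` with respect
#' to the two heads' score (logit) matrices; this is what joint training
#' backpropagates into each branch. The epsilon floor of the cross-entropy
#' is treated as inactive (probabilities are strictly positive under
#' softmax).
#'
#' @param t One-hot C x N matrix.
#' @param s1,s2 Head logit matrices, C x N.
#' @param lambda,sign_mode As in [multiloss()].
#' @return List with `gs1`, `gs2` (C x N gradients) and the forward
#'   `multiloss_value`.
#' @export
multiloss_logit_grads <- function(t, s1, s2, lambda = 3,
                                  sign_mode = c("literal", "diversity")) {
  sign_mode <- match.arg(sign_mode)
  if (!is.matrix(t)) {
    t <- matrix(t); s1 <- matrix(s1); s2 <- matrix(s2)
  }
  N <- ncol(t)
  p1 <- softmax(s1); p2 <- softmax(s2)
  value <- multiloss(t, p1, p2, lambda = lambda, sign_mode = sign_mode)
  pf <- (p1 + p2) / 2
  # dL/dp for each component (per sample, before the 1/N batch average)
  g1 <- -t / pf / 2 - t / p1      # dL1/dp1 + dL2/dp1
  g2 <- -t / pf / 2 - t / p2      # dL1/dp2 + dL3/dp2
  n1 <- sqrt(colSums(p1^2)); n2 <- sqrt(colSums(p2^2))
  cs <- colSums(p1 * p2) / (n1 * n2)
  gc1 <- sweep(p2, 2, n1 * n2, "/") -
    sweep(p1, 2, cs / n1^2, "*")
  gc2 <- sweep(p1, 2, n1 * n2, "/") -
    sweep(p2, 2, cs / n2^2, "*")
  sgn <- if (sign_mode == "literal") -1 else 1
  g1 <- g1 + sgn * lambda * gc1
  g2 <- g2 + sgn * lambda * gc2
  # softmax backward: gs = p * (g - colSums(g * p))
  back <- function(p, g) p * sweep(g, 2, colSums(g * p))
  list(gs1 = back(p1, g1) / N, gs2 = back(p2, g2) / N, value = value)
}
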