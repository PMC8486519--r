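# Softmax, cross-entropy, cosine similarity, fusion and the combined
# multiloss: closed forms, invariants and batch semantics.

test_that("softmax closed forms and stability", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_equal(softmax(c(1000, 0)), c(1, 0), tolerance = 1e-12)
  expect_equal(softmax(c(1e4, 0, -1e4))[1], 1, tolerance = 1e-12)
  expect_error(softmax(c(NaN, 1)), "finite")
  expect_error(softmax(c(Inf, 1)), "finite")
  # matrix form: columns are independent
  m <- softmax(matrix(c(0, 0, log(2), 0), 2))
  expect_equal(m[, 1], c(0.5, 0.5))
  expect_equal(m[, 2], c(2 / 3, 1 / 3))
})

test_that("cross-entropy closed forms", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(cross_entropy(rep(1 / 5, 5), c(0, 0, 1, 0, 0)), log(5))
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), log(2))
  expect_error(cross_entropy(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
  expect_error(cross_entropy(c(0.5, 0.5), c(1, 0), epsilon = 0.1))
})

test_that("cosine similarity closed forms", {
  expect_equal(cosine_similarity(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(0.5, 0.5), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("fusion averages probabilities and preserves agreeing argmax", {
  expect_equal(fuse_probs(c(0.2, 0.8), c(0.2, 0.8)), c(0.2, 0.8))
  expect_equal(fuse_probs(c(1, 0), c(0, 1)), c(0.5, 0.5))
  set.seed(7)
  for (r in 1:200) {
    pp <- random_prob_pair(4)
    if (which.max(pp$p1) == which.max(pp$p2)) {
      expect_identical(which.max(fuse_probs(pp$p1, pp$p2)),
                       which.max(pp$p1))
    }
    # fused true-class probability never drops below the weaker head
    ci <- which(pp$t == 1)
    expect_gte(fuse_probs(pp$p1, pp$p2)[ci],
               min(pp$p1[ci], pp$p2[ci]) - 1e-12)
  }
})

test_that("multiloss matches independently computed scalar values", {
  # perfectly confident, agreeing heads: kappa = -lambda in literal mode
  ml0 <- multiloss(c(1, 0), c(1, 0), c(1, 0))
  expect_equal(ml0$L1, 0, tolerance = 1e-6)
  expect_equal(ml0$L2, 0, tolerance = 1e-6)
  expect_equal(ml0$L3, 0, tolerance = 1e-6)
  expect_equal(ml0$L4, 1)
  expect_equal(ml0$kappa, -3, tolerance = 1e-5)
  # hand-evaluated example
  ml <- multiloss(c(1, 0), c(0.8, 0.2), c(0.6, 0.4))
  expect_equal(ml$L1, -log(0.7), tolerance = 1e-7)
  expect_equal(ml$L2, -log(0.8), tolerance = 1e-7)
  expect_equal(ml$L3, -log(0.6), tolerance = 1e-7)
  expect_equal(ml$L4, 0.94174, tolerance = 1e-5)
  expect_equal(ml$kappa, -1.73457, tolerance = 1e-4)
  # decoupled limit: lambda = 0 makes both sign modes agree
  a <- multiloss(c(1, 0), c(0.8, 0.2), c(0.6, 0.4), lambda = 0)
  b <- multiloss(c(1, 0), c(0.8, 0.2), c(0.6, 0.4), lambda = 0,
                 sign_mode = "diversity")
  expect_equal(a$kappa, a$L1 + a$L2 + a$L3)
  expect_equal(a$kappa, b$kappa)
})

test_that("decomposition, bound and swap-symmetry invariants hold on random pairs", {
  set.seed(99)
  for (r in 1:500) {
    C <- sample(2:8, 1)
    pp <- random_prob_pair(C)
    ml <- multiloss(pp$t, pp$p1, pp$p2)
    # decomposition: kappa + lambda * L4 = L1 + L2 + L3, all >= 0
    expect_equal(ml$kappa + ml$lambda * ml$L4, ml$L1 + ml$L2 + ml$L3,
                 tolerance = 1e-10)
    expect_gte(ml$L1, 0); expect_gte(ml$L2, 0); expect_gte(ml$L3, 0)
    expect_gte(ml$L4, 0); expect_lte(ml$L4, 1 + 1e-12)
    # bound: literal kappa >= -lambda
    expect_gte(ml$kappa, -ml$lambda - 1e-12)
    # head-swap symmetry
    sw <- multiloss(pp$t, pp$p2, pp$p1)
    expect_equal(sw$L1, ml$L1)
    expect_equal(sw$L4, ml$L4)
    expect_equal(sw$L2, ml$L3)
    expect_equal(sw$L3, ml$L2)
  }
})

test_that("batch multiloss equals the mean of per-sample values", {
  set.seed(5)
  C <- 4; N <- 6
  t <- matrix(0, C, N); p1 <- matrix(0, C, N); p2 <- matrix(0, C, N)
  singles <- vector("list", N)
  for (j in seq_len(N)) {
    pp <- random_prob_pair(C)
    t[, j] <- pp$t; p1[, j] <- pp$p1; p2[, j] <- pp$p2
    singles[[j]] <- multiloss(pp$t, pp$p1, pp$p2)
  }
  batch <- multiloss(t, p1, p2)
  for (comp in c("L1", "L2", "L3", "L4", "kappa")) {
    expect_equal(batch[[comp]],
                 mean(vapply(singles, `[[`, numeric(1), comp)),
                 tolerance = 1e-12)
  }
})

test_that("analytic logit gradients match finite differences of kappa", {
  set.seed(31)
  for (mode in c("literal", "diversity")) {
    C <- 3; N <- 2
    t <- matrix(0, C, N); t[1, 1] <- 1; t[3, 2] <- 1
    s1 <- matrix(stats::rnorm(C * N), C, N)
    s2 <- matrix(stats::rnorm(C * N), C, N)
    g <- multiloss_logit_grads(t, s1, s2, lambda = 3, sign_mode = mode)
    kap <- function(s1, s2) {
      multiloss(t, softmax(s1), softmax(s2), lambda = 3,
                sign_mode = mode)$kappa
    }
    h <- 1e-6
    for (i in seq_len(C * N)) {
      for (head in 1:2) {
        sp <- if (head == 1) s1 else s2
        sp[i] <- sp[i] + h
        up <- if (head == 1) kap(sp, s2) else kap(s1, sp)
        sp[i] <- sp[i] - 2 * h
        dn <- if (head == 1) kap(sp, s2) else kap(s1, sp)
        fd <- (up - dn) / (2 * h)
        an <- if (head == 1) g$gs1[i] else g$gs2[i]
        expect_equal(an, fd, tolerance = 1e-4)
      }
    }
  }
})
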