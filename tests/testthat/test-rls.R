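test_that("the normalized Laplacian matches closed forms and is PSD", {
  I3 <- diag(3); dimnames(I3) <- list(letters[1:3], letters[1:3])
  expect_equal(normalized_laplacian(I3), 0 * I3)
  ones <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(normalized_laplacian(ones),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                      dimnames = dimnames(ones)))
  withr::local_seed(41)
  for (rep in 1:20) {
    S <- random_similarity(sample(3:8, 1))
    # unnormalized form M - S has zero row sums
    M <- diag(rowSums(S))
    expect_equal(max(abs(rowSums(M - S))), 0, tolerance = 1e-12)
    L <- normalized_laplacian(S)
    expect_equal(L, t(L))
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the RLS kernel solves K(S + eta*L*S) = S and matches an explicit inverse", {
  withr::local_seed(43)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    S <- random_similarity(n)
    L <- normalized_laplacian(S)
    eta <- runif(1, 0, 1)
    K <- rls_kernel(S, L, eta)
    K_oracle <- S %*% solve(S + eta * L %*% S)  # explicit inverse
    expect_equal(K, K_oracle, tolerance = 1e-10)
  }
  # eta = 0 or a zero Laplacian reduce the kernel to the identity
  S <- random_similarity(4)
  expect_equal(rls_kernel(S, normalized_laplacian(S), 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-8)
  I4 <- diag(4); dimnames(I4) <- list(rownames(S), rownames(S))
  expect_equal(rls_kernel(I4, normalized_laplacian(I4), 0.7), I4,
               tolerance = 1e-12)
})

test_that("kernel smoothing applies the expected matrix products", {
  P <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("l1", "l2"), c("d1", "d2")))
  I2 <- diag(2)
  # identity kernels are a no-op in both pairings
  sm <- smooth_scores(P, P, I2, I2)
  expect_equal(sm$P_l, P, ignore_attr = TRUE)
  expect_equal(sm$P_d, P, ignore_attr = TRUE)
  # hand-checked single multiply with an asymmetric kernel
  K_d <- matrix(c(1, 0.5, 0, 0.5), 2, 2)
  sm2 <- smooth_scores(P, P, I2, K_d, cross_pairing = TRUE)
  expect_equal(sm2$P_l, P %*% t(K_d), ignore_attr = TRUE)
  expect_equal(sm2$P_d, P, ignore_attr = TRUE)
  sm3 <- smooth_scores(P, P, I2, K_d, cross_pairing = FALSE)
  expect_equal(sm3$P_d, P %*% t(K_d), ignore_attr = TRUE)
  # fusion is the entrywise mean
  A <- matrix(runif(4), 2, 2); B <- matrix(runif(4), 2, 2)
  expect_equal(fuse(A, B), (A + B) / 2)
  expect_equal(fuse(A, A), A)
})

test_that("prediction reduces to known identities in degenerate settings", {
  withr::local_seed(47)
  Y <- matrix(rbinom(20, 1, 0.4), 5, 4,
              dimnames = list(sprintf("l%d", 1:5), sprintf("d%d", 1:4)))
  Sl <- random_similarity(5, rownames(Y))
  Sd <- random_similarity(4, colnames(Y))
  # eta = 0: kernels are the identity, so predict is the plain walk average
  p0 <- model_params(eta_l = 0, eta_d = 0, gamma = 0.2, n_l = 3, n_d = 2)
  plain <- fuse(lncrna_walk(Y, Sl, 0.2, 3), disease_walk(Y, Sd, 0.2, 2))
  expect_equal(predict_associations(Y, Sl, Sd, p0), plain, tolerance = 1e-12)
  # all-identity similarities: every stage is the identity
  Il <- diag(5); dimnames(Il) <- list(rownames(Y), rownames(Y))
  Id <- diag(4); dimnames(Id) <- list(colnames(Y), colnames(Y))
  pid <- model_params(gamma = 0.3, n_l = 4, n_d = 2)
  expect_equal(predict_associations(Y, Il, Id, pid), Y + 0, tolerance = 1e-12)
  # final mode with a single step equals per-step with one iteration
  p1a <- model_params(gamma = 0.2, n_l = 1, n_d = 1, smoothing_mode = "per_step")
  p1b <- model_params(gamma = 0.2, n_l = 1, n_d = 1, smoothing_mode = "final")
  expect_equal(predict_associations(Y, Sl, Sd, p1a),
               predict_associations(Y, Sl, Sd, p1b), tolerance = 1e-14)
})

test_that("prediction commutes with consistent axis permutations", {
  withr::local_seed(53)
  Y <- matrix(rbinom(30, 1, 0.4), 6, 5,
              dimnames = list(sprintf("l%d", 1:6), sprintf("d%d", 1:5)))
  Sl <- random_similarity(6, rownames(Y))
  Sd <- random_similarity(5, colnames(Y))
  params <- model_params(gamma = 0.1, n_l = 4, n_d = 2)
  P <- predict_associations(Y, Sl, Sd, params)
  pi_l <- sample(6); pi_d <- sample(5)
  P2 <- predict_associations(Y[pi_l, pi_d], Sl[pi_l, pi_l], Sd[pi_d, pi_d],
                             params)
  expect_equal(P2, P[pi_l, pi_d], tolerance = 1e-14)
})

test_that("the kernel applied to scores minimizes the regularized objective", {
  # numerical-minimization oracle: K %*% Y minimizes
  # ||Y - S a||_F^2 + eta * tr(a' S L S a) over a, with F = S a
  withr::local_seed(59)
  S <- random_similarity(3)
  L <- normalized_laplacian(S)
  eta <- 0.3
  Y <- matrix(runif(6), 3, 2)
  obj <- function(a_vec) {
    a <- matrix(a_vec, 3, 2)
    sum((Y - S %*% a)^2) + eta * sum(diag(t(a) %*% S %*% L %*% S %*% a))
  }
  grad <- function(a_vec) {
    a <- matrix(a_vec, 3, 2)
    as.vector(2 * (S %*% (S %*% a - Y)) + 2 * eta * (S %*% L %*% S %*% a))
  }
  fit <- optim(rep(0, 6), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  F_opt <- S %*% matrix(fit$par, 3, 2)
  K <- rls_kernel(S, L, eta)
  expect_equal(K %*% Y, F_opt, tolerance = 1e-4, ignore_attr = TRUE)
})
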