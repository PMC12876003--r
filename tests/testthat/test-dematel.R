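test_that("panel aggregation is the element-wise mean", {
  m1 <- matrix(c(0, 4, 2, 0), 2, 2, byrow = TRUE)
  m2 <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
  expect_equal(aggregate_panel(list(m1, m2)),
               matrix(c(0, 2, 3, 0), 2, 2, byrow = TRUE))
  expect_equal(aggregate_panel(list(m1)), m1)
  expect_equal(aggregate_panel(rep(list(m1), 9)), m1)  # idempotent on ties
  expect_error(aggregate_panel(list(m1, matrix(0, 3, 3))),
               class = "danpv_shape_error")
})

test_that("normalization divides by the larger of max row/column sums", {
  A <- matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE)
  expect_equal(normalize_direct(A), matrix(c(0, 0.5, 1, 0), 2, 2, byrow = TRUE))
  Z <- matrix(0, 3, 3)
  expect_equal(normalize_direct(Z), Z)
  S <- matrix(1, 3, 3); diag(S) <- 0
  expect_equal(normalize_direct(S), S / 2)
  D <- normalize_direct(S)
  expect_lte(max(rowSums(D)), 1)
  expect_lte(max(colSums(D)), 1)
})

test_that("total influence matches the closed form and the Neumann series", {
  # nilpotent: no indirect paths
  D <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(total_influence(D), D)
  # 1x1 geometric series 0.5/(1 - 0.5)
  expect_equal(total_influence(matrix(0.5)), matrix(1))
  # series oracle on random contractions
  for (seed in 1:3) {
    D <- random_contraction(4, rho = 0.9, seed = seed)
    T <- total_influence(D)
    expect_equal(T, neumann_total_influence(D, 500), tolerance = 1e-8)
    expect_equal(T, D + D %*% T, tolerance = 1e-10)  # T = D + DT identity
    expect_true(all(T >= 0))
  }
  expect_error(total_influence(diag(2)), class = "danpv_singular")
})

test_that("dimension-level total influence averages framework blocks", {
  fw <- criteria_framework(
    data.frame(code = c("D1", "D2"), name = "d"),
    data.frame(code = c("C11", "C12", "C21", "C22"), name = "c",
               dimension = c("D1", "D1", "D2", "D2")))
  T_C <- matrix(5, 4, 4)
  expect_true(all(dimension_total_influence(T_C, fw) == 5))
  T_C[1:2, 3:4] <- matrix(c(1, 3, 5, 7), 2, 2, byrow = TRUE)
  expect_equal(dimension_total_influence(T_C, fw)["D1", "D2"], 4)
  # size-1 blocks: T_D coincides with T_C
  fw1 <- criteria_framework(
    data.frame(code = c("D1", "D2"), name = "d"),
    data.frame(code = c("C1", "C2"), name = "c", dimension = c("D1", "D2")))
  M <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(unname(dimension_total_influence(M, fw1)), M)
  # commutes with scaling
  expect_equal(dimension_total_influence(3 * T_C, fw),
               3 * dimension_total_influence(T_C, fw))
})

test_that("causal profiles obey the conservation identities", {
  T <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  p <- causal_profile(T)
  expect_equal(p$relation, c(1, -1))
  set.seed(3)
  T <- matrix(runif(25), 5, 5)
  p <- causal_profile(T)
  expect_equal(sum(p$prominence), 2 * sum(T))
  expect_equal(sum(p$relation), 0, tolerance = 1e-12)
  expect_equal(causal_profile(T + t(T))$relation, rep(0, 5), tolerance = 1e-12)
})

test_that("influence priority orders by net relation with stable tie-breaks", {
  p <- data.frame(code = c("Da", "Db"), r = c(1, 0), c = c(0.6, 0.4),
                  prominence = c(1.6, 0.4), relation = c(0.4, -0.4))
  expect_equal(dimension_priority(p), c("Da", "Db"))
  # all ties: input (framework) order preserved
  p$relation <- 0; p$prominence <- 1
  expect_equal(dimension_priority(p), c("Da", "Db"))
})

test_that("a structured panel reproduces the published dimension priority", {
  fw <- case_framework()
  # outgoing strength graded to induce net influence D2 > D3 > D5 > D1 > D4 > D6
  out <- c(D1 = 2.2, D2 = 3.8, D3 = 3.4, D4 = 1.8, D5 = 2.9, D6 = 1.0)
  receive <- c(D1 = 2.2, D2 = 0.6, D3 = 1.0, D4 = 2.6, D5 = 1.5, D6 = 3.6)
  base <- dematel_structure(fw, out = out, receive = receive)
  dm <- dematel(list(base), fw)
  expect_equal(dimension_priority(dm$profile_D),
               c("D2", "D3", "D5", "D1", "D4", "D6"))
  # sum oracle: relation really is rowSums - colSums of T_D
  expect_equal(dm$profile_D$relation,
               unname(rowSums(dm$T_D) - colSums(dm$T_D)))
})

test_that("INRM edges follow the inclusive off-diagonal-mean threshold", {
  fw1 <- criteria_framework(
    data.frame(code = c("D1", "D2"), name = "d"),
    data.frame(code = c("C1", "C2"), name = "c", dimension = c("D1", "D2")))
  # single dominant direct link C1 -> C2 (hence D1 -> D2)
  A <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)
  dm <- dematel(list(A), fw1)
  inrm <- build_inrm(dm)
  expect_equal(nrow(inrm$edges_D), 1)
  expect_equal(inrm$edges_D$from, "D1")
  expect_equal(inrm$edges_D$to, "D2")

  # constant off-diagonal total influence: every entry equals the mean,
  # and the inclusive rule keeps the complete digraph
  S <- matrix(2, 3, 3); diag(S) <- 0
  dimnames(S) <- list(paste0("C", 1:3), paste0("C", 1:3))
  dm_const <- structure(list(T_C = S, T_D = S, profile_C = causal_profile(S),
                             profile_D = causal_profile(S)),
                        class = "dematel")
  inrm <- build_inrm(dm_const)
  expect_equal(nrow(inrm$edges_C), 6)  # complete digraph on 3 nodes

  # receiver-dominant dimension gets in-edges from all five others
  fw <- case_framework()
  receive <- c(D1 = 1.4, D2 = 1.4, D3 = 1.4, D4 = 1.4, D5 = 1.4, D6 = 4)
  dm <- dematel(list(dematel_structure(fw, receive = receive)), fw)
  inrm <- build_inrm(dm)
  into_d6 <- inrm$edges_D$from[inrm$edges_D$to == "D6"]
  expect_setequal(into_d6, c("D1", "D2", "D3", "D4", "D5"))
})

test_that("test-retest consistency reports total and mean absolute difference", {
  M <- matrix(runif(16), 4, 4)
  r <- retest_consistency(M, M)
  expect_equal(r$total_abs_diff, 0)
  expect_equal(r$mean_abs_diff, 0)

  M2 <- matrix(0, 2, 2); M2[1, 2] <- 1
  r <- retest_consistency(matrix(0, 2, 2), M2)
  expect_equal(r$total_abs_diff, 1)
  expect_equal(r$mean_abs_diff, 0.25)

  # a 16x16 pair engineered to the published total difference
  A <- matrix(0, 16, 16)
  B <- A; B[1, ] <- 4.791 / 16
  r <- retest_consistency(A, B)
  expect_equal(r$n_pairs, 256)
  expect_equal(r$total_abs_diff, 4.791)
  expect_equal(r$mean_abs_diff, 4.791 / 256)
  expect_lt(r$mean_abs_diff, 0.019)
  expect_error(retest_consistency(A, matrix(0, 2, 2)),
               class = "danpv_shape_error")
})
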