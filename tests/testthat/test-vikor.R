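test_that("criterion performance is the panel mean, item-wise over missing", {
  fw <- criteria_framework(
    data.frame(code = "D1", name = "d"),
    data.frame(code = c("C1", "C2"), name = "c", dimension = "D1"))
  survey <- data.frame(
    respondent_id = rep(c("r1", "r2", "r3"), each = 2),
    criterion_code = rep(c("C1", "C2"), 3),
    rating = c(8, 5, 8, NA, 8, 7))
  m <- mean_performance(survey, fw)
  expect_equal(m[["C1"]], 8)
  expect_equal(m[["C2"]], 6)
  expect_equal(mean_performance(survey[survey$respondent_id == "r1", ], fw),
               c(C1 = 8, C2 = 5))
  empty <- survey; empty$rating[empty$criterion_code == "C2"] <- NA
  expect_error(mean_performance(empty, fw), class = "danpv_empty_panel")
})

test_that("respondents exceeding the missing-item tolerance are dropped whole", {
  fw <- case_framework()
  survey <- gen_satisfaction_survey(fw, 20, seed = 4, missing_rate = 0.1)
  val <- validate_survey_panel(survey, fw, max_missing = 0)
  expect_true(length(val$rejected) > 0)
  expect_true(all(!is.na(val$valid$rating)))
  # permissive tolerance keeps everyone
  val2 <- validate_survey_panel(survey, fw, max_missing = 0.9)
  expect_length(val2$rejected, 0)
})

test_that("the aspiration gap is the normalized shortfall from 10", {
  expect_equal(round_half_up(gap_ratio(8.036), 3), 0.196)
  expect_equal(gap_ratio(10), 0)
  expect_equal(gap_ratio(0), 1)
  expect_error(gap_ratio(11), class = "danpv_scale_error")
  # affine and strictly decreasing
  p <- seq(0, 10, by = 0.5)
  g <- gap_ratio(p)
  expect_true(all(diff(g) < 0))
  expect_equal(g, 1 - p / 10)
})

test_that("panel integration is the size-weighted mean and convex", {
  expect_equal(round_half_up(integrate_panels(7.157, 140, 8.000, 10), 3), 7.213)
  expect_equal(round_half_up(integrate_panels(2.793, 140, 3.900, 10), 3), 2.867)
  expect_equal(integrate_panels(5.5, 17, 5.5, 3), 5.5)
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    n1 <- sample(1:200, 1); n2 <- sample(1:200, 1)
    v <- integrate_panels(a, n1, b, n2)
    expect_gte(v, min(a, b)); expect_lte(v, max(a, b))
  }
})

test_that("dimension and total aggregation use local and global weights", {
  fx <- case_fixture()
  dp <- dimension_performance(fx$resident_means, fx$weights, fx$framework)
  expect_equal(round_half_up(dp[["D1"]], 3), 6.240)  # 0.436*7.157 + ...
  tp <- total_performance(fx$resident_means, fx$weights, fx$framework)
  expect_equal(sum(fx$weights$global), 1)

  # printed-precision global weights reproduce the printed panel totals
  expect_equal(sum(fx$printed_global * fx$resident_means), 4.942,
               tolerance = 0.005 / 4.942)
  expect_equal(sum(fx$printed_global * fx$expert_means), 6.534,
               tolerance = 0.01 / 6.534)

  fw1 <- criteria_framework(
    data.frame(code = "D1", name = "d"),
    data.frame(code = c("C1", "C2"), name = "c", dimension = "D1"))
  ws <- weight_set(global = c(C1 = 0.5, C2 = 0.5), framework = fw1)
  expect_equal(dimension_performance(c(C1 = 4, C2 = 6), ws, fw1)[["D1"]], 5)
  ws3 <- weight_set(global = c(C1 = 1/3, C2 = 1/3, C3 = 1/3),
                    framework = criteria_framework(
                      data.frame(code = "D1", name = "d"),
                      data.frame(code = c("C1", "C2", "C3"), name = "c",
                                 dimension = "D1")))
  expect_equal(total_performance(c(C1 = 2, C2 = 4, C3 = 6), ws3,
                                 criteria_framework(
                                   data.frame(code = "D1", name = "d"),
                                   data.frame(code = c("C1", "C2", "C3"),
                                              name = "c", dimension = "D1"))),
               4)
})

test_that("the case report reproduces every printed gap to 0.001", {
  rep <- case_report()
  printed <- case_printed_gaps()
  g <- setNames(rep$criteria$gap_integrated, rep$criteria$code)
  expect_equal(round_half_up(g, 3), round_half_up(printed$integrated, 3),
               tolerance = 0.001)
  gr <- setNames(rep$criteria$gap_resident, rep$criteria$code)
  ge <- setNames(rep$criteria$gap_expert, rep$criteria$code)
  expect_equal(unname(abs(gr - printed$resident[names(gr)])) < 0.001,
               rep(TRUE, 16))
  expect_equal(unname(abs(ge - printed$expert[names(ge)])) < 0.001,
               rep(TRUE, 16))
  gd <- setNames(rep$dimensions$gap_integrated, rep$dimensions$code)
  expect_equal(unname(abs(gd - printed$dim_integrated[names(gd)])) < 0.001,
               rep(TRUE, 6))
  expect_equal(rep$total$gap_integrated, 0.495, tolerance = 0.001)
  # structure: 16 criterion rows, 6 dimension rows, one total row
  expect_equal(nrow(rep$criteria), 16)
  expect_equal(nrow(rep$dimensions), 6)
  expect_equal(nrow(rep$total), 1)
})

test_that("aspiration-level ratings yield zero gaps everywhere", {
  fx <- case_fixture()
  ten <- setNames(rep(10, 16), fx$framework$criteria$code)
  rep <- vikor_report(fx$weights, ten, ten, 140, 10, fx$framework)
  expect_true(all(rep$criteria$gap_resident == 0))
  expect_true(all(rep$dimensions$gap_integrated == 0))
  expect_equal(rep$total$gap_integrated, 0)
})

test_that("gap of the aggregate equals the aggregate of gaps", {
  # gap is affine, so weighted aggregation commutes with it exactly
  fx <- case_fixture()
  rep <- vikor_report(fx$weights, fx$resident_means, fx$expert_means,
                      140, 10, fx$framework)
  for (d in fx$framework$dimensions$code) {
    i <- rep$criteria$dimension == d
    w <- rep$criteria$local_weight[i]
    expect_equal(sum(w * rep$criteria$gap_resident[i]),
                 rep$dimensions$gap_resident[rep$dimensions$code == d],
                 tolerance = 1e-12)
  }
  expect_equal(sum(rep$criteria$global_weight * rep$criteria$gap_resident),
               rep$total$gap_resident, tolerance = 1e-12)
})

test_that("priority ranking sorts by integrated gap with weight tie-breaks", {
  rep <- case_report()
  expect_equal(utils::head(priority_ranking(rep), 3), c("C54", "C63", "C51"))

  fx <- case_fixture()
  flat <- setNames(rep(5, 16), fx$framework$criteria$code)
  r2 <- vikor_report(fx$weights, flat, flat, 140, 10, fx$framework)
  pr <- priority_ranking(r2)  # all gaps equal: order by global weight
  gw <- sort(fx$weights$global, decreasing = TRUE)
  expect_equal(unname(fx$weights$global[pr]), unname(gw))

  fw1 <- criteria_framework(
    data.frame(code = "D1", name = "d"),
    data.frame(code = c("C1", "C2"), name = "c", dimension = "D1"))
  ws <- weight_set(global = c(C1 = 0.5, C2 = 0.5), framework = fw1)
  r3 <- vikor_report(ws, c(C1 = 8, C2 = 2), c(C1 = 8, C2 = 2), 5, 5, fw1)
  expect_equal(priority_ranking(r3), c("C2", "C1"))
})

test_that("the sample-adequacy margin follows the normal approximation", {
  m <- sample_margin_of_error(140, 0.5, 0.95)
  expect_equal(round(100 * m$margin_of_error, 2), 8.28)
  expect_equal(sample_margin_of_error(100, 0.5, 0.95)$margin_of_error, 0.098,
               tolerance = 1e-3)
  ns <- c(50, 100, 200, 400, 1000)
  ms <- vapply(ns, function(n) sample_margin_of_error(n)$margin_of_error,
               numeric(1))
  expect_true(all(diff(ms) < 0))
})
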