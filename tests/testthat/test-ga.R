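test_that("initial populations respect ranges, seeds and log-uniformity", {
  pop <- init_population(ga_config(pop_size = 20, seed = 4))
  expect_length(pop, 20)
  for (ch in pop) {
    expect_true(ch$kernel %in% c("linear", "rbf", "poly"))
    expect_true(ch$C >= 0.1 && ch$C <= 1000)
    expect_true(ch$epsilon >= 0.001 && ch$epsilon <= 1)
    expect_true(ch$gamma >= 1e-5 && ch$gamma <= 10)
    expect_true(ch$degree %in% 2:5)
  }
  expect_identical(pop, init_population(ga_config(pop_size = 20, seed = 4)))
  # log-uniform C: P(C < 10) = log(10/0.1)/log(1000/0.1) = 0.5
  big <- init_population(ga_config(pop_size = 1000, seed = 8))
  frac <- mean(vapply(big, function(ch) ch$C < 10, logical(1)))
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("fitness is a seeded 5-fold CV MSE bounded by the tube on an exact copy", {
  x <- matrix(seq(-2, 2, length.out = 50), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- x[, 1]  # target is an exact copy of the predictor
  cfg <- svr_config("linear", C = 500, epsilon = 0.001)
  f1 <- ga_fitness(cfg, x, y, k = 5, fold_seed = 3)
  f2 <- ga_fitness(cfg, x, y, k = 5, fold_seed = 3)
  expect_identical(f1, f2)
  # residuals live inside the (standardized) insensitive tube
  expect_lte(f1, (0.001 * sd(y))^2 + 0.01)
})

test_that("tournaments of size 2 always return the better of the drawn pair", {
  pop <- init_population(ga_config(pop_size = 4, seed = 1))[1:2]
  fit <- c(0.5, 0.2)
  set.seed(10)
  winners <- replicate(50, tournament_select(pop, fit, 2))
  expect_true(all(winners == 2))
  # worst of three can never win a distinct-pair tournament
  pop3 <- init_population(ga_config(pop_size = 4, seed = 2))[1:3]
  set.seed(11)
  w3 <- replicate(1000, tournament_select(pop3, c(0.1, 0.2, 0.3), 2))
  expect_equal(sum(w3 == 3), 0)
  expect_error(tournament_select(pop, fit, 3), "smaller")
})

test_that("crossover blends within the parent hull and copies fixed points", {
  a <- svr_config("linear", C = 10, epsilon = 0.2, gamma = 0.01, degree = 2)
  b <- svr_config("rbf", C = 20, epsilon = 0.6, gamma = 0.1, degree = 3)
  set.seed(12)
  for (i in 1:25) {
    kids <- ga_crossover(a, b, prob = 1)
    for (kid in kids) {
      expect_true(kid$kernel %in% c("linear", "rbf"))
      expect_true(kid$C >= 10 && kid$C <= 20)
      expect_true(kid$epsilon >= 0.2 && kid$epsilon <= 0.6)
      expect_true(kid$degree %in% 2:3)
    }
    # the two offspring use complementary blend weights
    expect_equal(kids[[1]]$C + kids[[2]]$C, 30)
  }
  set.seed(13)
  same <- ga_crossover(a, a, prob = 1)
  expect_equal(same[[1]], a)
  expect_equal(same[[2]], a)
  # probability 0 copies the parents
  expect_identical(ga_crossover(a, b, prob = 0), list(a, b))
})

test_that("mutation respects per-gene probability and clips to ranges", {
  ch <- svr_config("rbf", C = 1000, epsilon = 1, gamma = 10, degree = 5)
  set.seed(14)
  expect_equal(ga_mutate(ch, prob = 0), ch)
  for (i in 1:300) {
    m <- ga_mutate(ch, prob = 1)
    expect_lte(m$C, 1000); expect_gte(m$C, 0.1)
    expect_lte(m$epsilon, 1); expect_gte(m$epsilon, 0.001)
    expect_lte(m$gamma, 10); expect_gte(m$gamma, 1e-5)
    expect_true(m$degree %in% 2:5)
    expect_true(m$kernel %in% c("linear", "poly"))  # re-drawn from others
  }
})

test_that("evolution is elitist-monotone and reproducible", {
  sd <- gen_numeric(synthetic_spec(n = 80, n_numeric = 4, rate = 0.15,
                                   seed = 21))
  enc <- encode_categoricals(sd$masked)$dataset
  tr <- which(!enc$mask[, "x02"])
  x <- as.matrix(enc$values[tr, c("x01", "x03", "x04")])
  x[is.na(x)] <- 0
  y <- enc$values$x02[tr]
  gacfg <- ga_config(pop_size = 8, generations = 5, patience = 3, seed = 5)
  ev1 <- suppressWarnings(evolve(x, y, gacfg))
  ev2 <- suppressWarnings(evolve(x, y, gacfg))
  expect_identical(ev1$best, ev2$best)
  expect_identical(ev1$trace, ev2$trace)
  expect_true(all(diff(ev1$trace$best) <= 0))
  expect_s3_class(ev1$best, "svr_config")
})
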