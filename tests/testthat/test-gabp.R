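toy <- make_three_blobs(n_per = 10, seed = 6)

test_that("a degenerate GA returns its sole individual unchanged", {
  spec <- network_spec(2, 2, 3)
  ctrl <- ga_control(population_size = 4, generations = 5,
                     crossover_prob = 0, mutation_prob = 0, elitism = 1)
  genes <- runif(spec$n_params, -1, 1)
  pop <- matrix(rep(genes, each = 4), nrow = 4)
  res <- ga_evolve(toy$x, toy$y, spec, ctrl, seed = 1, init_population = pop)
  expect_equal(res$best, genes, tolerance = 0)
  expect_true(all(res$trace == res$trace[1]))
})

test_that("elitism makes the best-fitness trace nondecreasing for any seed", {
  spec <- network_spec(2, 3, 3)
  ctrl <- ga_control(population_size = 10, generations = 15)
  for (seed in c(1, 7, 99)) {
    res <- ga_evolve(toy$x, toy$y, spec, ctrl, seed = seed)
    expect_true(all(diff(res$trace) >= 0))
    expect_equal(res$best_fitness, res$trace[length(res$trace)])
    expect_equal(chromosome_fitness(res$best, toy$x, toy$y, spec),
                 res$best_fitness)
  }
  # deterministic under a fixed seed
  expect_identical(ga_evolve(toy$x, toy$y, spec, ctrl, seed = 5),
                   ga_evolve(toy$x, toy$y, spec, ctrl, seed = 5))
})

test_that("evolution beats the random-search baseline on a separable task", {
  spec <- network_spec(2, 3, 3)
  res <- ga_evolve(toy$x, toy$y, spec,
                   ga_control(population_size = 20, generations = 30),
                   seed = 3)
  set.seed(33)
  baseline <- mean(replicate(1000, chromosome_fitness(
    runif(spec$n_params, -1, 1), toy$x, toy$y, spec)))
  expect_gt(res$best_fitness, baseline)
  expect_error(ga_control(gene_bounds = c(1, -1)), "low < high")
  expect_error(ga_control(population_size = 1), ">= 2")
})

test_that("backpropagation honours the epoch budget and reduces the loss", {
  spec <- network_spec(2, 4, 3)
  init <- random_params(spec, seed = 10)
  none <- train_bp(init, toy$x, toy$y, spec, bp_control(epochs = 0))
  expect_identical(none$params, init)
  expect_length(none$loss, 1)
  for (ctrl in list(bp_control(learning_rate = 0.01, epochs = 300),
                    bp_control(learning_rate = 0.01, epochs = 300,
                               adaptive = FALSE, momentum = 0))) {
    tr <- train_bp(init, toy$x, toy$y, spec, ctrl)
    expect_length(tr$loss, 301)
    expect_lte(tr$loss[301], tr$loss[1])
  }
  expect_error(bp_control(learning_rate = 0), "positive")
})

test_that("training reaches perfect accuracy on separated clusters", {
  spec <- network_spec(2, 5, 3)
  # inputs scaled to [0,1] as in the analysis pipeline
  sc <- fit_minmax(toy$x)
  xs <- scale_minmax(sc, toy$x)
  tr <- train_bp(random_params(spec, seed = 3), xs, toy$y, spec,
                 bp_control(epochs = 2000))
  expect_identical(predict_grades(tr$params, spec, xs), toy$y)
})

test_that("gabp fits, predicts, persists and reloads identically", {
  sc <- fit_minmax(toy$x)
  xs <- scale_minmax(sc, toy$x)
  fit <- gabp(xs, toy$y, n_hidden = 5,
              ga = ga_control(population_size = 10, generations = 10),
              bp = bp_control(epochs = 500), seed = 2)
  expect_s3_class(fit, "gabp")
  expect_identical(predict(fit, xs),
                   max.col(naive_forward(coef(fit), xs), ties.method = "first"))
  expect_gte(mean(predict(fit, xs) == toy$y), 0.9)
  # persistence round trip gives identical predictions
  path <- withr::local_tempfile(fileext = ".txt")
  write_gabp(fit, path)
  back <- read_gabp(path)
  expect_identical(predict(back, xs), predict(fit, xs))
  expect_equal(coef(back), coef(fit))
  # same seed, same model
  refit <- gabp(xs, toy$y, n_hidden = 5,
                ga = ga_control(population_size = 10, generations = 10),
                bp = bp_control(epochs = 500), seed = 2)
  expect_identical(predict(refit, xs), predict(fit, xs))
  # summary reports the pieces
  s <- summary(fit)
  expect_s3_class(s, "summary.gabp")
  expect_equal(s$epochs, 500L)
  expect_output(print(fit), "GA-BP")
})

test_that("GA initialisation usually trains to a lower loss than random", {
  sc <- fit_minmax(toy$x)
  xs <- scale_minmax(sc, toy$x)
  wins <- 0L
  for (seed in 1:10) {
    ga_fit <- gabp(xs, toy$y, n_hidden = 4,
                   ga = ga_control(population_size = 12, generations = 15),
                   bp = bp_control(epochs = 150), seed = seed)
    rnd_fit <- gabp(xs, toy$y, n_hidden = 4, init = "random",
                    bp = bp_control(epochs = 150), seed = seed)
    final <- function(m) m$loss[length(m$loss)]
    if (final(ga_fit) <= final(rnd_fit)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
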