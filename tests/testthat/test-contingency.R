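task1 <- binarize(pattern_fixture())[["+"]]

test_that("endpoints are midpoints of the class means", {
  expect_equal(endpoint(task1, "G1"), 75)
  expect_equal(endpoint(task1, "G2"), 75)
  expect_equal(endpoint(task1, "G9"), 41.25)  # (27.5 + 55) / 2
  expect_equal(endpoint(task1, "G3"), 7.5)
  d <- expression_dataset(cbind(g = rep(3.5, 4)), labels = c("a", "a", "b", "b"))
  expect_equal(endpoint(binary_task(d, "a"), "g"), 3.5)
})

test_that("individual tables reproduce the fixture's printed counts", {
  # patterns I-IV: positives on one side, negatives on the other (the
  # positive class is low on every pattern gene except G2 and G4)
  for (g in c("G1", "G3", "G5", "G6", "G7", "G8"))
    expect_equal(unname(individual_table(task1, g)),
                 rbind(c(0, 4), c(4, 0)), info = g)
  for (g in c("G2", "G4"))
    expect_equal(unname(individual_table(task1, g)),
                 rbind(c(4, 0), c(0, 4)), info = g)
  # patterns V and VI: balanced, individually invisible
  for (g in c("G9", "G10", "G11", "G12"))
    expect_equal(unname(individual_table(task1, g)),
                 rbind(c(2, 2), c(2, 2)), info = g)
})

test_that("values equal to the endpoint split 0.5/0.5 within their class row", {
  d <- expression_dataset(cbind(g = c(7, 7, 7, 7, 7, 7)),
                          labels = c("a", "a", "a", "a", "b", "b"))
  t <- binary_task(d, "a")
  expect_equal(unname(individual_table(t, "g", ep = 7)),
               rbind(c(2, 2), c(1, 1)))
  # single positive above, single negative below
  d2 <- expression_dataset(cbind(g = c(10, 2)), labels = c("a", "b"))
  expect_equal(unname(individual_table(binary_task(d2, "a"), "g", ep = 6)),
               rbind(c(1, 0), c(0, 1)))
})

test_that("horizontal pair tables match the fixture and split ties", {
  expect_equal(unname(horizontal_pair_table(task1, "G1", "G2")),
               rbind(c(0, 4), c(4, 0)))
  expect_equal(unname(horizontal_pair_table(task1, "G3", "G4")),
               rbind(c(0, 4), c(0, 4)))
  expect_equal(unname(horizontal_pair_table(task1, "G5", "G6")),
               rbind(c(2, 2), c(2, 2)))   # all within-sample ties
  expect_equal(unname(horizontal_pair_table(task1, "G9", "G10")),
               rbind(c(0, 4), c(4, 0)))
  expect_equal(unname(horizontal_pair_table(task1, "G11", "G12")),
               rbind(c(2, 2), c(2, 2)))
  expect_error(horizontal_pair_table(task1, "G1", "G1"), "must differ")
})

test_that("vertical pair tables match the fixture and handle double ties", {
  expect_equal(unname(vertical_pair_table(task1, "G11", "G12")),
               rbind(c(2, 0, 0, 2), c(0, 2, 2, 0)))
  # positives sit at (G1 < 75, G2 > 75), negatives at the reverse
  expect_equal(unname(vertical_pair_table(task1, "G1", "G2")),
               rbind(c(0, 0, 4, 0), c(0, 4, 0, 0)))
  expect_equal(unname(vertical_pair_table(task1, "G9", "G10")),
               rbind(c(2, 0, 0, 2), c(2, 0, 0, 2)))
  # both genes exactly at their endpoints: every cell n_class / 4
  d <- expression_dataset(matrix(4, 6, 2), labels = rep(c("a", "b"), 3))
  t <- binary_task(d, "a")
  expect_equal(unname(vertical_pair_table(t, "G1", "G2", 4, 4)),
               rbind(rep(0.75, 4), rep(0.75, 4)))
  expect_error(vertical_pair_table(task1, "G2", "G2"), "must differ")
})

test_that("tie splitting conserves mass and swapping genes permutes columns", {
  set.seed(9)
  for (rep in 1:5) {
    d <- random_dataset(n = 10, p = 4)
    d$values[sample(40, 6)] <- 100  # force some exact ties
    t <- binary_task(d, "a")
    g <- colnames(d$values)
    expect_equal(sum(individual_table(t, g[1])), 10)
    hor <- horizontal_pair_table(t, g[1], g[2])
    expect_equal(sum(hor), 10)
    expect_equal(unname(horizontal_pair_table(t, g[2], g[1])),
                 unname(hor[, c(2, 1)]))
    ver <- vertical_pair_table(t, g[1], g[2])
    expect_equal(sum(ver), 10)
    expect_equal(unname(vertical_pair_table(t, g[2], g[1])),
                 unname(ver[, c(1, 3, 2, 4)]))
  }
})

test_that("individual tables are invariant under monotone transforms", {
  set.seed(10)
  d <- random_dataset(n = 8, p = 2)
  t <- binary_task(d, "a")
  ep <- endpoint(t, "G1")
  base <- individual_table(t, "G1", ep)
  d2 <- d
  d2$values <- exp(d$values / 50)
  t2 <- binary_task(d2, "a")
  expect_equal(unname(individual_table(t2, "G1", exp(ep / 50))),
               unname(base))
})
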