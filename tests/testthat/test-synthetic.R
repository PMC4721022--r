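test_that("the built-in fixture matches its defining layout", {
  fx <- pattern_fixture()
  expect_equal(dim(fx$values), c(8L, 12L))
  expect_setequal(unique(fx$labels), c("-", "+"))
  expect_equal(unname(table(fx$labels)["+"]), 4L, ignore_attr = TRUE)
  expect_equal(unname(fx$values[, "G1"]), c(50, 50, 50, 50, 100, 100, 100, 100))
  expect_equal(unname(fx$values[, "G9"]), c(50, 5, 50, 5, 100, 10, 100, 10))
  expect_equal(unname(fx$values[, "G12"]), c(50, 100, 50, 100, 100, 50, 100, 50))
})

test_that("generation is seed-deterministic and leaves the RNG alone", {
  sp <- synthetic_spec(per_class = 6, patterns = c("I", "V"),
                       noise_genes = 5, seed = 123)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$values, d2$values)
  d3 <- generate_dataset(synthetic_spec(per_class = 6,
                                        patterns = c("I", "V"),
                                        noise_genes = 5, seed = 124))
  expect_false(identical(d1$values, d3$values))
  set.seed(99); before <- runif(1)
  set.seed(99); generate_dataset(sp); after <- runif(1)
  expect_identical(before, after)
  expect_error(generate_dataset(synthetic_spec(per_class = 0)), "at least one")
})

test_that("zero-jitter patterns reproduce the fixture's detection verdicts", {
  # per comparison: which chi-square value each pattern must produce on a
  # balanced 4+4 design (matching the printed fixture verdicts):
  #   individual: I-IV separable (4.5), V and VI all-tie (0.5)
  #   horizontal: I and V pure (4.5); II/IV one-sided (0); III/VI ties (0.5)
  #   vertical pair (zero-total columns dropped): I-IV 4.5, V 0.5, VI 8
  verdicts <- list(I   = c(4.5, 4.5, 4.5),
                   II  = c(4.5, 0.0, 4.5),
                   III = c(4.5, 0.5, 4.5),
                   IV  = c(4.5, 0.0, 4.5),
                   V   = c(0.5, 4.5, 0.5),
                   VI  = c(0.5, 0.5, 8.0))
  for (pat in names(verdicts)) {
    d <- generate_dataset(synthetic_spec(per_class = 4, patterns = pat,
                                         noise_genes = 0, jitter_sd = 0,
                                         seed = 1))
    t <- binary_task(d, "class1")
    g <- colnames(d$values)
    ind <- chi2_2x2_corrected(individual_table(t, g[1]))$statistic
    hor <- chi2_2x2_corrected(horizontal_pair_table(t, g[1], g[2]))$statistic
    ver <- chi2_collapsed(vertical_pair_table(t, g[1], g[2]))
    expect_equal(c(ind, hor, ver), verdicts[[pat]], info = pat)
    # RS view: pair evaluation sees every pattern (weakest is VI at 0.4,
    # whose horizontal table is all ties), the individual view misses V/VI
    expect_gt(rs_pair(t, g[1], g[2])$score, 0.35)
    if (pat %in% c("V", "VI"))
      expect_equal(rs_individual(t, g[1]), 0)
    else
      expect_equal(rs_individual(t, g[1]), 1)
  }
})

test_that("planted pattern I-IV genes outrank noise genes across seeds", {
  planted_irs <- noise_irs <- list()
  worst_strong <- numeric(6)
  # the six high-contrast genes (class gap far above the default jitter);
  # the low-expression partner of patterns II/IV (template 5 vs 10, within
  # one jitter sd) is legitimately harder and only checked stochastically
  strong <- c("Ia_class1", "Ib_class1", "IIb_class1", "IIIa_class1",
              "IIIb_class1", "IVb_class1")
  for (s in 1:6) {
    d <- generate_dataset(synthetic_spec(per_class = 8,
                                         patterns = c("I", "II", "III", "IV"),
                                         noise_genes = 24, seed = 200 + s))
    rk <- integrated_rank(binary_task(d, "class1"))
    noise <- grepl("^noise", rk$gene)
    planted_irs[[s]] <- rk$irs[!noise]
    noise_irs[[s]] <- rk$irs[noise]
    worst_strong[s] <- max(rk$rank[rk$gene %in% strong])
  }
  expect_true(all(worst_strong <= 8))
  # planted IRS stochastically dominates noise IRS (pooled rank-sum)
  w <- stats::wilcox.test(unlist(planted_irs), unlist(noise_irs),
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 1e-10)
})

test_that("multi-class targets plant positive templates in their own class", {
  d <- generate_dataset(synthetic_spec(classes = 3, per_class = 4,
                                       patterns = data.frame(
                                         pattern = "I", target = 2),
                                       noise_genes = 0, jitter_sd = 0,
                                       seed = 7))
  v <- d$values[, "Ia_class2"]
  expect_true(all(v[d$labels == "class2"] == 50))
  expect_true(all(v[d$labels != "class2"] == 100))
})
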