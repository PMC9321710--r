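test_that("dominates implements strict Pareto dominance", {
  dirs <- c("max", "max")
  expect_true(dominates(c(2, 2), c(1, 1), dirs))
  expect_false(dominates(c(2, 1), c(1, 2), dirs))  # incomparable
  expect_false(dominates(c(1, 1), c(1, 1), dirs))  # no strict improvement
  expect_true(dominates(c(1, 3), c(1, 2), dirs))
  expect_true(dominates(c(0, 1), c(5, 1), c("min", "max")))
})

test_that("fast_nondominated_sort agrees with the pairwise oracle", {
  set.seed(701)
  dirs <- c("max", "max")
  # degenerate layouts
  all_nd <- cbind(1:5, 5:1)
  expect_equal(fast_nondominated_sort(all_nd, dirs), list(1:5))
  chain <- cbind(c(3, 2, 1), c(3, 2, 1))
  expect_equal(fast_nondominated_sort(chain, dirs), list(1L, 2L, 3L))
  # random 20-point clouds, peeled front by front against the oracle
  for (rep in 1:10) {
    M <- matrix(stats::runif(40), 20, 2)
    fronts <- fast_nondominated_sort(M, dirs)
    expect_setequal(unlist(fronts), 1:20)
    remaining <- 1:20
    for (f in fronts) {
      expect_setequal(f, remaining[front_oracle(
        M[remaining, , drop = FALSE], dirs)])
      remaining <- setdiff(remaining, f)
    }
  }
})

test_that("mutation flips at the binomial rate and respects the cap", {
  set.seed(702)
  x <- rep(FALSE, 100)
  expect_identical(mutate_design(x, 0), x)
  y <- rep(c(TRUE, FALSE, TRUE), 1)
  expect_identical(mutate_design(y, 1), !y)

  flips <- replicate(2000, sum(xor(mutate_design(x, 0.01), x)))
  expect_equal(mean(flips), 1, tolerance = 0.1)  # E[flips] = 100 * 0.01

  # repair: never more than max_deletions survive
  z <- rep(TRUE, 30)
  for (rep in 1:50) expect_lte(sum(mutate_design(z, 0.2, 5)), 5)
})

test_that("uniform crossover mixes parents and respects closure", {
  set.seed(703)
  a <- rep(TRUE, 12); b <- rep(FALSE, 12)
  same <- crossover_designs(a, a)
  expect_identical(same[[1]], a)
  expect_identical(same[[2]], a)
  for (rep in 1:20) {
    kids <- crossover_designs(a, b)
    # complementary parents: each child bit comes from exactly one parent
    expect_identical(kids[[1]], !kids[[2]])
    # child deletions are a subset of the union of parent deletions
    pa <- sample(c(TRUE, FALSE), 12, TRUE); pb <- sample(c(TRUE, FALSE), 12, TRUE)
    kids2 <- crossover_designs(pa, pb)
    expect_true(all(which(kids2[[1]]) %in% which(pa | pb)))
  }
})

test_that("evaluate_strain enforces the feasibility contract", {
  core <- make_core_model()
  sl_pair <- c("YALI0F00101g", "YALI0F00202g")  # the two CNV1 isozymes
  cfg <- core_test_config(
    cofactor_bound_fraction = 0.10, cofactor_metabolites = "atp",
    growth_floor_fraction = 0.5,
    synthetic_lethal_pairs = list(sl_pair))

  wt <- evaluate_strain(core, strain_design(knockins = "bcar"), cfg)
  expect_true(wt$feasible)
  expect_equal(unname(wt$objectives["growth_rate"]), 10, tolerance = 1e-9)

  # essential gene: excluded before any LP runs
  ess <- evaluate_strain(core, strain_design(deletions = "YALI0A00011g",
                                             knockins = "bcar"), cfg)
  expect_false(ess$feasible)
  expect_match(ess$infeasibility, "essential")

  # synthetic-lethal pair: jointly fatal, singly allowed
  pairko <- evaluate_strain(core, strain_design(
    deletions = sl_pair, knockins = "bcar"), cfg)
  expect_false(pairko$feasible)
  expect_match(pairko$infeasibility, "synthetic-lethal")
  single <- evaluate_strain(core, strain_design(
    deletions = sl_pair[1], knockins = "bcar"), cfg)
  expect_true(single$feasible)

  # cofactor bound: gL+gE3 deletion drops uptake to 6, atp 3 vs WT 5
  cof <- evaluate_strain(core, strain_design(
    deletions = c("YALI0C00404g", "YALI0E00303g"), knockins = "bcar"), cfg)
  expect_false(cof$feasible)
  expect_match(cof$infeasibility, "cofactor")

  # growth floor: all-route knockout lands at 0 growth
  dead <- evaluate_strain(core, strain_design(
    deletions = c("YALI0F00101g", "YALI0F00202g", "YALI0E00303g",
                  "YALI0C00404g"), knockins = "bcar"), cfg)
  expect_false(dead$feasible)
})

test_that("run_moea is deterministic, constrained and matches the oracle front", {
  core <- make_core_model()
  cfg <- core_test_config()
  ar1 <- run_moea(core, cfg)
  ar2 <- run_moea(core, cfg)
  expect_equal(front_tuples(ar1), front_tuples(ar2))  # same seed, same front
  expect_identical(length(ar1$strains), length(ar2$strains))

  bf <- brute_force_front(core, cfg)
  expect_equal(front_tuples(ar1), front_tuples(bf), tolerance = 1e-9)

  # archive invariants: mutual non-domination, feasibility
  M <- archive_objectives(ar1)
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(nrow(M))) {
      if (i != j) expect_false(dominates(M[j, ], M[i, ], cfg$directions))
    }
  }
  expect_true(all(vapply(ar1$strains, `[[`, logical(1), "feasible")))

  # hypervolume log is non-decreasing
  log <- attr(ar1, "log")
  expect_true(all(diff(log$hypervolume) >= -1e-12))
})

test_that("brute_force_front counts subsets and is never dominated by the MOEA", {
  core <- make_core_model()
  cfg <- core_test_config(max_deletions = 2L)
  bf <- brute_force_front(core, cfg)
  g <- length(knockable_genes(core, cfg$essential_genes, cfg$knockins))
  expect_equal(attr(bf, "n_evaluated"), sum(choose(g, 0:2)))

  ar <- run_moea(core, core_test_config(max_deletions = 2L,
                                        population_size = 30L,
                                        generations = 15L))
  Mb <- archive_objectives(bf)
  Ma <- archive_objectives(ar)
  for (i in seq_len(nrow(Mb))) {
    for (j in seq_len(nrow(Ma))) {
      expect_false(dominates(Ma[j, ], Mb[i, ], cfg$directions))
    }
  }
})

test_that("hypervolume_2d computes exact dominated area", {
  # single point: rectangle
  expect_equal(hypervolume_2d(matrix(c(2, 3), 1, 2), c(0, 0)), 6)
  # staircase of two incomparable points
  M <- rbind(c(1, 3), c(2, 1))
  expect_equal(hypervolume_2d(M, c(0, 0)), 1 * 3 + 1 * 1)
  # dominated point adds nothing
  M2 <- rbind(M, c(1, 1))
  expect_equal(hypervolume_2d(M2, c(0, 0)), hypervolume_2d(M, c(0, 0)))
  # points below the reference are ignored
  expect_equal(hypervolume_2d(rbind(M, c(-1, -1)), c(0, 0)),
               hypervolume_2d(M, c(0, 0)))
})

test_that("chromosome co-location can serve as a third objective", {
  core <- make_core_model()
  cfg <- core_test_config(
    objectives = c("growth_rate", "product_yield", "chromosome_score"),
    population_size = 30L, generations = 15L)
  ar <- run_moea(core, cfg)
  expect_gt(length(ar$strains), 0)
  M <- archive_objectives(ar)
  expect_true(all(M[, "chromosome_score"] >= 0 & M[, "chromosome_score"] <= 1))
  # the empty design scores 1 by convention and always survives
  expect_true(any(M[, "chromosome_score"] == 1))
})
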