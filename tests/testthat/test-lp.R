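chain_model <- function(uptake = 10) {
  # uptake -> conversion -> biomass with unit stoichiometry: the optimum is
  # the uptake bound, and the optimal flux vector is unique
  stoich_model(
    metabolite_ids = c("s_e", "x"),
    reaction_ids = c("EX", "CNV", "BIO"),
    S = matrix(c(-1, -1, 0,
                 0, 1, -1), 2, 3, byrow = TRUE),
    lb = c(-uptake, 0, 0), ub = c(0, 1000, 1000), obj = c(0, 0, 1),
    biomass_reaction = "BIO", carbon_source_exchange = "EX",
    product_reaction = "BIO")
}

test_that("fba solves the closed-form chain and handles edge statuses", {
  m <- chain_model()
  f <- fba(m)
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(f$v), c(-10, 10, 10), tolerance = 1e-9)

  # no carbon: optimum 0
  m0 <- chain_model()
  m0$lb["EX"] <- 0
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-12)

  # infeasible: forced uptake but blocked conversion
  mi <- chain_model()
  mi$lb["EX"] <- -5; mi$ub["EX"] <- -5; mi$ub["CNV"] <- 1
  expect_equal(fba(mi)$status, "infeasible")

  # unbounded: free internal cycle carrying the objective
  mu <- stoich_model(
    metabolite_ids = "x", reaction_ids = c("A", "B"),
    S = matrix(c(1, -1), 1, 2), lb = c(-Inf, -Inf), ub = c(Inf, Inf),
    obj = c(1, 0), biomass_reaction = "A",
    carbon_source_exchange = "A", product_reaction = "B")
  expect_equal(fba(mu)$status, "unbounded")

  # degenerate, all-zero objective rejected
  mz <- chain_model(); mz$obj[] <- 0
  expect_error(fba(mz), "objective")
})

test_that("fba matches the vertex-enumeration oracle on random small LPs", {
  set.seed(301)
  for (rep in 1:30) {
    m <- 2L; n <- 5L
    A <- matrix(stats::rnorm(m * n), m, n)
    lb <- stats::runif(n, -5, 0); ub <- lb + stats::runif(n, 0, 10)
    obj <- stats::rnorm(n)
    got <- solve_lp(obj, A, NULL, lb, ub, maximize = TRUE)
    want <- lp_vertex_oracle(obj, A, lb, ub, maximize = TRUE)
    if (is.null(want)) {
      expect_equal(got$status, "infeasible")
    } else {
      expect_equal(got$status, "optimal")
      expect_equal(got$objective, want, tolerance = 1e-9)
    }
  }
  # and on the metabolic fixtures
  for (model in list(chain_model(), make_core_model())) {
    p <- moeko:::model_lp_parts(model)
    want <- lp_vertex_oracle(p$obj, p$A, p$lb, p$ub)
    expect_equal(fba(model)$objective_value, want, tolerance = 1e-9)
  }
})

test_that("optimal flux states conserve mass and respect bounds", {
  set.seed(302)
  core <- make_core_model()
  genes <- knockable_genes(core)
  for (rep in 1:20) {
    d <- strain_design(deletions = sample(genes, sample(0:3, 1)),
                       knockins = if (rep %% 2) "bcar" else character())
    applied <- apply_design(core, d)
    f <- fba(applied)
    expect_equal(f$status, "optimal")
    expect_lt(max(abs(applied$S %*% f$v)), 1e-6)
    expect_true(all(f$v >= applied$lb - 1e-9 & f$v <= applied$ub + 1e-9))
  }
})

test_that("fva collapses at unique optima, widens when relaxed, and is exact on rebounded reactions", {
  m <- chain_model()
  r <- fva(m, 1.0)
  # unique optimum: every range collapses to the FBA flux
  f <- fba(m)
  expect_equal(r$min, unname(f$v), tolerance = 1e-9)
  expect_equal(r$max, unname(f$v), tolerance = 1e-9)

  r90 <- fva(m, 0.9)
  expect_true(all(r90$min <= r$min + 1e-9))
  expect_true(all(r90$max >= r$max - 1e-9))

  # a clamped reaction has range (0, 0)
  mz <- make_core_model()
  mz$lb["CNV3"] <- 0; mz$ub["CNV3"] <- 0
  rz <- fva(mz, 1.0, reactions = "CNV3")
  expect_equal(c(rz$min, rz$max), c(0, 0), tolerance = 1e-12)

  expect_error(fva(m, 0), "fraction")
})

test_that("pfba zeroes the futile cycle and never increases total flux", {
  core <- make_core_model()
  f <- fba(core)
  p <- pfba(core)
  expect_equal(p$objective_value, f$objective_value, tolerance = 1e-9)
  # the B <-> Bx loop carries nothing under parsimonious fluxes
  expect_equal(unname(p$v["F1"]), 0, tolerance = 1e-9)
  expect_equal(unname(p$v["F2"]), 0, tolerance = 1e-9)
  expect_lte(sum(abs(p$v)), sum(abs(f$v)) + 1e-9)

  # unique-optimum chain: pfba flux equals fba flux
  m <- chain_model()
  expect_equal(unname(pfba(m)$v), unname(fba(m)$v), tolerance = 1e-9)
})

test_that("fva brackets pfba fluxes at fraction 1", {
  for (model in list(make_core_model(),
                     apply_design(make_core_model(),
                                  strain_design(knockins = "bcar")),
                     make_random_toy(toy_spec(rng_seed = 11)))) {
    p <- pfba(model)
    r <- fva(model, 1.0)
    expect_true(all(r$min - 1e-6 <= unname(p$v[r$reaction])),
                info = model$id)
    expect_true(all(unname(p$v[r$reaction]) <= r$max + 1e-6),
                info = model$id)
  }
})

test_that("knockout monotonicity and scale invariance hold", {
  core <- make_core_model()
  wt_opt <- fba(core)$objective_value
  genes <- knockable_genes(core)
  set.seed(303)
  for (rep in 1:40) {
    d <- strain_design(deletions = sample(genes, sample(1:4, 1)))
    expect_lte(fba(apply_design(core, d))$objective_value, wt_opt + 1e-9)
  }
  # homogeneous constraints: scaling all bounds by k scales the optimum by k
  for (k in c(0.5, 2, 7)) {
    sc <- core
    sc$lb <- core$lb * k; sc$ub <- core$ub * k
    expect_equal(fba(sc)$objective_value, k * wt_opt, tolerance = 1e-9)
  }
})
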