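test_that("yield_of reproduces printed strain arithmetic and conventions", {
  # engineered double-knockout strain: product flux over glucose uptake
  # (the printed fluxes carry fewer digits than the printed yield)
  expect_lt(abs(yield_of(0.22634, -3.631218038) - 0.062331504), 1e-6)
  expect_equal(yield_of(0, -3.6), 0)
  expect_equal(yield_of(0, 0), 0)           # zero product: yield 0 by convention
  expect_equal(yield_of(5, -5), 1)          # theoretical upper bound
  expect_equal(yield_of(2, -8, molar_mass_ratio = 2), 0.5)
  expect_error(yield_of(1, 0), "zero carbon uptake")
})

test_that("productivity_of reproduces printed yield x growth products", {
  expect_lt(abs(productivity_of(0.19708, 0.71361) - 0.14064), 1e-5)
  expect_lt(abs(productivity_of(0.20685, 0.71528) - 0.14795), 1e-5)
  expect_equal(productivity_of(0, 0.7), 0)
  # composition identity: productivity(yield(p, u), g) == p/|u| * g
  set.seed(501)
  for (rep in 1:50) {
    p <- stats::runif(1, 0, 5); u <- -stats::runif(1, 0.1, 10)
    g <- stats::runif(1, 0, 1)
    expect_equal(productivity_of(yield_of(p, u), g), p / abs(u) * g,
                 tolerance = 1e-12)
  }
})

test_that("wt_variation matches the printed WT-variation percentages", {
  expect_equal(round(wt_variation(130.8433, 62.68911709), 2), 108.72)
  expect_equal(round(wt_variation(25.6254, 11.83086467), 2), 116.60)
  expect_equal(wt_variation(3, 3), 0)
  expect_true(is.na(wt_variation(1, 0)))
  # algebraic identity wt_variation(a,b) = -wt_variation(b,a) * a/b
  set.seed(502)
  for (rep in 1:50) {
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, 0.1, 10)
    expect_equal(wt_variation(a, b), -wt_variation(b, a) * a / b,
                 tolerance = 1e-9)
  }
})

test_that("cofactor_flux_sum counts production only and matches brute force", {
  core <- make_core_model()
  zero <- structure(list(v = stats::setNames(
    numeric(length(core$reaction_ids)), core$reaction_ids)),
    class = "flux_state")
  expect_equal(cofactor_flux_sum(core, zero, "atp"), 0)

  p <- pfba(core)
  # brute-force oracle: loop over every (reaction, coefficient) pair
  brute <- function(model, v, met) {
    total <- 0
    for (j in seq_along(model$reaction_ids)) {
      coef <- model$S[met, j]
      if (coef * v[[j]] > 0) total <- total + coef * v[[j]]
    }
    total
  }
  for (met in core$metabolite_ids) {
    expect_equal(cofactor_flux_sum(core, p, met), brute(core, p$v, met))
  }
  # WT atp production: 0.5 per unit uptake, uptake 10
  expect_equal(cofactor_flux_sum(core, p, "atp"), 5, tolerance = 1e-9)
  expect_error(cofactor_flux_sum(core, p, "nadph"), "unknown metabolite")

  # invariant under flipping a reaction's direction convention
  flipped <- core
  flipped$S[, "UPT"] <- -flipped$S[, "UPT"]
  v2 <- p$v; v2["UPT"] <- -v2["UPT"]
  for (met in core$metabolite_ids) {
    expect_equal(cofactor_flux_sum(flipped, v2, met),
                 cofactor_flux_sum(core, p, met))
  }
})

test_that("strain_metrics and productivity_range fit together", {
  core <- make_core_model()
  # coupled strain: all carbon through the lossy route
  d <- strain_design(deletions = c("YALI0F00101g", "YALI0F00202g",
                                   "YALI0E00303g"), knockins = "bcar")
  sm <- strain_metrics(core, d, cofactors = "atp")
  expect_true(sm$feasible)
  expect_equal(sm$growth_rate, 5, tolerance = 1e-9)
  expect_equal(sm$product_flux, 5, tolerance = 1e-9)
  expect_equal(sm$yield, 0.5, tolerance = 1e-9)
  expect_equal(sm$productivity, 2.5, tolerance = 1e-9)
  expect_equal(sm$n_knockouts, 3L)

  # fully determined product flux: the range collides with a single value
  pr <- productivity_range(core, d)
  expect_equal(unname(pr["min"]), unname(pr["max"]), tolerance = 1e-9)
  expect_equal(unname(pr["min"]), sm$productivity, tolerance = 1e-9)

  # WT without knock-in: no product at all
  expect_equal(unname(productivity_range(core, strain_design())),
               c(0, 0), tolerance = 1e-12)

  # bracketing: min <= pointwise productivity <= max for sampled strains
  set.seed(503)
  genes <- knockable_genes(core, core_essential_genes())
  for (rep in 1:10) {
    d <- strain_design(deletions = sample(genes, sample(0:3, 1)),
                       knockins = "bcar")
    sm <- strain_metrics(core, d)
    if (!sm$feasible) next
    pr <- productivity_range(core, d)
    expect_gte(sm$productivity, unname(pr["min"]) - 1e-6)
    expect_lte(sm$productivity, unname(pr["max"]) + 1e-6)
  }
})
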