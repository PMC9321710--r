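minimal_model <- function() {
  # smallest valid network: one metabolite, two reactions (in/out)
  stoich_model(
    metabolite_ids = "m", reaction_ids = c("EX_in", "SINK"),
    S = matrix(c(-1, -1), 1, 2), lb = c(-5, 0), ub = c(0, 10),
    obj = c(0, 1),
    biomass_reaction = "SINK", carbon_source_exchange = "EX_in",
    product_reaction = "SINK")
}

test_that("stoich_model validates its invariants", {
  m <- minimal_model()
  expect_s3_class(m, "stoich_model")
  expect_equal(dim(m$S), c(1L, 2L))

  # m >= n rejected
  expect_error(
    stoich_model(c("a", "b"), c("r1", "r2"), diag(2), c(0, 0), c(1, 1),
                 c(1, 0), biomass_reaction = "r1",
                 carbon_source_exchange = "r1", product_reaction = "r2"),
    "m < n")
  # lb > ub rejected
  expect_error(
    stoich_model("m", c("r1", "r2"), matrix(c(-1, 1), 1, 2),
                 c(2, 0), c(1, 1), c(1, 0), biomass_reaction = "r1",
                 carbon_source_exchange = "r1", product_reaction = "r2"),
    "lb > ub")
  # designated reaction must exist
  expect_error(
    stoich_model("m", c("r1", "r2"), matrix(c(-1, 1), 1, 2),
                 c(0, 0), c(1, 1), c(1, 0), biomass_reaction = "nope",
                 carbon_source_exchange = "r1", product_reaction = "r2"),
    "biomass_reaction")
  # GPR gene must be declared
  expect_error(
    stoich_model("m", c("r1", "r2"), matrix(c(-1, 1), 1, 2),
                 c(0, 0), c(1, 1), c(1, 0), genes = "g1",
                 gpr = list(r1 = parse_gpr("gX")),
                 biomass_reaction = "r1", carbon_source_exchange = "r1",
                 product_reaction = "r2"),
    "gX")
})

test_that("apply_design zeroes exactly the reactions whose rules go inactive", {
  core <- make_core_model()

  # identity: empty design leaves bounds untouched
  same <- apply_design(core, strain_design())
  expect_identical(same$lb, core$lb)
  expect_identical(same$ub, core$ub)

  # single-gene reaction dies with its gene
  ko <- apply_design(core, strain_design(deletions = "YALI0E00303g"))
  expect_equal(unname(ko$lb["CNV3"]), 0)
  expect_equal(unname(ko$ub["CNV3"]), 0)
  expect_equal(unname(ko$ub["CNV1"]), unname(core$ub["CNV1"]))

  # one isozyme of an OR rule is not enough to kill the reaction
  iso <- apply_design(core, strain_design(deletions = "YALI0F00101g"))
  expect_equal(unname(iso$ub["CNV1"]), unname(core$ub["CNV1"]))
  both <- apply_design(core, strain_design(
    deletions = c("YALI0F00101g", "YALI0F00202g")))
  expect_equal(unname(both$ub["CNV1"]), 0)

  # one subunit of an AND rule kills the reaction
  sub <- apply_design(core, strain_design(deletions = "YALI0A00011g"))
  expect_equal(unname(sub$ub["UPT"]), 0)

  # the original model is untouched (immutability)
  expect_equal(unname(core$ub["CNV3"]), 4)

  expect_error(apply_design(core, strain_design(deletions = "not_a_gene")),
               "unknown gene")
})

test_that("apply_design is monotone and idempotent", {
  core <- make_core_model()
  set.seed(17)
  genes <- knockable_genes(core)
  for (rep in 1:25) {
    d1 <- sample(genes, sample(0:3, 1))
    extra <- sample(setdiff(genes, d1), 1)
    a <- apply_design(core, strain_design(deletions = d1))
    b <- apply_design(core, strain_design(deletions = c(d1, extra)))
    zeroed_a <- a$lb == 0 & a$ub == 0
    zeroed_b <- b$lb == 0 & b$ub == 0
    expect_true(all(zeroed_b[zeroed_a]))  # never re-enables a reaction

    twice <- apply_design(a, strain_design(deletions = d1))
    expect_identical(twice$lb, a$lb)
    expect_identical(twice$ub, a$ub)
  }
})

test_that("add_pathway bookkeeping: dimensions, idempotence, conflicts", {
  core <- make_core_model()
  bcar <- core$pathways$bcar
  m2 <- add_pathway(core, bcar)
  expect_equal(length(m2$reaction_ids), length(core$reaction_ids) + 3L)
  expect_equal(length(m2$metabolite_ids), length(core$metabolite_ids) + 2L)
  expect_setequal(setdiff(m2$genes, core$genes), c("GGS1", "carRP", "carB"))

  # idempotent on the same pathway id
  m3 <- add_pathway(m2, bcar)
  expect_identical(m3$reaction_ids, m2$reaction_ids)

  # conflicting stoichiometry under an existing reaction id
  clash <- pathway_definition("clash", list(
    list(id = "CNV1", stoichiometry = c(A = -1, C = 1), lb = 0, ub = 10)))
  expect_error(add_pathway(core, clash), "different stoichiometry")

  # unknown metabolite in stoichiometry
  bad <- pathway_definition("bad", list(
    list(id = "RX", stoichiometry = c(nope = -1), lb = 0, ub = 1)))
  expect_error(add_pathway(core, bad), "unknown metabolite")
})

test_that("product is only reachable through the knock-in pathway", {
  core <- make_core_model()
  expect_equal(unname(fba(core)$v["EX_prd"]), 0)

  # knocked-in and forced through the lossy route: product flows
  d <- strain_design(deletions = c("YALI0F00101g", "YALI0F00202g",
                                   "YALI0E00303g"), knockins = "bcar")
  v <- fba(apply_design(core, d))$v
  expect_gt(unname(v["EX_prd"]), 0)
})
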