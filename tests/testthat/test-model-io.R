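test_that("GPR parsing honors parentheses and and/or precedence", {
  g <- parse_gpr("(g1 and g2) or g3")
  expect_equal(g$op, "or")
  expect_length(g$children, 2)
  expect_equal(g$children[[1]]$op, "and")
  expect_equal(gpr_genes(g), c("g1", "g2", "g3"))
  # without parentheses AND binds tighter than OR
  g2 <- parse_gpr("g1 and g2 or g3")
  expect_equal(gpr_to_string(g2), gpr_to_string(g))
  # synonyms and empty input
  expect_equal(gpr_to_string(parse_gpr("a && b || c")),
               gpr_to_string(parse_gpr("a and b or c")))
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NULL))
  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("(g1 or g2"), "parse error")
})

test_that("parsed GPR trees agree with an independent generator on random rules", {
  set.seed(11)
  genes <- paste0("y", 1:8)
  for (i in 1:50) {
    ref <- random_gpr_tree(genes, depth = 3)
    tree <- parse_gpr(ref$string)
    lev <- setNames(runif(length(genes), 0, 10), genes)
    got <- reaction_raw_expression(tree, lev)
    expect_equal(got$value, eval_gpr_ref(ref, lev), tolerance = 1e-12)
    # round-trip: normalized string parses to an equivalent tree
    expect_equal(
      reaction_raw_expression(parse_gpr(gpr_to_string(tree)), lev)$value,
      got$value)
  }
})

toy_sbml <- function() {
  path <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb0" value="0" constant="true"/>
      <parameter id="ub1000" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_g1"/>
              <fbc:geneProductRef fbc:geneProduct="G_g2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}

test_that("SBML and JSON dialects load to the same canonical network", {
  net <- read_model(toy_sbml())
  expect_equal(nrow(net$S), 2)
  expect_equal(ncol(net$S), 3)
  expect_equal(unname(net$S[, "R2"]), c(-1, 1))
  expect_equal(gpr_to_string(net$gpr$R2),
               gpr_to_string(parse_gpr("(g1 and g2) or g3")))
  expect_equal(net$gpr$R2$op, "or")
  expect_equal(net$gpr$R2$children[[1]]$op, "and")
  expect_equal(unname(net$ub), rep(1000, 3))

  jpath <- tempfile(fileext = ".json")
  write_model(net, jpath)
  net2 <- read_model(jpath)
  expect_equal(net2$S, net$S)
  expect_equal(net2$lb, net$lb)
  expect_equal(net2$ub, net$ub)
  expect_equal(vapply(net2$gpr, gpr_to_string, ""),
               vapply(net$gpr, gpr_to_string, ""))
  # idempotence of write/read on canonical fields
  jpath2 <- tempfile(fileext = ".json")
  write_model(net2, jpath2)
  expect_equal(read_model(jpath2)$S, net$S)
})

test_that("model validation rejects malformed input by name", {
  mets <- data.frame(id = c("A", "B"), compartment = "c")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(Z = 1), lb = 0, ub = 10))),
    "undeclared metabolite")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = 1), lb = 5, ub = 1))),
    "lb > ub")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = 1), lb = 0, ub = 1),
    list(id = "R1", stoich = c(B = 1), lb = 0, ub = 1))),
    "duplicate reaction")
  expect_warning(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = 1), lb = 0, ub = 1, gpr = "g1 and (or)"))),
    "unparseable GPR")
})

test_that("splitting reversible reactions mirrors stoichiometry and counts", {
  net <- chain3()
  net$lb["R2"] <- -1000   # make R2 reversible
  dnet <- split_reversible(net)
  expect_equal(ncol(dnet$S), 4)  # 2 irreversible + 2 for the reversible one
  expect_equal(unname(dnet$S[, "R2_r"]), unname(-dnet$S[, "R2_f"]))
  expect_true(all(dnet$ub >= 0))
  expect_equal(unname(dnet$ub["R2_r"]), 1000)
  # all-irreversible network maps to identity
  dnet0 <- split_reversible(chain3())
  expect_equal(ncol(dnet0$S), 3)
  expect_equal(unname(dnet0$base_id), colnames(chain3()$S))
  # lb < 0 with ub <= 0 flips to a forward-running reverse copy
  netr <- chain3()
  netr$lb["R2"] <- -500; netr$ub["R2"] <- 0
  dr <- split_reversible(netr)
  expect_true("R2_r" %in% colnames(dr$S))
  expect_false("R2_f" %in% colnames(dr$S))
  expect_equal(unname(dr$ub["R2_r"]), 500)
})

test_that("directed columns reproduce the original mass balance on random networks", {
  set.seed(21)
  for (rep in 1:10) {
    n_met <- 8
    mets <- data.frame(id = paste0("M", 1:n_met), compartment = "c")
    rxns <- lapply(1:20, function(i) {
      sub <- sample(n_met, 1); pro <- sample(setdiff(1:n_met, sub), 1)
      rev <- runif(1) < 0.4
      list(id = paste0("R", i),
           stoich = setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                             paste0("M", c(sub, pro))),
           lb = if (rev) -1000 else 0, ub = 1000)
    })
    net <- metabolic_network(mets, rxns)
    dnet <- split_reversible(net)
    expect_equal(ncol(dnet$S),
                 sum(!is_reversible(net)) + 2 * sum(is_reversible(net)))
    for (j in colnames(dnet$S)) {
      orig <- net$S[, dnet$base_id[[j]]]
      expect_equal(unname(dnet$S[, j]),
                   unname(if (dnet$direction[[j]] == "f") orig else -orig))
    }
    # a random feasible directed flux merges to a feasible original flux
    obj <- runif(ncol(dnet$S))
    sol <- efpa:::solve_flux_lp(obj, dnet$S, pmin(dnet$ub, 10))
    expect_equal(sol$status, "optimal")
    v <- sol$solution
    merged <- vapply(colnames(net$S), function(r) {
      f <- if (paste0(r, "_f") %in% names(v)) v[[paste0(r, "_f")]] else 0
      b <- if (paste0(r, "_r") %in% names(v)) v[[paste0(r, "_r")]] else 0
      f - b
    }, numeric(1))
    expect_true(all(abs(net$S %*% merged) < 1e-8))
    expect_true(all(merged >= net$lb - 1e-8 & merged <= net$ub + 1e-8))
  }
})

test_that("model summary reports formulas, reversibility and GPR strings", {
  net <- chain3()
  net$lb["R2"] <- -1000
  s <- model_summary(net)
  expect_equal(s$reaction, c("R1", "R2", "R3"))
  expect_true(grepl("<=>", s$formula[2]))
  expect_true(grepl("-->", s$formula[1]))
  expect_equal(s$gpr, c("g1", "g2", "g3"))
  path <- tempfile(fileext = ".tsv")
  write_model_summary(net, path)
  expect_equal(read.delim(path)$reaction, s$reaction)
})
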