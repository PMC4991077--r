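test_that("registry defines exactly 41 descriptors per ion", {
  reg <- constitutionalRegistry()
  expect_length(reg, 41L)
  expect_false(anyDuplicated(reg) > 0)
  # every descriptor named in the map interpretation is present
  expect_true(all(c("Se", "Sp", "Si", "nAT", "nBT", "RBN", "RBF", "nH", "nC",
                    "nCsp3", "MW", "H%", "nSK", "nBO", "SCBO", "nDB", "nO",
                    "nS", "nF", "nHet") %in% reg))
})

test_that("element counts match hand tallies", {
  v <- elementCounts(parseSmiles("[Cl-]"))
  expect_equal(unname(v[c("nAT", "nSK", "nH", "nX", "nHet", "H%")]),
               c(1, 1, 0, 1, 1, 0))
  v <- elementCounts(parseSmiles("C[N+](C)(C)C"))
  expect_equal(unname(v[c("nAT", "nSK", "nH", "nC", "nN", "nHet")]),
               c(17, 5, 12, 4, 1, 1))
  expect_equal(unname(v["H%"]), 100 * 12 / 17)
  v <- elementCounts(parseSmiles("c1ccccc1"))
  expect_equal(unname(v[c("nAT", "nC", "nH", "nHet")]), c(12, 6, 6, 0))
})

test_that("bond block matches hand tallies including the rotatable-bond rule", {
  v <- bondBlock(parseSmiles("C[N+](C)(C)C"))
  expect_equal(unname(v[c("nBT", "nBO", "SCBO", "RBN", "RBF")]),
               c(16, 4, 4, 0, 0))
  v <- bondBlock(parseSmiles("[Cl-]"))
  expect_equal(unname(v[c("nBT", "nBO", "SCBO", "ARR", "RBF")]),
               c(0, 0, 0, 0, 0))
  # butyl chain on trimethylammonium: two interior C-C bonds + the N-C bond
  v <- bondBlock(parseSmiles("CCCC[N+](C)(C)C"))
  expect_equal(unname(v["RBN"]), 3)
})

test_that("weighted sums follow the shipped element table", {
  tab <- elementTable()
  v <- weightedSums(parseSmiles("[Cl-]"))
  expect_equal(unname(v["MW"]), tab["Cl", "mass"])
  expect_equal(unname(v["Se"]), tab["Cl", "en"] / tab["C", "en"])
  v <- weightedSums(parseSmiles("C[N+](C)(C)C"))
  expect_equal(unname(v["MW"]),
               4 * tab["C", "mass"] + 12 * tab["H", "mass"] + tab["N", "mass"])
  expect_equal(unname(v["MW"]), 74.147, tolerance = 1e-3)
  # mean * count identity
  expect_equal(unname(v["Me"] * 17), unname(v["Se"]), tolerance = 1e-12)
})

test_that("carbon hybridization follows the bond-pattern rule", {
  expect_equal(unname(hybridizationCounts(parseSmiles("C[N+](C)(C)C"))),
               c(4, 0, 0))
  expect_equal(unname(hybridizationCounts(parseSmiles("c1ccccc1"))["nCsp2"]), 6)
  v <- hybridizationCounts(parseSmiles("CCC#N"))
  expect_equal(unname(v), c(2, 0, 1))
})

test_that("the full vector agrees with a naive enumeration oracle on >= 20 ions", {
  lib <- ion_library()
  expect_gte(length(lib), 20L)
  for (nm in names(lib)) {
    g <- parseSmiles(lib[[nm]])
    v <- constitutionalVector(g)
    expect_length(v, 41L)
    expect_true(all(is.finite(v)), label = nm)
    o <- oracle_constitutional(g)
    expect_equal(v[names(o)], o, tolerance = 1e-12,
                 label = paste("oracle match for", nm),
                 ignore_attr = TRUE)
  }
})

test_that("carbon-free ions zero every carbon-related slot", {
  v <- constitutionalVector(parseSmiles("[Cl-]"))
  expect_equal(unname(v[c("nC", "C%", "nCsp3", "nCsp2", "nCsp", "ARR")]),
               rep(0, 6))
})

test_that("count identities hold on generated ions (property test)", {
  set.seed(42)
  lib <- unname(ion_library())
  for (rep_i in 1:30) {
    smi <- sample(lib, 1)
    v <- constitutionalVector(parseSmiles(smi))
    expect_equal(unname(v["nAT"]), unname(v["nSK"] + v["nH"]), label = smi)
    expect_equal(unname(v["nBT"]), unname(v["nBO"] + v["nH"]), label = smi)
    expect_equal(unname(v["nBM"]), unname(v["nDB"] + v["nTB"] + v["nAB"]))
    expect_gte(unname(v["SCBO"]), unname(v["nBO"]))
    expect_lte(unname(v["nCsp3"] + v["nCsp2"] + v["nCsp"]), unname(v["nC"]))
    expect_equal(unname(v["H%"]), unname(100 * v["nH"] / v["nAT"]))
    expect_equal(unname(v["X%"]), unname(100 * v["nX"] / v["nAT"]))
    expect_equal(unname(v["AMW"]), unname(v["MW"] / v["nAT"]))
    expect_equal(unname(v["Me"]), unname(v["Se"] / v["nAT"]))
    expect_true(v["RBF"] >= 0 && v["RBF"] <= 1)
    expect_true(v["ARR"] >= 0 && v["ARR"] <= 1)
    counts <- v[c("nAT", "nSK", "nBT", "nBO", "nDB", "nTB", "nAB", "nH",
                  "nC", "nN", "nO", "nP", "nS", "nF", "nCl", "nBr", "nI",
                  "nX", "nHet", "nCsp3", "nCsp2", "nCsp", "RBN")]
    expect_true(all(counts >= 0) && all(counts == floor(counts)), label = smi)
  }
})

test_that("appending CH2 to an alkyl chain moves the homologous descriptors", {
  for (k in 1:6) {
    a <- constitutionalVector(parseSmiles(paste0(strrep("C", k), "[N+](C)(C)C")))
    b <- constitutionalVector(parseSmiles(paste0(strrep("C", k + 1), "[N+](C)(C)C")))
    for (d in c("MW", "nAT", "nC", "nH", "nCsp3")) {
      expect_gt(b[[d]], a[[d]], label = paste(d, "at chain", k))
    }
    expect_gte(b[["RBN"]], a[["RBN"]])
  }
})

test_that("the 82-slot IL vector concatenates cation then anion blocks", {
  vc <- constitutionalVector(parseSmiles("C[N+](C)(C)C"))
  va <- constitutionalVector(parseSmiles("[Cl-]"))
  v <- ilVector(vc, va, "tma_cl")
  expect_length(v, 82L)
  expect_identical(attr(v, "il_id"), "tma_cl")
  expect_equal(unname(v[paste0(constitutionalRegistry(), "^C")]), unname(vc),
               ignore_attr = TRUE)
  expect_equal(unname(v[paste0(constitutionalRegistry(), "^A")]), unname(va),
               ignore_attr = TRUE)
  # swapping the ions gives a different vector for different ions
  v_sw <- ilVector(va, vc, "swapped")
  expect_false(isTRUE(all.equal(unname(v), unname(v_sw))))
  expect_error(ilVector(vc[-1], va), "complete 41-slot")
})
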