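# Reference steroids used throughout: exemestane (C20H24O2) and
# androstenedione (C19H26O2), each with two ketone carbonyls as the only
# polar atoms.
EXEMESTANE_SMILES <- "C=C1CC2C(CCC3(C)C2CCC3=O)C2(C)C=CC(=O)C=C12"
ANDROSTENEDIONE_SMILES <- "CC12CCC(=O)C=C1CCC3C2CCC4(C3CCC4=O)C"

test_that("molecular weight sums standard masses over formulas and graphs", {
  expect_equal(molecular_weight("H2O"), 18.02, tolerance = 0.005)
  expect_equal(molecular_weight("C20H24O2"), 296.4, tolerance = 0.05)
  expect_equal(molecular_weight("C19H26O2"), 286.4, tolerance = 0.05)
  ex <- read_small_molecule(EXEMESTANE_SMILES, id = "exemestane")
  an <- read_small_molecule(ANDROSTENEDIONE_SMILES, id = "androstenedione")
  # graph route (implicit hydrogens from perception) agrees with the formula
  expect_equal(molecular_weight(ex), molecular_weight("C20H24O2"))
  expect_equal(molecular_weight(an), molecular_weight("C19H26O2"))
  expect_error(molecular_weight("C2Xx3"), "unknown element")
})

test_that("molecular weight and TPSA are invariant under atom reordering", {
  m <- read_small_molecule("CC(=O)NC1=CC=C(O)C=C1", id = "paracetamol")
  perm <- rev(seq_len(nrow(m$atoms)))
  m2 <- m
  m2$atoms <- m$atoms[perm, ]
  inv <- order(perm)
  m2$bonds$i <- inv[m$bonds$i]
  m2$bonds$j <- inv[m$bonds$j]
  expect_equal(molecular_weight(m2), molecular_weight(m))
  expect_equal(tpsa(m2), tpsa(m))
})

test_that("Ertl TPSA reproduces fragment-table sums", {
  # alkane: no polar atoms
  expect_equal(tpsa(read_small_molecule("CCCCC")), 0)
  # two ketone carbonyl oxygens: 2 x 17.07 = 34.14 (the steroid case)
  ex <- read_small_molecule(EXEMESTANE_SMILES, id = "exemestane")
  an <- read_small_molecule(ANDROSTENEDIONE_SMILES, id = "androstenedione")
  expect_equal(tpsa(ex), 2 * 17.07)
  expect_equal(tpsa(an), 2 * 17.07)
  # carboxylic acid: carbonyl O (17.07) + hydroxyl O (20.23)
  expect_equal(tpsa(read_small_molecule("CC(=O)O")), 37.30)
  # aromatic nitrogen cases from the table
  expect_equal(tpsa(read_small_molecule("c1ccncc1")), 12.89)   # pyridine
  expect_equal(tpsa(read_small_molecule("c1cc[nH]c1")), 15.79) # pyrrole
  # ether and hydroxyl
  expect_equal(tpsa(read_small_molecule("COC")), 9.23)
  expect_equal(tpsa(read_small_molecule("CCO")), 20.23)
})

test_that("TPSA agrees with OpenBabel's implementation on drug-like SMILES", {
  smiles <- c(
    "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
    "CN1CCC[C@H]1c1cccnc1",           # nicotine
    "CC(=O)NC1=CC=C(O)C=C1",          # paracetamol
    "OCC(O)CO",                       # glycerol
    "c1ccc2[nH]ccc2c1"                # indole
  )
  for (s in smiles) {
    mol <- read_small_molecule(s)
    ob <- ChemmineR::propOB(pocketrepo:::mol_to_sdfset(mol))$TPSA
    expect_equal(tpsa(mol), ob, tolerance = 1e-6, label = s)
  }
})

test_that("Crippen logP is additive over disconnected fragments", {
  m1 <- read_small_molecule("CCO")
  m2 <- read_small_molecule("c1ccccc1")
  both <- read_small_molecule("CCO.c1ccccc1")
  expect_equal(clogp(both), clogp(m1) + clogp(m2), tolerance = 1e-6)
  expect_true(is.finite(clogp(read_small_molecule("C"))))
})

test_that("fingerprint Tanimoto has the metric and identity properties", {
  ex <- read_small_molecule(EXEMESTANE_SMILES, id = "ex")
  an <- read_small_molecule(ANDROSTENEDIONE_SMILES, id = "an")
  et <- read_small_molecule("CCO", id = "ethanol")
  f_ex <- fingerprint(ex)
  f_an <- fingerprint(an)
  f_et <- fingerprint(et)
  expect_equal(tanimoto(f_ex, f_ex), 1)
  expect_equal(tanimoto(f_ex, f_an), tanimoto(f_an, f_ex))
  expect_gt(tanimoto(f_ex, f_an), tanimoto(f_ex, f_et))
  # 1 - TC triangle inequality on the triple
  d <- function(a, b) 1 - tanimoto(a, b)
  expect_lte(d(f_ex, f_an), d(f_ex, f_et) + d(f_et, f_an) + 1e-12)
  expect_lte(d(f_ex, f_et), d(f_ex, f_an) + d(f_an, f_et) + 1e-12)
  other <- structure(list(bits = f_ex$bits, scheme = "other"), class = "chem_fp")
  expect_error(tanimoto(f_ex, other), "schemes differ")
})

test_that("maximum common substructure matches enumeration anchors", {
  eth <- read_small_molecule("CCO")
  amine <- read_small_molecule("CCN")
  m <- mcs_common_atoms(eth, amine)
  expect_equal(m$count, 2)     # the CC fragment
  expect_true(m$exact)
  # symmetric in count
  expect_equal(mcs_common_atoms(amine, eth)$count, 2)
  # aromatic/aliphatic mismatch blocks benzene vs cyclohexane
  bz <- read_small_molecule("c1ccccc1")
  ch <- read_small_molecule("C1CCCCC1")
  expect_equal(mcs_common_atoms(bz, ch)$count, 0)
  # self-match is the identity
  self <- mcs_common_atoms(eth, eth)
  expect_equal(self$count, 3)
  expect_equal(self$mapping$a_atom, self$mapping$b_atom)
})

test_that("descriptor sets collect the three descriptors", {
  ex <- read_small_molecule(EXEMESTANE_SMILES, id = "exemestane")
  d <- descriptor_set(ex)
  expect_equal(round(d$mw), 296)
  expect_equal(round(d$tpsa, 1), 34.1)
  expect_equal(round(d$logp, 2), 4.03)
})
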