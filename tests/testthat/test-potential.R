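test_that("contact counting respects bins, boundaries and additivity", {
  typing <- default_atom_typing()
  binning <- distance_binning(width = 1, r_cut = 10)
  prot <- mol_structure(tibble::tibble(
    serial = 1L, name = "CB", altloc = "", res_name = "ALA", chain = "A",
    resnum = 1L, icode = "", x = 0, y = 0, z = 0, occupancy = 1,
    element = "C", hetero = FALSE
  ), id = "p1")
  pose_at <- function(d) coords_mol(rbind(c(d, 0, 0)), elements = "O")
  cc <- count_contacts(list(list(structure = prot, pose = pose_at(3.2))),
    typing, binning)
  ip <- match("p.C.sc", typing$protein_types)
  il <- match("l.O", typing$ligand_types)
  expect_equal(cc$counts[ip, il, 4], 1) # bin [3, 4)
  expect_equal(sum(cc$counts), 1)
  # exactly at r_cut: excluded by the half-open binning
  cc_edge <- count_contacts(list(list(structure = prot, pose = pose_at(10))),
    typing, binning)
  expect_equal(sum(cc_edge$counts), 0)
  # duplicating a complex doubles every count
  cpx <- list(structure = prot, pose = pose_at(3.2))
  cc2 <- count_contacts(list(cpx, cpx), typing, binning)
  expect_equal(cc2$counts, 2 * cc$counts)
  expect_error(count_contacts(list()), "at least one")
})

test_that("training reproduces the reference state as zero energy", {
  typing <- default_atom_typing()
  binning <- distance_binning()
  # counts drawn exactly from the reference distribution for one type pair
  counts <- array(0, dim = c(length(typing$protein_types),
    length(typing$ligand_types), binning$n_bins))
  rc <- binning$centers
  ref <- (rc / rc[binning$n_bins])^1.61
  counts[1, 1, ] <- 1000 * ref
  cc <- structure(
    list(counts = counts, typing = typing, binning = binning, n_complexes = 1),
    class = "contact_counts"
  )
  tab <- train_potential(cc, pseudocount = 0)
  expect_true(all(abs(tab$u[1, 1, ]) < 1e-9))
  # doubling all counts leaves u unchanged at pseudocount 0
  cc2 <- cc
  cc2$counts <- cc$counts * 2
  tab2 <- train_potential(cc2, pseudocount = 0)
  expect_equal(tab2$u[1, 1, ], tab$u[1, 1, ], tolerance = 1e-12)
  # planted short-range excess turns the short bins negative
  cc3 <- cc
  cc3$counts[1, 1, 7:8] <- cc3$counts[1, 1, 7:8] * 10 # 3-4 A bins
  tab3 <- train_potential(cc3, pseudocount = 0)
  expect_true(all(tab3$u[1, 1, 7:8] < 0))
})

test_that("complex scoring is additive over tabulated pairs and rigid-invariant", {
  set.seed(71)
  complexes <- make_toy_complexes(80, planted_pair_preference = 0.4, seed = 4)
  cc <- count_contacts(complexes)
  tab <- train_potential(cc)
  cx <- complexes[[1]]
  e <- score_complex(cx$structure, cx$pose, tab)
  expect_true(is.finite(e))
  # rigid motion applied jointly to protein and pose leaves the score fixed
  rot <- random_rotation()
  tr <- rigid_transform(rot, c(7, -3, 2))
  st2 <- cx$structure
  xyz <- apply_transform(tr, as.matrix(st2$atoms[, c("x", "y", "z")]))
  st2$atoms$x <- xyz[, 1]; st2$atoms$y <- xyz[, 2]; st2$atoms$z <- xyz[, 3]
  pose2 <- mol_set_coords(cx$pose, apply_transform(tr, mol_coords(cx$pose)))
  expect_equal(score_complex(st2, pose2, tab), e, tolerance = 1e-9)
  # a ligand beyond the cutoff of every protein atom scores zero
  far <- mol_set_coords(cx$pose, mol_coords(cx$pose) + 500)
  expect_equal(score_complex(cx$structure, far, tab), 0)
})

test_that("planted pair preference is recovered as short-range attraction", {
  # corpus size at which the training contract is stated: 500 complexes
  planted_short_u <- function(pref, seed) {
    complexes <- make_toy_complexes(500, planted_pair_preference = pref,
      seed = seed)
    tab <- train_potential(count_contacts(complexes))
    pair <- attr(complexes, "planted_pair")
    ip <- match(pair[["protein"]], tab$typing$protein_types)
    il <- match(pair[["ligand"]], tab$typing$ligand_types)
    short_bins <- which(tab$binning$centers >= 3 & tab$binning$centers <= 4)
    mean(tab$u[ip, il, short_bins])
  }
  strong <- vapply(1:10, function(s) planted_short_u(0.5, s), numeric(1))
  expect_true(all(strong < 0))
  null <- vapply(1:10, function(s) planted_short_u(0, s), numeric(1))
  expect_lt(abs(mean(null)), 0.2)
})

test_that("source-destination energy comparison summarizes correlation", {
  recs <- tibble::tibble(
    source_energy = c(-5, -3, -1, -7),
    destination_energies = list(c(-5), c(-3), c(-1), c(-7))
  )
  cmp <- compare_source_destination(recs)
  expect_equal(cmp$correlation, 1)
  expect_equal(cmp$slope, 1)
  set.seed(72)
  src <- rnorm(50, mean = -20, sd = 5)
  recs2 <- tibble::tibble(
    source_energy = src,
    destination_energies = lapply(src, function(e) e + rnorm(3, sd = 1))
  )
  cmp2 <- compare_source_destination(recs2)
  expect_gt(cmp2$correlation, 0.95)
  expect_s3_class(autoplot(cmp2), "ggplot")
  expect_named(glance(cmp2), c("n", "correlation", "slope", "intercept"))
  expect_error(compare_source_destination(recs[1:2, ]), "at least 3")
  degenerate <- tibble::tibble(
    source_energy = c(-1, -1, -1),
    destination_energies = list(-1, -1, -1)
  )
  expect_error(compare_source_destination(degenerate), "degenerate")
})

test_that("potential tables round-trip through JSON", {
  complexes <- make_toy_complexes(20, planted_pair_preference = 0.3, seed = 8)
  tab <- train_potential(count_contacts(complexes))
  path <- withr::local_tempfile(fileext = ".json")
  write_potential(tab, path)
  tab2 <- read_potential(path)
  expect_equal(tab2$u, tab$u, tolerance = 1e-12)
  expect_equal(tab2$alpha, tab$alpha)
  expect_equal(tab2$binning$edges, tab$binning$edges)
})
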