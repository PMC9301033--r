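test_that("role perception follows the documented rules", {
  roles <- assign_roles(benzene_conf())
  expect_length(roles$rings, 1)
  expect_length(roles$donors, 0)
  expect_length(roles$acceptors, 0)
  # aromatic carbons are excluded from the hydrophobic set by design so
  # stacking and hydrophobic channels stay disjoint
  expect_length(roles$hydrophobic, 0)
  expect_equal(sqrt(sum(roles$rings[[1]]$normal^2)), 1)

  # ammonium fragment: positively charged group carrying the donor role
  amm <- embed_conformer(smiles_mol("C[NH3+]", "methylammonium"))
  ra <- assign_roles(amm)
  expect_length(ra$positive, 1)
  expect_gte(length(ra$donors), 1)

  # toluene: the methyl carbon is hydrophobic
  tol <- embed_conformer(smiles_mol("Cc1ccccc1", "toluene"))
  rt <- assign_roles(tol)
  expect_length(rt$hydrophobic, 1)
  expect_equal(tol$atoms$elem[rt$hydrophobic], "C")
})

test_that("aspartate-like residue template carries one carboxylate group", {
  cx <- mk_complex(6)   # residue 0 is an ASP template
  roles <- assign_roles(cx$receptor)
  expect_length(roles[[1]]$negative, 1)
  expect_length(roles[[1]]$negative[[1]]$atoms, 2)
})

test_that("a planted ideal hydrogen bond yields exactly one contact", {
  cx <- mk_complex(3)
  ct <- detect_contacts(cx$receptor, cx$ligand)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$channel, 3L)
  expect_equal(ct$residue, 0L)
  expect_lte(ct$distance, 3.5)
})

test_that("a ligand translated 50 A away makes no contacts", {
  cx <- mk_complex(c(0, 1, 3, 4))
  far <- translate(cx$ligand, c(50, 0, 0))
  expect_equal(nrow(detect_contacts(cx$receptor, far)), 0L)
})

test_that("planted interactions are recovered exactly for every channel", {
  for (channels in list(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L,
                        c(0, 1, 2, 3, 4), c(5, 6, 7), c(3, 4, 1, 1))) {
    cx <- mk_complex(channels)
    ct <- detect_contacts(cx$receptor, cx$ligand)
    expect_identical(contacts_as_pairs(ct), truth_as_pairs(cx),
                     label = paste("channels", paste(channels, collapse = ",")))
  }
})

test_that("detection is invariant under joint rigid motion", {
  cx <- mk_complex(c(0, 2, 3, 5))
  ref <- contacts_as_pairs(detect_contacts(cx$receptor, cx$ligand))
  for (seed in 1:3) {
    R <- random_rotation(seed)
    t <- c(5, -3, 11)
    lig <- ifpgrow:::transform_mol(cx$ligand, R, t)
    rec <- cx$receptor
    for (i in seq_along(rec$residues)) {
      xyz <- as.matrix(rec$residues[[i]]$atoms[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, t, "+")
      rec$residues[[i]]$atoms$x <- xyz[, 1]
      rec$residues[[i]]$atoms$y <- xyz[, 2]
      rec$residues[[i]]$atoms$z <- xyz[, 3]
    }
    expect_identical(contacts_as_pairs(detect_contacts(rec, lig)), ref)
  }
})

test_that("shrinking cutoffs never adds contacts", {
  cx <- mk_complex(c(0, 1, 2, 3, 4))
  loose <- detect_contacts(cx$receptor, cx$ligand, contact_params())
  tight <- detect_contacts(cx$receptor, cx$ligand, contact_params(
    hydrophobic_dist = 2.8, aromatic_dist = 3.5, hbond_dist = 2.4,
    salt_dist = 2.8, metal_dist = 2.0))
  expect_true(all(contacts_as_pairs(tight) %in% contacts_as_pairs(loose)))
})

test_that("contact parameters are validated", {
  expect_error(contact_params(hbond_dist = -1), "distance")
  expect_error(contact_params(f2f_angle_max = 200), "angle")
  expect_error(assign_roles(smiles_mol("CCO")), "no conformer")
})
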